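random_expr_matrix <- function(n_genes, n_samples) {
  mat <- matrix(
    round(2^rnorm(n_genes * n_samples, 5, 2), 4),
    nrow = n_genes,
    dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                    sprintf("S%02d", seq_len(n_samples)))
  )
  mat
}

test_that("ssGSEA equals the naive reference on a small worked matrix", {
  mat <- matrix(c(5, 3, 9, 1, 7), ncol = 1,
                dimnames = list(paste0("G", 1:5), "S1"))
  sig <- gene_signature("toy", c("G1", "G3"))
  got <- ssgsea_scores(mat, sig, alpha = 0.25, normalize = FALSE)
  expect_equal(got$score, ssgsea_reference(mat, sig$genes, normalize = FALSE),
               tolerance = 1e-10)
})

test_that("ssGSEA is rank-invariant and identical for identical profiles", {
  set.seed(31)
  mat <- random_expr_matrix(40, 3)
  mat[, 2] <- mat[, 1] # duplicate profile
  sig <- gene_signature("s", rownames(mat)[c(3, 8, 15, 22)])
  sc <- ssgsea_scores(mat, sig, normalize = FALSE)
  expect_equal(sc$score[1], sc$score[2], tolerance = 1e-12)

  # strictly increasing transform leaves ranks, hence scores, unchanged
  sc2 <- ssgsea_scores(log1p(mat)^3, sig, normalize = FALSE)
  expect_equal(sc2$score, sc$score, tolerance = 1e-12)
})

test_that("ssGSEA matches the reference on random instances, both modes", {
  set.seed(17)
  for (i in 1:50) {
    n_genes <- sample(5:50, 1)
    n_samples <- sample(1:5, 1)
    mat <- random_expr_matrix(n_genes, n_samples)
    n_sig <- sample(2:max(2, n_genes %/% 2), 1)
    sig <- gene_signature("r", sample(rownames(mat), n_sig))
    for (norm in c(TRUE, FALSE)) {
      got <- ssgsea_scores(mat, sig, alpha = 0.25, normalize = norm)
      expect_equal(got$score,
                   ssgsea_reference(mat, sig$genes, 0.25, norm),
                   tolerance = 1e-10)
    }
  }
})

test_that("ssGSEA validates signature coverage and degenerate input", {
  mat <- random_expr_matrix(20, 2)
  sig <- gene_signature("missing", c(rownames(mat)[1], "NOPE1", "NOPE2"))
  expect_error(ssgsea_scores(mat, sig), "NOPE1")

  flat <- mat
  flat[, 1] <- 1
  ok_sig <- gene_signature("ok", rownames(mat)[1:4])
  expect_warning(ssgsea_scores(flat, ok_sig), "constant expression")
})

test_that("gene-wise z-scoring uses the population-SD convention", {
  mat <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_warning(z <- zscore_genes(mat), "zero-variance")
  expect_equal(unname(z["g1", ]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_error(zscore_genes(mat[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("group comparison uses the exact rank-sum null and is symmetric", {
  scores <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                           score = c(1, 2, 3, 4, 5, 6))
  labels <- setNames(rep(c("lo", "hi"), each = 3), scores$sample_id)
  res <- compare_groups(scores, labels)
  # enumeration of the C(6,3) = 20 rank splits gives p = 2/20 = 0.1
  expect_equal(res$p_value, 0.1)
  expect_equal(sort(c(res$median_1, res$median_2)), c(2, 5))

  flipped <- setNames(rep(c("hi", "lo"), each = 3), scores$sample_id)
  expect_equal(compare_groups(scores, flipped)$p_value, res$p_value)

  # identical score multisets: p = 1
  same <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                         score = rep(c(1, 2, 3), 2))
  expect_equal(compare_groups(same, labels)$p_value, 1)

  expect_error(compare_groups(scores, labels[1:5]), "label")
})

test_that("group comparison recovers simulated signature shifts", {
  # null: rejection near nominal; strong shift: near-certain rejection
  rejections <- function(effect, reps) {
    mean(vapply(seq_len(reps), function(i) {
      sim <- simulate_expression_cohort(
        n_per_group = 12, effect_size = effect,
        n_background_genes = 120, seed = 1000 + i
      )
      sc <- ssgsea_scores(sim$matrix, tis_signature(), normalize = FALSE)
      compare_groups(sc, sim$labels)$p_value < 0.05
    }, logical(1)))
  }
  expect_lte(rejections(0, 40), 0.15)
  expect_gte(rejections(2, 40), 0.9)
})

test_that("panel normalization subtracts background and equalizes housekeeping", {
  genes <- c("T1", "T2", "NEG1", "NEG2", "HK1", "HK2")
  raw <- matrix(
    c(100, 50, 0, 0, 60, 40, # sample A: clean background, hk sum 100
      220, 90, 10, 30, 250, 150), # sample B: background 20, hk sum 400 - 40
    nrow = 6, dimnames = list(genes, c("A", "B"))
  )
  res <- normalize_panel_counts(raw, c("NEG1", "NEG2"), c("HK1", "HK2"))
  norm <- res$normalized
  hk_sums <- colSums(norm[c("HK1", "HK2"), ])
  expect_equal(hk_sums[["A"]], hk_sums[["B"]], tolerance = 1e-9)

  # zero negative controls leave sample A untouched up to its scale factor
  scale_a <- norm["T1", "A"] / raw["T1", "A"]
  expect_equal(norm["T2", "A"] / raw["T2", "A"], scale_a, tolerance = 1e-12)

  # counts below background floor at zero
  raw2 <- raw
  raw2["T2", "B"] <- 5 # below background of 20
  res2 <- normalize_panel_counts(raw2, c("NEG1", "NEG2"), c("HK1", "HK2"))
  expect_equal(res2$normalized["T2", "B"], 0)

  # housekeeping-dead sample is flagged and excluded
  raw3 <- raw
  raw3[c("HK1", "HK2"), "B"] <- 0
  expect_warning(res3 <- normalize_panel_counts(raw3, c("NEG1", "NEG2"),
                                                c("HK1", "HK2")),
                 "excluding")
  expect_equal(res3$excluded, "B")
})

test_that("longitudinal mixed model recovers visit shifts and controls type I", {
  make_long <- function(n_pat, shift, seed) {
    withr::with_seed(seed, {
      pat <- sprintf("P%02d", seq_len(n_pat))
      base <- rnorm(n_pat, 0, 1)
      tibble::tibble(
        patient_id = rep(pat, 3),
        visit = rep(c("C0D1", "C1D1", "C1D22"), each = n_pat),
        score = c(base + rnorm(n_pat, 0, 0.5),
                  base + shift + rnorm(n_pat, 0, 0.5),
                  base + rnorm(n_pat, 0, 0.5))
      )
    })
  }
  # null calibration over replicate fits
  p_null <- vapply(1:60, function(i) {
    longitudinal_signature_model(make_long(12, 0, 5000 + i))$lrt_p
  }, numeric(1))
  expect_lte(mean(p_null < 0.05), 0.15)

  # a +1 SD shift at the second visit is recovered within 2 SEs
  hits <- vapply(1:30, function(i) {
    fit <- longitudinal_signature_model(make_long(40, 1, 7000 + i))
    est <- fit$estimates[fit$estimates$visit == "C1D1", ]
    abs(est$estimate - 1) <= 2 * est$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(
    longitudinal_signature_model(
      tibble::tibble(patient_id = "P1", visit = c("C0D1", "C1D1"),
                     score = c(0, 1))
    ),
    "at least 3 patients"
  )
})
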
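test_that("repertoire simulator is deterministic in (spec, seed)", {
  a <- simulate_longitudinal_repertoires(3, n_clones = 80, depth = 800,
                                         seed = 5)
  b <- simulate_longitudinal_repertoires(3, n_clones = 80, depth = 800,
                                         seed = 5)
  expect_identical(a$repertoires[[2]]$samples[[2]]$clonotypes,
                   b$repertoires[[2]]$samples[[2]]$clonotypes)
  c <- simulate_longitudinal_repertoires(3, n_clones = 80, depth = 800,
                                         seed = 6)
  expect_false(identical(a$repertoires[[1]]$samples[[1]]$clonotypes,
                         c$repertoires[[1]]$samples[[1]]$clonotypes))
  # no expansion events -> empty ground truth
  expect_equal(nrow(a$truth), 0)
  # generators leave global RNG state untouched
  suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
  invisible(simulate_longitudinal_repertoires(1, n_clones = 10, depth = 100,
                                              seed = 1))
  expect_false(exists(".Random.seed", envir = globalenv()))
})

test_that("simulated repertoires satisfy the consuming modules' invariants", {
  sim <- simulate_longitudinal_repertoires(
    2, n_clones = 100, depth = 1000,
    expansion_events = data.frame(clone = 3L, visit = "C1D1", fold = 5,
                                  target_freq = NA),
    seed = 9
  )
  for (rep in sim$repertoires) {
    expect_equal(names(rep$samples), default_visit_schedule())
    for (s in rep$samples) {
      expect_s3_class(s, "repertoire_sample")
      expect_false(is_empty_sample(s))
      expect_equal(sum(s$clonotypes$template_count), s$total_templates)
      expect_false(anyDuplicated(s$clonotypes$rearrangement_id) > 0)
      # round-trips through clonality without error
      expect_true(clonality(s)$clonality >= 0)
    }
  }
  expect_equal(nrow(sim$truth), 2) # one event x two patients
})

test_that("observed top-clone frequency tracks the latent power law", {
  sim <- simulate_longitudinal_repertoires(1, n_clones = 1000, depth = 10000,
                                           visits = "C0D1", exponent = 1,
                                           seed = 33)
  s <- sim$repertoires[[1]]$samples[[1]]
  latent_top <- (1 / sum((1:1000)^-1))
  obs_top <- max(s$clonotypes$template_count) / s$total_templates
  se <- sqrt(latent_top * (1 - latent_top) / 10000)
  expect_lt(abs(obs_top - latent_top), 4 * se)
})

test_that("expansion events validate and inject as specified", {
  expect_error(
    simulate_longitudinal_repertoires(
      1, n_clones = 10, depth = 100,
      expansion_events = data.frame(clone = 1L, visit = "C1D1", fold = 0.5),
      seed = 1
    ),
    "exceed 1"
  )
  expect_error(
    simulate_longitudinal_repertoires(
      1, n_clones = 10, depth = 100,
      expansion_events = data.frame(clone = 1L, visit = "C1D1", fold = 100),
      seed = 1
    ),
    "above 1"
  )
  sim <- simulate_longitudinal_repertoires(
    1, n_clones = 200, depth = 5000,
    expansion_events = data.frame(clone = NA_integer_, visit = "C1D22",
                                  fold = NA, target_freq = 0.05),
    seed = 11
  )
  novel_id <- sim$truth$rearrangement_id[1]
  s3 <- sim$repertoires[[1]]$samples[["C1D22"]]
  expect_true(novel_id %in% s3$clonotypes$rearrangement_id)
  s1 <- sim$repertoires[[1]]$samples[["C0D1"]]
  expect_false(novel_id %in% s1$clonotypes$rearrangement_id)
})

test_that("expression simulator is seeded and shifts only signature genes", {
  a <- simulate_expression_cohort(n_per_group = 5, effect_size = 1,
                                  n_background_genes = 50, seed = 4)
  b <- simulate_expression_cohort(n_per_group = 5, effect_size = 1,
                                  n_background_genes = 50, seed = 4)
  expect_identical(a$matrix, b$matrix)
  expect_error(
    simulate_expression_cohort(effect_size = -1, seed = 1),
    "effect_size"
  )

  # with a huge effect, signature rows separate by group; background doesn't
  big <- simulate_expression_cohort(n_per_group = 15, effect_size = 4,
                                    n_background_genes = 100, seed = 8)
  lg <- log2(big$matrix)
  sig_rows <- rownames(lg) %in% big$truth$signature_genes
  diff_sig <- rowMeans(lg[sig_rows, big$labels == "group_2"]) -
    rowMeans(lg[sig_rows, big$labels == "group_1"])
  diff_bg <- rowMeans(lg[!sig_rows, big$labels == "group_2"]) -
    rowMeans(lg[!sig_rows, big$labels == "group_1"])
  expect_gt(min(diff_sig), 2)
  expect_lt(max(abs(mean(diff_bg)), 0), 0.5)
})

test_that("clinical simulator respects arm parameters and determinism", {
  arms <- tibble::tibble(module = "m", n = 50, responder_prob = 0,
                         median_pfs_weeks = 20, median_os_weeks = 60)
  sim <- simulate_clinical_cohort(arms = arms, seed = 13)
  expect_equal(nrow(sim$patients), 50)
  expect_equal(compute_orr(sim$patients, sim$assessments)$pct, 0)

  sim2 <- simulate_clinical_cohort(arms = arms, seed = 13)
  expect_identical(sim$patients, sim2$patients)
  expect_identical(sim$assessments, sim2$assessments)

  expect_error(
    simulate_clinical_cohort(
      arms = tibble::tibble(module = "m", n = 5, responder_prob = 2,
                            median_pfs_weeks = 10, median_os_weeks = 20),
      seed = 1
    ),
    "responder_prob"
  )
})

test_that("assessment sequences are valid patient records", {
  sim <- simulate_clinical_cohort(seed = 29)
  ok <- vapply(split(sim$assessments, sim$assessments$patient_id),
               function(a) {
    all(diff(a$week) > 0) &&
      all(a$category %in% c("CR", "PR", "SD", "PD", "NE")) &&
      sum(a$category == "PD") <= 1
  }, logical(1))
  expect_true(all(ok))
  # death never precedes the last assessment
  last_assess <- tapply(sim$assessments$week, sim$assessments$patient_id, max)
  pat <- sim$patients[sim$patients$patient_id %in% names(last_assess), ]
  dw <- pat$death_week[match(names(last_assess), pat$patient_id)]
  expect_true(all(is.na(dw) | dw >= last_assess))
})
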
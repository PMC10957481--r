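# Single-sample gene-set enrichment scoring of inflammation signatures,
# gene-wise z-scoring, subgroup rank-sum comparisons, panel-count
# normalization and longitudinal mixed-effect signature modeling.

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Non-empty character vector of unique gene symbols.
#' @return A `gene_signature` (named list with `name`, `genes`).
#' @export
gene_signature <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) abort("a signature needs at least one gene symbol")
  if (anyDuplicated(toupper(genes))) abort("signature gene symbols must be unique")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_signature")
}

#' Read gene signatures from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   then symbols).
#' @return Named list of `gene_signature` objects.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(setNames(names(sets), names(sets)), function(nm) {
    gene_signature(nm, sets[[nm]])
  })
}

#' The 18-gene tumor inflammation signature (TIS)
#'
#' Loads the published 18-gene tumor inflammation signature shipped with
#' the package as an editable GMT file (`inst/extdata/signatures/`). The
#' membership is configuration, not code: point [read_gene_sets()] at your
#' own file to score a different signature.
#'
#' @return A `gene_signature` with 18 genes.
#' @export
tis_signature <- function() {
  path <- system.file("extdata", "signatures", "tis_18_gene.gmt",
                      package = "tcelldyn")
  read_gene_sets(path)[["TIS_18_GENE"]]
}

.check_expression_matrix <- function(mat, min_samples = 1) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(mat))) abort("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) abort("duplicate sample ids")
  if (any(mat < 0, na.rm = TRUE)) abort("expression values must be non-negative")
  if (ncol(mat) < min_samples) {
    abort(sprintf("at least %d samples required", min_samples))
  }
  invisible(mat)
}

# Case-insensitive exact symbol matching after whitespace stripping; no
# alias resolution, so results are deterministic without external databases.
.match_signature <- function(mat, signature, min_frac = 0.5) {
  genes_up <- toupper(trimws(rownames(mat)))
  sig_up <- toupper(trimws(signature$genes))
  hit <- match(sig_up, genes_up)
  found <- !is.na(hit)
  frac <- mean(found)
  if (frac < min_frac) {
    abort(sprintf(
      "only %.0f%% of signature '%s' present in the matrix; missing: %s",
      100 * frac, signature$name,
      paste(signature$genes[!found], collapse = ", ")
    ))
  }
  list(rows = hit[found], fraction_found = frac)
}

#' Single-sample GSEA enrichment scores
#'
#' Per-sample rank-based enrichment of a gene set, in the weighted-ECDF
#' form introduced for single-sample scoring: within each sample, genes
#' are ranked by expression (average rank for ties; tied positions ordered
#' deterministically by gene id), in-set genes are weighted by
#' `rank^alpha`, and the score is the sum over the ordered gene list of
#' the difference between the weighted in-set ECDF and the uniform
#' out-of-set ECDF. Scores depend on ranks only, so any strictly
#' increasing per-sample transform of expression leaves them unchanged.
#'
#' @param mat Numeric genes x samples matrix (TPM or normalized counts),
#'   with row and column names.
#' @param signature A [gene_signature()].
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide all scores by their range across samples
#'   (default `TRUE`, emulating the usual ssGSEA normalization; with a
#'   single sample the raw score is returned).
#' @param min_frac Minimum fraction of signature genes that must be
#'   present (default 0.5), else an error listing the missing symbols.
#' @return Tibble with `sample_id`, `score`, plus the signature name and
#'   fraction of genes found as attributes `signature` and
#'   `fraction_genes_found`.
#' @export
ssgsea_scores <- function(mat, signature, alpha = 0.25, normalize = TRUE,
                          min_frac = 0.5) {
  .check_expression_matrix(mat)
  if (nrow(mat) < 2) abort("at least 2 genes required")
  m <- .match_signature(mat, signature, min_frac)
  in_set <- logical(nrow(mat))
  in_set[m$rows] <- TRUE
  if (all(in_set)) abort("signature covers every gene in the matrix")

  es <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    r <- rank(x, ties.method = "average")
    if (length(unique(x)) == 1L) {
      warn(sprintf("constant expression in sample %s", colnames(mat)[j]))
    }
    ord <- order(-r, rownames(mat))
    w <- r[ord]^alpha
    inn <- in_set[ord]
    step_in <- cumsum(w * inn) / sum(w[inn])
    step_out <- cumsum(!inn) / sum(!inn)
    sum(step_in - step_out)
  }, numeric(1))

  if (normalize && ncol(mat) > 1) {
    rng <- diff(range(es))
    if (rng > 0) es <- es / rng
  }
  out <- tibble(sample_id = colnames(mat), score = es)
  attr(out, "signature") <- signature$name
  attr(out, "fraction_genes_found") <- m$fraction_found
  out
}

#' Gene-wise z-scoring of an expression matrix
#'
#' Centers and scales each gene row to mean 0 and unit standard deviation
#' using the population (divide-by-n) convention. Zero-variance rows are
#' set to all zeros with a warning.
#'
#' @param mat Numeric genes x samples matrix with at least 2 samples.
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2) {
    abort("z-scoring requires a matrix with at least 2 samples")
  }
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))
  flat <- sdp == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene row(s) set to zero", sum(flat)))
    sdp[flat] <- 1
  }
  out <- (mat - mu) / sdp
  out[flat, ] <- 0
  out
}

#' Compare signature scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test between the two label groups: exact
#' null distribution when both groups have at most `exact_max`
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction. Deliberately applies no multiplicity adjustment;
#' when several subgroup comparisons are run, treat the p-values as
#' exploratory.
#'
#' @param scores Tibble from [ssgsea_scores()] (or any data frame with
#'   `sample_id` and `score`).
#' @param labels Named character/factor vector mapping sample ids to
#'   exactly two groups.
#' @param exact_max Largest per-group size for the exact test (default 20).
#' @return One-row tibble: group names, sizes, medians and `p_value`.
#' @export
compare_groups <- function(scores, labels, exact_max = 20) {
  labs <- labels[scores$sample_id]
  if (anyNA(labs)) abort("every sample needs a group label")
  groups <- sort(unique(as.character(labs)))
  if (length(groups) != 2) abort("exactly two groups are required")
  x <- scores$score[labs == groups[1]]
  y <- scores$score[labs == groups[2]]
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(
    group_1 = groups[1], group_2 = groups[2],
    n_1 = length(x), n_2 = length(y),
    median_1 = median(x), median_2 = median(y),
    p_value = wt$p.value
  )
}

#' Normalize panel counts (background subtraction + housekeeping scaling)
#'
#' Emulates the standard two-step normalization of hybridization-counting
#' panels: per sample, the background (mean of negative-control counts
#' plus `k` standard deviations) is subtracted with a floor at zero; each
#' sample is then scaled by the ratio of the cohort geometric mean of
#' housekeeping sums to its own housekeeping sum, so housekeeping sums are
#' equal across retained samples by construction.
#'
#' @param raw Numeric genes x samples matrix of raw counts.
#' @param negative_controls,housekeeping Character vectors of control gene
#'   ids present in `raw`.
#' @param k Number of negative-control standard deviations added to the
#'   background (default 0).
#' @return List with `normalized` (matrix, control rows retained) and
#'   `excluded` (sample ids dropped for a zero housekeeping sum, with a
#'   warning).
#' @export
normalize_panel_counts <- function(raw, negative_controls, housekeeping,
                                   k = 0) {
  .check_expression_matrix(raw)
  missing <- setdiff(c(negative_controls, housekeeping), rownames(raw))
  if (length(missing)) {
    abort(sprintf("control gene(s) absent from matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  neg <- raw[negative_controls, , drop = FALSE]
  bg <- colMeans(neg) + k * apply(neg, 2, sd)
  bg[is.na(bg)] <- colMeans(neg)[is.na(bg)] # single negative control
  sub <- pmax(sweep(raw, 2, bg, "-"), 0)

  hk_sum <- colSums(sub[housekeeping, , drop = FALSE])
  keep <- hk_sum > 0
  if (any(!keep)) {
    warn(sprintf("excluding sample(s) with zero housekeeping signal: %s",
                 paste(colnames(raw)[!keep], collapse = ", ")))
  }
  sub <- sub[, keep, drop = FALSE]
  hk_sum <- hk_sum[keep]
  scale <- geometric_mean(hk_sum) / hk_sum
  list(
    normalized = sweep(sub, 2, scale, "*"),
    excluded = colnames(raw)[!keep]
  )
}

#' Longitudinal mixed-effect model of signature scores
#'
#' Fits `score ~ visit + (1 | patient)` by maximum likelihood (visit as a
#' fixed factor with the first schedule level as baseline, patient-level
#' random intercept) and tests the visit effect with a likelihood-ratio
#' test against the intercept-only model. Per-visit contrasts versus
#' baseline are reported with Wald standard errors. If the fit fails or
#' does not converge, falls back to paired signed-rank tests per visit
#' with a warning.
#'
#' @param scores Data frame with `patient_id`, `visit`, `score`.
#' @param schedule Visit ordering; the first level present is baseline.
#' @return List with `estimates` (tibble: `visit`, `estimate`, `se`),
#'   `lrt_p` (global visit-effect p-value), and `method`
#'   (`"lmm"` or `"signed_rank"`).
#' @export
longitudinal_signature_model <- function(scores,
                                         schedule = default_visit_schedule()) {
  stopifnot(all(c("patient_id", "visit", "score") %in% names(scores)))
  lv <- intersect(schedule, unique(scores$visit))
  if (length(lv) < 2) abort("at least 2 visits required")
  reps <- table(scores$patient_id)
  if (sum(reps >= 2) < 3) {
    abort("at least 3 patients with repeated measures required")
  }
  dat <- data.frame(
    patient = factor(scores$patient_id),
    visit = factor(scores$visit, levels = lv),
    score = scores$score
  )
  fit <- tryCatch({
    full <- lme4::lmer(score ~ visit + (1 | patient), data = dat, REML = FALSE)
    null <- lme4::lmer(score ~ 1 + (1 | patient), data = dat, REML = FALSE)
    conv <- full@optinfo$conv$lme4
    if (!is.null(conv$code) && conv$code != 0) stop("non-convergence")
    list(full = full, null = null)
  }, error = function(e) NULL)

  if (is.null(fit)) {
    warn("mixed model did not converge; falling back to paired signed-rank tests")
    base <- dat[dat$visit == lv[1], c("patient", "score")]
    est <- dplyr::bind_rows(lapply(lv[-1], function(v) {
      cur <- dat[dat$visit == v, c("patient", "score")]
      m <- merge(base, cur, by = "patient", suffixes = c("_0", "_1"))
      wt <- suppressWarnings(wilcox.test(m$score_1, m$score_0, paired = TRUE))
      tibble(visit = v, estimate = median(m$score_1 - m$score_0),
             se = NA_real_, p_value = wt$p.value)
    }))
    return(list(estimates = est, lrt_p = min(est$p_value) * nrow(est),
                method = "signed_rank"))
  }

  beta <- lme4::fixef(fit$full)
  se <- sqrt(diag(as.matrix(stats::vcov(fit$full))))
  idx <- grep("^visit", names(beta))
  est <- tibble(
    visit = sub("^visit", "", names(beta)[idx]),
    estimate = unname(beta[idx]),
    se = unname(se[idx])
  )
  lrt <- anova(fit$null, fit$full)
  list(estimates = est, lrt_p = lrt$`Pr(>Chisq)`[2], method = "lmm")
}
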
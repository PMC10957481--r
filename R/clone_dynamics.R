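# Differential clone-abundance calling between two visits of one patient:
# per-clonotype Fisher exact tests, BH false-discovery control,
# expansion/contraction classification, the newly-detected-expanded rule,
# and cohort-level paired comparisons.

#' Two-sided Fisher exact test for clone abundance
#'
#' For each clonotype, tests the null hypothesis that the population
#' abundance of the clone is identical in the two samples, via the 2x2
#' table `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`.
#' The two-sided p-value is the sum of conditional hypergeometric
#' probabilities of all tables (with the same margins) whose probability
#' does not exceed that of the observed table, the same rule used by
#' [stats::fisher.test()]. Vectorized over clones; totals are recycled.
#'
#' @param count_a,count_b Non-negative integer clone counts in the two
#'   samples.
#' @param total_a,total_b Positive template totals of the two samples.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
fisher_clone_test <- function(count_a, total_a, count_b, total_b) {
  n <- max(length(count_a), length(count_b))
  a <- rep_len(as.numeric(count_a), n)
  b <- rep_len(as.numeric(count_b), n)
  ta <- rep_len(as.numeric(total_a), n)
  tb <- rep_len(as.numeric(total_b), n)
  if (any(ta <= 0) || any(tb <= 0)) abort("totals must be positive")
  if (any(a < 0) || any(b < 0)) abort("counts must be non-negative")
  if (any(a > ta) || any(b > tb)) {
    abort("validation error: count exceeds its sample total")
  }
  vapply(seq_len(n), function(i) {
    .fisher_p_2x2(a[i], ta[i], b[i], tb[i])
  }, numeric(1))
}

# Conditional on both margins, the count in sample A follows a
# hypergeometric distribution; two-sided p sums probabilities <= observed
# (with the conventional 1 + 1e-7 relative tolerance).
.fisher_p_2x2 <- function(a, ta, b, tb) {
  k <- a + b
  if (k == 0) return(1)
  lo <- max(0, k - tb)
  hi <- min(k, ta)
  d <- dhyper(lo:hi, ta, tb, k)
  p_obs <- d[a - lo + 1]
  # floor at the smallest positive double: p lies in (0, 1] by definition,
  # but the probability sum can underflow for extreme tables
  max(min(sum(d[d <= p_obs * (1 + 1e-7)]), 1), .Machine$double.xmin)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement, aligned to the
#' input order (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in input order; empty input gives an empty
#'   vector.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Classify clone dynamics between two visits
#'
#' Tests every clonotype in the union of the two samples with
#' [fisher_clone_test()], adjusts across the tested clones with
#' [bh_adjust()], and labels each clone `expanded` (significant, higher
#' frequency at the later visit), `contracted` (significant, lower
#' frequency) or `unchanged`. Significantly expanded clones absent at the
#' first visit and detected above `read_threshold` reads at the second are
#' flagged newly detected.
#'
#' @param a,b Productive-filtered, non-empty `repertoire_sample` objects
#'   from the same patient; `a` is the earlier visit.
#' @param alpha Significance threshold on adjusted p-values (default 0.01,
#'   applied strictly: `q < alpha`).
#' @param read_threshold Newly-detected read threshold (default 5, applied
#'   strictly: `count_b > read_threshold`).
#' @param newly_requires_significance When `TRUE` (default) the
#'   newly-detected flag is restricted to Fisher-significant expanded
#'   clones; `FALSE` gives the looser absence-plus-count rule for
#'   sensitivity analysis.
#' @return List with `tests` (tibble of per-clone records: counts, totals,
#'   frequencies, `p_value`, `q_value`, `direction`, `newly_detected`) and
#'   `summary` (one-row tibble with the tested/expanded/contracted/newly
#'   detected counts plus the pair's clonality and Morisita-Horn overlap).
#' @export
classify_dynamics <- function(a, b, alpha = 0.01, read_threshold = 5,
                              newly_requires_significance = TRUE) {
  .check_stats_ready(a, "a")
  .check_stats_ready(b, "b")
  if (!identical(a$patient_id, b$patient_id)) {
    abort(sprintf(
      "samples are from different patients (%s vs %s)",
      a$patient_id, b$patient_id
    ))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")

  keys <- union(a$clonotypes$rearrangement_id, b$clonotypes$rearrangement_id)
  ca <- setNames(numeric(length(keys)), keys)
  cb <- ca
  ca[a$clonotypes$rearrangement_id] <- a$clonotypes$template_count
  cb[b$clonotypes$rearrangement_id] <- b$clonotypes$template_count
  ta <- a$total_templates
  tb <- b$total_templates

  p <- fisher_clone_test(ca, ta, cb, tb)
  q <- bh_adjust(p)
  fa <- ca / ta
  fb <- cb / tb
  sig <- q < alpha
  direction <- rep("unchanged", length(keys))
  direction[sig & fb > fa] <- "expanded"
  direction[sig & fb < fa] <- "contracted"
  newly <- ca == 0 & cb > read_threshold
  if (newly_requires_significance) newly <- newly & direction == "expanded"

  tests <- tibble(
    rearrangement_id = keys,
    count_a = as.integer(unname(ca)), count_b = as.integer(unname(cb)),
    total_a = ta, total_b = tb,
    freq_a = unname(fa), freq_b = unname(fb),
    p_value = p, q_value = q,
    direction = direction, newly_detected = unname(newly)
  )
  summary <- tibble(
    patient_id = a$patient_id,
    visit_a = a$visit, visit_b = b$visit,
    n_tested = length(keys),
    n_expanded = sum(direction == "expanded"),
    n_contracted = sum(direction == "contracted"),
    n_newly_detected_expanded = sum(newly),
    clonality_a = clonality(a)$clonality,
    clonality_b = clonality(b)$clonality,
    morisita_horn = morisita_horn(a, b)$morisita_horn
  )
  list(tests = tests, summary = summary)
}

#' Paired cohort comparisons between visits
#'
#' For each requested visit pair, runs a two-sided Wilcoxon paired
#' signed-rank test on patients measured at both visits (zero differences
#' dropped, exact null distribution for up to 25 non-zero pairs, normal
#' approximation with continuity correction above), then BH-adjusts across
#' the comparison set.
#'
#' @param values Data frame with columns `patient_id`, `visit`, `value`
#'   (one measurement per patient-visit, e.g. clonality or expanded-clone
#'   counts).
#' @param comparisons List of length-2 character vectors of visit codes.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   null distribution is used (default 25).
#' @return Tibble with one row per testable comparison: `visit_a`,
#'   `visit_b`, `n_pairs`, `p_value`, `q_value`, plus a `deltas`
#'   list-column of named per-patient differences (`value_b - value_a`)
#'   for waterfall-style output. Comparisons with fewer than two non-zero
#'   pairs are skipped with a warning.
#' @export
cohort_visit_comparison <- function(values, comparisons, exact_max = 25) {
  stopifnot(all(c("patient_id", "visit", "value") %in% names(values)))
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    va <- values[values$visit == cmp[1], c("patient_id", "value")]
    vb <- values[values$visit == cmp[2], c("patient_id", "value")]
    m <- merge(va, vb, by = "patient_id", suffixes = c("_a", "_b"))
    delta <- setNames(m$value_b - m$value_a, m$patient_id)
    n_nonzero <- sum(delta != 0)
    if (nrow(m) < 2 || n_nonzero < 2) {
      warn(sprintf(
        "comparison %s vs %s skipped (%s)", cmp[1], cmp[2],
        if (nrow(m) < 2) "fewer than 2 complete pairs" else "all differences zero"
      ))
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(
      m$value_b, m$value_a,
      paired = TRUE, exact = n_nonzero <= exact_max, correct = TRUE
    ))
    tibble(
      visit_a = cmp[1], visit_b = cmp[2],
      n_pairs = nrow(m), p_value = wt$p.value,
      deltas = list(delta)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$q_value <- bh_adjust(out$p_value)
    out <- out[, c("visit_a", "visit_b", "n_pairs", "p_value", "q_value", "deltas")]
  }
  out
}

#' Clone dynamics across a cohort of longitudinal repertoires
#'
#' Runs [classify_dynamics()] on each consecutive within-patient visit pair.
#'
#' @param repertoires List of `longitudinal_repertoire` objects with
#'   productive-filtered samples.
#' @inheritParams classify_dynamics
#' @return List with `tests` (per-clone records across all pairs, with
#'   patient and visit-pair columns) and `summaries` (one row per pair).
#' @export
cohort_dynamics <- function(repertoires, alpha = 0.01, read_threshold = 5,
                            newly_requires_significance = TRUE) {
  tests <- list()
  summaries <- list()
  for (rep in repertoires) {
    v <- names(rep$samples)
    if (length(v) < 2) next
    for (k in seq_len(length(v) - 1)) {
      res <- classify_dynamics(
        rep$samples[[k]], rep$samples[[k + 1]],
        alpha = alpha, read_threshold = read_threshold,
        newly_requires_significance = newly_requires_significance
      )
      res$tests <- dplyr::bind_cols(
        tibble(
          patient_id = rep$patient_id,
          visit_a = v[k], visit_b = v[k + 1]
        )[rep(1, nrow(res$tests)), ],
        res$tests
      )
      tests[[length(tests) + 1]] <- res$tests
      summaries[[length(summaries) + 1]] <- res$summary
    }
  }
  list(
    tests = dplyr::bind_rows(tests),
    summaries = dplyr::bind_rows(summaries)
  )
}
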
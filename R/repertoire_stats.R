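# Formula-defined repertoire summary statistics: richness, entropy,
# evenness, clonality and Morisita-Horn overlap.

.check_stats_ready <- function(sample, arg = "sample") {
  stopifnot(inherits(sample, "repertoire_sample"))
  if (!sample$productive_only) {
    abort(sprintf("`%s` must be productive-filtered first (see filter_productive())", arg))
  }
  if (is_empty_sample(sample)) {
    abort(sprintf("`%s` is empty; repertoire statistics are undefined", arg))
  }
  invisible(sample)
}

#' Clonotype frequency vector
#'
#' Template counts normalized to frequencies (summing to one), named by
#' clonotype key.
#'
#' @param sample A productive-filtered, non-empty `repertoire_sample`.
#' @return Named numeric vector of frequencies.
#' @export
frequency_vector <- function(sample) {
  .check_stats_ready(sample)
  counts <- sample$clonotypes$template_count
  setNames(counts / sum(counts), sample$clonotypes$rearrangement_id)
}

#' Repertoire diversity and clonality
#'
#' Shannon entropy `H = -sum f_i log f_i` (natural log), Pielou evenness
#' `J = H / log(R)` for richness `R >= 2`, and clonality `C = 1 - J`
#' clamped to `[0, 1]`. A monoclonal repertoire (`R = 1`) is fully
#' concentrated: `J` is defined as 0 and `C = 1`, with a warning. The base
#' of the logarithm cancels in `J`, so natural log is used throughout.
#'
#' @param sample A productive-filtered, non-empty `repertoire_sample`.
#' @return One-row tibble with columns `richness`, `entropy`, `evenness`,
#'   `clonality`.
#' @export
clonality <- function(sample) {
  .check_stats_ready(sample)
  f <- frequency_vector(sample)
  f <- f[f > 0]
  r <- length(f)
  h <- -sum(f * log(f))
  if (r == 1L) {
    warn("monoclonal repertoire (richness 1): clonality set to 1")
    j <- 0
  } else {
    j <- h / log(r)
  }
  tibble(
    richness = r,
    entropy = h,
    evenness = j,
    clonality = min(max(1 - j, 0), 1)
  )
}

#' Morisita-Horn overlap between two repertoires
#'
#' Abundance-weighted similarity over the union of clonotype keys:
#' `MH = 2 sum(p_i q_i) / (sum(p_i^2) + sum(q_i^2))` on template
#' frequencies, most sensitive to the dominant clones. 1 for identical
#' frequency distributions, 0 for disjoint clonotype sets.
#'
#' @param a,b Productive-filtered, non-empty `repertoire_sample` objects.
#' @return One-row tibble with columns `morisita_horn` and
#'   `shared_clonotypes`.
#' @export
morisita_horn <- function(a, b) {
  .check_stats_ready(a, "a")
  .check_stats_ready(b, "b")
  p <- frequency_vector(a)
  q <- frequency_vector(b)
  keys <- union(names(p), names(q))
  pu <- setNames(numeric(length(keys)), keys)
  qu <- pu
  pu[names(p)] <- p
  qu[names(q)] <- q
  tibble(
    morisita_horn = 2 * sum(pu * qu) / (sum(pu^2) + sum(qu^2)),
    shared_clonotypes = sum(pu > 0 & qu > 0)
  )
}

#' Diversity table for a set of longitudinal repertoires
#'
#' @param repertoires List of `longitudinal_repertoire` objects (samples
#'   must already be productive-filtered).
#' @return Tibble with one row per patient-visit: `patient_id`, `visit`,
#'   `richness`, `entropy`, `evenness`, `clonality`, `total_templates`.
#' @export
repertoire_diversity <- function(repertoires) {
  rows <- lapply(repertoires, function(rep) {
    dplyr::bind_rows(lapply(rep$samples, function(s) {
      dplyr::bind_cols(
        tibble(patient_id = s$patient_id, visit = s$visit),
        clonality(s),
        tibble(total_templates = s$total_templates)
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Within-patient visit-pair overlap table
#'
#' Morisita-Horn overlap for consecutive visit pairs (or all pairs) within
#' each patient's longitudinal repertoire.
#'
#' @param repertoires List of `longitudinal_repertoire` objects.
#' @param pairs `"consecutive"` (default) or `"all"`.
#' @return Tibble with `patient_id`, `visit_a`, `visit_b`,
#'   `morisita_horn`, `shared_clonotypes`.
#' @export
repertoire_overlap <- function(repertoires, pairs = c("consecutive", "all")) {
  pairs <- match.arg(pairs)
  rows <- lapply(repertoires, function(rep) {
    v <- names(rep$samples)
    if (length(v) < 2) return(NULL)
    idx <- if (pairs == "consecutive") {
      cbind(seq_len(length(v) - 1), seq_len(length(v) - 1) + 1)
    } else {
      t(utils::combn(length(v), 2))
    }
    dplyr::bind_rows(lapply(seq_len(nrow(idx)), function(k) {
      a <- rep$samples[[idx[k, 1]]]
      b <- rep$samples[[idx[k, 2]]]
      dplyr::bind_cols(
        tibble(patient_id = rep$patient_id, visit_a = a$visit, visit_b = b$visit),
        morisita_horn(a, b)
      )
    }))
  })
  dplyr::bind_rows(rows)
}
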
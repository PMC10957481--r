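# Parsing, validation and filtering of clonotype tables, and assembly of
# per-patient longitudinal repertoires.

# Column layouts for the two supported table dialects. `frame` is optional in
# both: when absent, productivity is derived from the amino-acid junction.
.dialect_columns <- list(
  airr = c(
    nt = "junction", aa = "junction_aa", v = "v_call", j = "j_call",
    count = "duplicate_count", frame = "productive"
  ),
  immunoseq = c(
    nt = "rearrangement", aa = "amino_acid", v = "v_gene", j = "j_gene",
    count = "templates", frame = "frame_type"
  )
)

#' Default blood-draw visit schedule
#'
#' Visit codes for the pre-treatment and on-treatment blood collections:
#' cycle 0 day 1 (baseline), cycle 1 day 1 (after the lead-in week) and
#' cycle 1 day 22.
#'
#' @return Character vector of visit codes in schedule order.
#' @export
default_visit_schedule <- function() c("C0D1", "C1D1", "C1D22")

#' Construct a repertoire sample from clonotype counts
#'
#' Convenience constructor used by the simulators and tests. Builds an
#' in-frame (productive) clonotype table from a vector of template counts.
#'
#' @param patient_id Patient identifier.
#' @param visit Visit code (see [default_visit_schedule()]).
#' @param template_counts Non-negative integer vector of template counts,
#'   one per clonotype. Zero-count clones are dropped.
#' @param rearrangement_id Optional clonotype keys; defaults to
#'   `clone_0001`, `clone_0002`, ...
#' @param productive Whether the sample should be marked as already
#'   productive-filtered (default `TRUE`; counts are assumed in-frame).
#' @return A `repertoire_sample` object.
#' @export
repertoire_sample <- function(patient_id, visit, template_counts,
                              rearrangement_id = NULL, productive = TRUE) {
  if (any(template_counts < 0) || !all(is_whole_number(template_counts))) {
    abort("`template_counts` must be non-negative integers")
  }
  n <- length(template_counts)
  ids <- rearrangement_id %||% sprintf("clone_%04d", seq_len(n))
  if (anyDuplicated(ids)) abort("`rearrangement_id` must be unique")
  keep <- template_counts > 0
  clonotypes <- tibble(
    rearrangement_id = as.character(ids)[keep],
    cdr3_nt = as.character(ids)[keep],
    cdr3_aa = as.character(ids)[keep],
    v_call = "TRBV0-0",
    j_call = "TRBJ0-0",
    template_count = as.integer(round(template_counts[keep])),
    frame_status = "in-frame"
  )
  new_repertoire_sample(patient_id, visit, clonotypes, productive = productive)
}

new_repertoire_sample <- function(patient_id, visit, clonotypes,
                                  productive = FALSE) {
  if (anyDuplicated(clonotypes$rearrangement_id)) {
    abort("duplicate rearrangement_id within a sample")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      visit = as.character(visit),
      clonotypes = clonotypes,
      total_templates = sum(clonotypes$template_count),
      productive_only = isTRUE(productive)
    ),
    class = "repertoire_sample"
  )
}

#' Is a repertoire sample empty?
#'
#' A sample is empty when it has no clonotypes (for example after productive
#' filtering removed everything). Downstream statistics refuse empty samples.
#'
#' @param sample A `repertoire_sample`.
#' @return Logical scalar.
#' @export
is_empty_sample <- function(sample) {
  nrow(sample$clonotypes) == 0L || sample$total_templates == 0L
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "<repertoire_sample> patient %s, visit %s: %d clonotypes, %d templates%s\n",
    x$patient_id, x$visit, nrow(x$clonotypes), x$total_templates,
    if (x$productive_only) " (productive only)" else ""
  ))
  invisible(x)
}

#' Read a clonotype table
#'
#' Parses an AIRR Rearrangement TSV or an immunoSEQ-style TSV into a
#' [repertoire_sample()]. Rows sharing a clonotype key are merged by summing
#' their template counts.
#'
#' @param path Path to a tab-separated clonotype table.
#' @param dialect `"airr"` (columns `junction`, `junction_aa`, `v_call`,
#'   `j_call`, `duplicate_count`, optional `productive`) or `"immunoseq"`
#'   (columns `rearrangement`/`nucleotide`, `amino_acid`, `v_gene`, `j_gene`,
#'   `templates`, optional `frame_type`).
#' @param patient_id,visit Sample annotations; when `NULL` they are taken
#'   from optional `patient_id`/`visit` columns if present.
#' @param id_key Clonotype identity: `"nt_vj"` (CDR3 nucleotide + V call +
#'   J call, the default) or `"nt"` (nucleotide sequence only).
#' @param column_map Optional named character vector overriding the
#'   dialect's column names (names among `nt`, `aa`, `v`, `j`, `count`,
#'   `frame`).
#' @return A `repertoire_sample` (not yet productive-filtered).
#' @seealso [filter_productive()], [assemble_longitudinal()]
#' @export
read_clonotype_table <- function(path, dialect = c("airr", "immunoseq"),
                                 patient_id = NULL, visit = NULL,
                                 id_key = c("nt_vj", "nt"),
                                 column_map = NULL) {
  dialect <- match.arg(dialect)
  id_key <- match.arg(id_key)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cols <- .dialect_columns[[dialect]]
  if (!is.null(column_map)) cols[names(column_map)] <- column_map

  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (dialect == "immunoseq" && !cols[["nt"]] %in% names(raw) &&
      "nucleotide" %in% names(raw)) {
    cols[["nt"]] <- "nucleotide"
  }
  required <- cols[c("nt", "aa", "v", "j", "count")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing)) {
    abort(sprintf(
      "format error in %s: missing required column(s) %s",
      path, paste(missing, collapse = ", ")
    ))
  }

  count_chr <- raw[[cols[["count"]]]]
  count <- suppressWarnings(as.numeric(count_chr))
  if (anyNA(count)) {
    abort(sprintf(
      "validation error in %s: non-numeric template count at row %d",
      path, which(is.na(count))[1]
    ))
  }
  if (any(count < 0)) {
    abort(sprintf(
      "validation error in %s: negative template count at row %d",
      path, which(count < 0)[1]
    ))
  }
  if (!all(is_whole_number(count))) {
    abort(sprintf(
      "validation error in %s: fractional template count at row %d",
      path, which(!is_whole_number(count))[1]
    ))
  }

  nt <- raw[[cols[["nt"]]]]
  aa <- raw[[cols[["aa"]]]]
  aa[is.na(aa)] <- ""
  frame_status <- .frame_status(raw, cols, dialect, nt, aa)

  key <- switch(id_key,
    nt = nt,
    nt_vj = paste(nt, raw[[cols[["v"]]]], raw[[cols[["j"]]]], sep = "|")
  )
  tab <- tibble(
    rearrangement_id = key,
    cdr3_nt = nt,
    cdr3_aa = aa,
    v_call = raw[[cols[["v"]]]],
    j_call = raw[[cols[["j"]]]],
    template_count = as.integer(round(count)),
    frame_status = frame_status
  )
  # merge rows sharing a clonotype key by summing templates
  tab <- dplyr::summarise(
    dplyr::group_by(tab, .data$rearrangement_id),
    cdr3_nt = .data$cdr3_nt[1], cdr3_aa = .data$cdr3_aa[1],
    v_call = .data$v_call[1], j_call = .data$j_call[1],
    template_count = sum(.data$template_count),
    frame_status = .data$frame_status[1],
    .groups = "drop"
  )

  pid <- patient_id %||%
    (if ("patient_id" %in% names(raw)) raw$patient_id[1] else NA_character_)
  vis <- visit %||%
    (if ("visit" %in% names(raw)) raw$visit[1] else NA_character_)
  new_repertoire_sample(pid, vis, tab, productive = FALSE)
}

# Productivity call: trust the table's frame/productive column when present,
# otherwise derive from the amino-acid junction (non-empty, no stop, and a
# nucleotide length divisible by three for the in-frame call).
.frame_status <- function(raw, cols, dialect, nt, aa) {
  frame_col <- cols[["frame"]]
  if (!is.na(frame_col) && frame_col %in% names(raw)) {
    val <- raw[[frame_col]]
    if (dialect == "airr") {
      prod <- tolower(val) %in% c("t", "true", "1", "yes")
      status <- ifelse(prod, "in-frame",
        ifelse(grepl("\\*", aa), "has-stop", "out-of-frame")
      )
      status[is.na(val)] <- .derive_frame(nt[is.na(val)], aa[is.na(val)])
      return(status)
    }
    low <- tolower(substr(val, 1, 2))
    status <- rep("out-of-frame", length(val))
    status[low == "in"] <- "in-frame"
    status[low == "st"] <- "has-stop"
    status[is.na(val)] <- .derive_frame(nt[is.na(val)], aa[is.na(val)])
    return(status)
  }
  .derive_frame(nt, aa)
}

.derive_frame <- function(nt, aa) {
  ifelse(
    grepl("\\*", aa), "has-stop",
    ifelse(nzchar(aa) & nchar(nt) %% 3 == 0, "in-frame", "out-of-frame")
  )
}

#' Write a repertoire sample as an AIRR Rearrangement TSV
#'
#' @param sample A `repertoire_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(sample, path) {
  tab <- tibble(
    sequence_id = sample$clonotypes$rearrangement_id,
    junction = sample$clonotypes$cdr3_nt,
    junction_aa = sample$clonotypes$cdr3_aa,
    v_call = sample$clonotypes$v_call,
    j_call = sample$clonotypes$j_call,
    productive = ifelse(sample$clonotypes$frame_status == "in-frame", "T", "F"),
    duplicate_count = sample$clonotypes$template_count,
    patient_id = sample$patient_id,
    visit = sample$visit
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Keep only productive clonotypes
#'
#' Retains exactly the in-frame clonotypes whose CDR3 amino-acid sequence
#' contains no stop symbol, and recomputes the template total. Only
#' productive sequences enter any downstream repertoire statistic.
#'
#' @param sample A `repertoire_sample`.
#' @return A productive-only `repertoire_sample`; if every clonotype is
#'   removed the sample is empty (see [is_empty_sample()]) and a warning is
#'   raised.
#' @export
filter_productive <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  keep <- sample$clonotypes$frame_status == "in-frame" &
    nzchar(sample$clonotypes$cdr3_aa) &
    !grepl("\\*", sample$clonotypes$cdr3_aa)
  out <- new_repertoire_sample(
    sample$patient_id, sample$visit,
    sample$clonotypes[keep, , drop = FALSE],
    productive = TRUE
  )
  if (is_empty_sample(out)) {
    warn(sprintf(
      "no productive clonotypes remain for patient %s visit %s",
      sample$patient_id, sample$visit
    ))
  }
  out
}

#' Assemble per-patient longitudinal repertoires
#'
#' Groups repertoire samples by patient and orders them by the visit
#' schedule. Patients with fewer than two visits are retained but marked
#' unpaired; duplicate (patient, visit) combinations are an error.
#'
#' @param samples List of `repertoire_sample` objects.
#' @param schedule Ordered character vector of visit codes; every sample's
#'   visit must appear in it.
#' @return Named list of `longitudinal_repertoire` objects (one per
#'   patient), each with fields `patient_id`, `samples` (named by visit, in
#'   schedule order) and `unpaired`.
#' @export
assemble_longitudinal <- function(samples, schedule = default_visit_schedule()) {
  stopifnot(length(samples) > 0)
  visits <- vapply(samples, function(s) s$visit, character(1))
  patients <- vapply(samples, function(s) s$patient_id, character(1))
  bad <- !visits %in% schedule
  if (any(bad)) {
    abort(sprintf(
      "visit(s) not in schedule: %s",
      paste(unique(visits[bad]), collapse = ", ")
    ))
  }
  key <- paste(patients, visits)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf(
      "conflict: multiple samples for patient/visit %s (sources %s)",
      dup, paste(which(key == dup), collapse = " and ")
    ))
  }
  out <- lapply(unique(patients), function(p) {
    idx <- which(patients == p)
    idx <- idx[order(match(visits[idx], schedule))]
    smp <- setNames(samples[idx], visits[idx])
    structure(
      list(patient_id = p, samples = smp, unpaired = length(smp) < 2L),
      class = "longitudinal_repertoire"
    )
  })
  setNames(out, unique(patients))
}

#' @export
print.longitudinal_repertoire <- function(x, ...) {
  cat(sprintf(
    "<longitudinal_repertoire> patient %s: visits %s%s\n",
    x$patient_id, paste(names(x$samples), collapse = ", "),
    if (x$unpaired) " [unpaired]" else ""
  ))
  invisible(x)
}
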
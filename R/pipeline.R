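# End-to-end orchestration: validated run configuration, stage execution
# (io -> stats -> dynamics -> scoring -> outcomes), versioned TSV outputs,
# a JSON summary and a parameter log.

.default_thresholds <- function() {
  list(
    alpha = 0.01,            # FDR threshold on adjusted clone p-values
    read_threshold = 5,      # newly-detected read threshold (strictly above)
    resistance_cutoff_weeks = 24,
    tmb_cutoff = 10,
    pdl1_cutoff = 1,
    ci_level = 0.80,
    ssgsea_alpha = 0.25
  )
}

#' Validate a pipeline run configuration
#'
#' @param config List (or path to a YAML file) with optional sections
#'   `repertoire` (`manifest`, `schedule`), `expression` (`matrix`,
#'   `groups`, optional `signature_file`/`signature`), `clinical`
#'   (`patients`, `assessments`, `landmarks`), plus `out_dir`, `seed` and
#'   a `thresholds` block overriding [.default_thresholds()] entries.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  config$thresholds <- modifyList(.default_thresholds(),
                                  config$thresholds %||% list())
  th <- config$thresholds
  if (th$alpha <= 0 || th$alpha >= 1) abort("alpha must lie in (0, 1)")
  if (th$read_threshold < 0) abort("read_threshold must be non-negative")
  if (th$ci_level <= 0 || th$ci_level >= 1) abort("ci_level must lie in (0, 1)")
  for (sec in c("repertoire", "expression", "clinical")) {
    for (f in intersect(names(config[[sec]]),
                        c("manifest", "matrix", "groups", "signature_file",
                          "patients", "assessments"))) {
      if (!file.exists(config[[sec]][[f]])) {
        abort(sprintf("%s file not found: %s", sec, config[[sec]][[f]]))
      }
    }
  }
  config
}

.read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tab[, -1])
  rownames(mat) <- tab[[1]]
  mat
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which the configuration provides inputs and
#' writes one TSV per result table, a `summary.json` and a `run_log.txt`
#' recording every threshold used, into `out_dir`. Re-running with an
#' identical configuration and inputs reproduces the tables byte for
#' byte.
#'
#' @param config See [validate_config()].
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  th <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list(thresholds = th)
  log_lines <- c(
    "tcelldyn pipeline run",
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("thresholds: %s",
            paste(sprintf("%s=%s", names(th), unlist(th)), collapse = ", "))
  )
  emit <- function(tab, name) {
    readr::write_tsv(tab, file.path(out, name), progress = FALSE)
    log_lines <<- c(log_lines, sprintf("wrote %s (%d rows)", name, nrow(tab)))
  }

  if (!is.null(config$repertoire)) {
    rc <- config$repertoire
    schedule <- rc$schedule %||% default_visit_schedule()
    manifest <- readr::read_tsv(rc$manifest, show_col_types = FALSE,
                                progress = FALSE)
    samples <- lapply(seq_len(nrow(manifest)), function(i) {
      filter_productive(read_clonotype_table(
        manifest$path[i], dialect = manifest$dialect[i] %||% "airr",
        patient_id = manifest$patient_id[i], visit = manifest$visit[i]
      ))
    })
    samples <- samples[!vapply(samples, is_empty_sample, logical(1))]
    reps <- assemble_longitudinal(samples, schedule)

    diversity <- repertoire_diversity(reps)
    overlap <- repertoire_overlap(reps)
    dyn <- cohort_dynamics(reps, alpha = th$alpha,
                           read_threshold = th$read_threshold)
    clon <- diversity[, c("patient_id", "visit", "clonality")]
    names(clon)[3] <- "value"
    pairs <- lapply(seq_len(length(schedule) - 1),
                    function(k) schedule[k:(k + 1)])
    comparisons <- cohort_visit_comparison(clon, pairs)

    emit(diversity, "repertoire_diversity.tsv")
    emit(overlap, "repertoire_overlap.tsv")
    emit(dyn$tests, "clone_tests.tsv")
    emit(dyn$summaries, "dynamics_summary.tsv")
    if (nrow(comparisons)) {
      emit(comparisons[, setdiff(names(comparisons), "deltas")],
           "cohort_comparisons.tsv")
    }
    summary$repertoire <- list(
      n_patients = length(reps),
      n_samples = nrow(diversity),
      median_clonality_by_visit = as.list(tapply(
        diversity$clonality, diversity$visit, median
      )[schedule[schedule %in% diversity$visit]]),
      total_expanded = sum(dyn$summaries$n_expanded),
      total_newly_detected = sum(dyn$summaries$n_newly_detected_expanded),
      clonality_comparisons = if (nrow(comparisons)) {
        lapply(seq_len(nrow(comparisons)), function(i) list(
          visits = c(comparisons$visit_a[i], comparisons$visit_b[i]),
          n_pairs = comparisons$n_pairs[i],
          p_value = comparisons$p_value[i],
          q_value = comparisons$q_value[i]
        ))
      } else list()
    )
  }

  if (!is.null(config$expression)) {
    ec <- config$expression
    mat <- .read_expression_tsv(ec$matrix)
    sig <- if (!is.null(ec$signature_file)) {
      sets <- read_gene_sets(ec$signature_file)
      sets[[ec$signature %||% names(sets)[1]]]
    } else {
      tis_signature()
    }
    scores <- ssgsea_scores(mat, sig, alpha = th$ssgsea_alpha,
                            normalize = !isFALSE(ec$normalize))
    emit(scores, "signature_scores.tsv")
    comp_rows <- NULL
    if (!is.null(ec$groups)) {
      groups <- readr::read_tsv(ec$groups, show_col_types = FALSE,
                                progress = FALSE)
      comp_rows <- dplyr::bind_rows(lapply(
        setdiff(names(groups), "sample_id"),
        function(col) {
          labs <- setNames(as.character(groups[[col]]), groups$sample_id)
          labs <- labs[!is.na(labs)]
          res <- compare_groups(scores[scores$sample_id %in% names(labs), ],
                                labs)
          dplyr::bind_cols(tibble(grouping = col), res)
        }
      ))
      emit(comp_rows, "group_comparisons.tsv")
    }
    summary$expression <- list(
      signature = sig$name,
      n_samples = nrow(scores),
      group_comparisons = if (!is.null(comp_rows)) {
        lapply(seq_len(nrow(comp_rows)), function(i) list(
          grouping = comp_rows$grouping[i],
          p_value = comp_rows$p_value[i]
        ))
      } else list()
    )
  }

  if (!is.null(config$clinical)) {
    cc <- config$clinical
    patients <- readr::read_csv(cc$patients, show_col_types = FALSE,
                                progress = FALSE)
    assessments <- readr::read_csv(cc$assessments, show_col_types = FALSE,
                                   progress = FALSE)
    landmarks <- cc$landmarks %||% c(12, 24)
    modules <- unique(patients$module)
    rate_rows <- list()
    surv_rows <- list()
    km_list <- list()
    for (m in modules) {
      pm <- patients[patients$module == m, , drop = FALSE]
      am <- assessments[assessments$patient_id %in% pm$patient_id, ,
                        drop = FALSE]
      orr <- compute_orr(pm, am)
      dcrs <- lapply(landmarks, function(lw) compute_dcr(pm, am, lw))
      surv <- derive_survival(pm, am)
      km_pfs <- km_estimate(surv$pfs_time, surv$pfs_event, th$ci_level)
      km_os <- km_estimate(surv$os_time, surv$os_event, th$ci_level)
      rate_rows[[m]] <- tibble(
        module = m, n = nrow(pm),
        orr_pct = orr$pct, orr_n = orr$numerator,
        dcr12_pct = dcrs[[1]]$pct,
        dcr24_pct = if (length(dcrs) > 1) dcrs[[2]]$pct else NA_real_,
        median_pfs_weeks = km_pfs$median,
        pfs_ci_lo = km_pfs$median_ci[1], pfs_ci_hi = km_pfs$median_ci[2],
        median_os_weeks = km_os$median,
        os_ci_lo = km_os$median_ci[1], os_ci_hi = km_os$median_ci[2]
      )
      surv_rows[[m]] <- surv
      km_list[[m]] <- list(pfs = km_pfs, os = km_os)
    }
    rates <- dplyr::bind_rows(rate_rows)
    emit(rates, "module_outcomes.tsv")
    emit(dplyr::bind_rows(surv_rows), "survival_times.tsv")
    summary$clinical <- list(
      ci_level = th$ci_level,
      modules = lapply(seq_len(nrow(rates)), function(i) as.list(rates[i, ]))
    )
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(summary)
}

#' Write a complete simulated study input set
#'
#' Generates all three input classes at the study's scale (62 patients
#' with longitudinal TCR profiling, 48 expression samples, the four
#' treatment arms of the clinical cohort), writes them in the interchange
#' formats the pipeline reads (AIRR TSVs plus manifest, expression and
#' group TSVs, clinical CSVs), a ground-truth JSON and a ready-to-run
#' `config.yaml`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Mandatory RNG seed; stage seeds are derived from it.
#' @param n_patients_repertoire,n_clones,depth Repertoire scale.
#' @param n_per_group Expression samples per subgroup.
#' @param expression_effect Signature shift between subgroups (SD units).
#' @param arms Clinical arm table (default [default_trial_arms()]).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
simulate_study_inputs <- function(dir, seed,
                                  n_patients_repertoire = 62,
                                  n_clones = 1000, depth = 10000,
                                  n_per_group = 24,
                                  expression_effect = 1,
                                  arms = default_trial_arms()) {
  dir.create(file.path(dir, "repertoire"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(seed)

  # modest on-treatment expansions so the dynamics stage has signal
  events <- tibble(
    clone = c(50L, NA), visit = c("C1D22", "C1D22"),
    fold = c(8, NA), target_freq = c(NA, 0.01)
  )
  sim_rep <- simulate_longitudinal_repertoires(
    n_patients = n_patients_repertoire, n_clones = n_clones, depth = depth,
    expansion_events = events, seed = seed + 1L
  )
  manifest <- list()
  for (rep in sim_rep$repertoires) {
    for (s in rep$samples) {
      fn <- sprintf("%s_%s.tsv", s$patient_id, s$visit)
      write_clonotype_table(s, file.path(dir, "repertoire", fn))
      manifest[[length(manifest) + 1]] <- tibble(
        path = file.path(dir, "repertoire", fn), dialect = "airr",
        patient_id = s$patient_id, visit = s$visit
      )
    }
  }
  readr::write_tsv(dplyr::bind_rows(manifest),
                   file.path(dir, "manifest.tsv"), progress = FALSE)

  sim_expr <- simulate_expression_cohort(
    n_per_group = n_per_group, effect_size = expression_effect,
    seed = seed + 2L
  )
  expr_tab <- dplyr::bind_cols(
    tibble(gene = rownames(sim_expr$matrix)),
    as_tibble(sim_expr$matrix)
  )
  readr::write_tsv(expr_tab, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble(sample_id = names(sim_expr$labels),
           resistance = ifelse(sim_expr$labels == "group_1",
                               "primary", "acquired")),
    file.path(dir, "groups.tsv"), progress = FALSE
  )

  sim_clin <- simulate_clinical_cohort(arms = arms, seed = seed + 3L)
  readr::write_csv(sim_clin$patients, file.path(dir, "patients.csv"),
                   progress = FALSE)
  readr::write_csv(sim_clin$assessments, file.path(dir, "assessments.csv"),
                   progress = FALSE)

  jsonlite::write_json(
    list(
      repertoire = sim_rep$truth,
      expression = sim_expr$truth,
      clinical = sim_clin$truth$patients
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )

  config <- list(
    seed = seed,
    out_dir = file.path(dir, "results"),
    repertoire = list(manifest = file.path(dir, "manifest.tsv"),
                      schedule = default_visit_schedule()),
    expression = list(matrix = file.path(dir, "expression.tsv"),
                      groups = file.path(dir, "groups.tsv")),
    clinical = list(patients = file.path(dir, "patients.csv"),
                    assessments = file.path(dir, "assessments.csv"),
                    landmarks = c(12, 24))
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
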
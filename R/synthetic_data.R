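# Seeded generators for the three input classes (clonotype tables,
# expression cohorts, clinical cohorts) with ground-truth labels, so every
# pipeline stage is testable without external data. All generators are
# pure functions of their arguments plus an explicit seed; global RNG
# state is left untouched.

# Random productive CDR3s: codons drawn from the non-stop part of the
# standard genetic code, framed by the canonical C...F motif.
.random_cdr3 <- function(n, min_codons = 10, max_codons = 16) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa_of <- unname(gc[codons])
  lens <- sample(min_codons:max_codons, n, replace = TRUE)
  nt <- character(n)
  aa <- character(n)
  for (i in seq_len(n)) {
    pick <- sample(length(codons), lens[i], replace = TRUE)
    nt[i] <- paste0("TGT", paste(codons[pick], collapse = ""), "TTT")
    aa[i] <- paste0("C", paste(aa_of[pick], collapse = ""), "F")
  }
  list(nt = nt, aa = aa)
}

#' Simulate longitudinal TCR repertoires with known expansions
#'
#' Per patient, latent clone frequencies are drawn from the abundance
#' model (power law over abundance rank, or log-normal); at each visit,
#' observed template counts are a multinomial draw of `depth` templates
#' from the (possibly perturbed) latent frequencies. Expansion events
#' modify the latent frequencies before sampling — for an existing clone
#' the latent frequency is multiplied by `fold` and the vector
#' renormalized; a `"novel"` clone is injected at `target_freq` with the
#' rest scaled down — so sampling noise stays realistic. Every perturbed
#' clone is recorded in the ground truth.
#'
#' @param n_patients Number of patients.
#' @param n_clones Latent clones per patient (default 1000).
#' @param depth Templates per sample (default 10000).
#' @param visits Visit schedule (default [default_visit_schedule()]).
#' @param abundance_model `"power_law"` (frequency proportional to
#'   `rank^-exponent`) or `"log_normal"`.
#' @param exponent Power-law exponent (default 1).
#' @param sigma Log-normal sigma (default 1.5).
#' @param expansion_events `NULL`, or a data frame with columns `clone`
#'   (abundance-rank index, or `NA` for a novel clone), `visit`, `fold`
#'   (for existing clones) and `target_freq` (for novel clones). Events
#'   apply to every patient at the stated visit.
#' @param seed Mandatory RNG seed.
#' @return List with `repertoires` (named list of
#'   `longitudinal_repertoire`, samples productive) and `truth` (tibble of
#'   perturbed clones: `patient_id`, `visit`, `rearrangement_id`,
#'   `clone`, `latent_freq`).
#' @export
simulate_longitudinal_repertoires <- function(n_patients,
                                              n_clones = 1000,
                                              depth = 10000,
                                              visits = default_visit_schedule(),
                                              abundance_model = c("power_law", "log_normal"),
                                              exponent = 1,
                                              sigma = 1.5,
                                              expansion_events = NULL,
                                              seed) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_patients >= 1, n_clones >= 2, depth > 0)
  if (!is.null(expansion_events)) {
    stopifnot(all(c("clone", "visit") %in% names(expansion_events)))
    if (!all(expansion_events$visit %in% visits)) {
      abort("expansion event visit not in schedule")
    }
    fold <- expansion_events$fold %||% rep(NA_real_, nrow(expansion_events))
    if (any(!is.na(fold) & fold <= 1)) {
      abort("expansion fold-changes must exceed 1")
    }
  }

  with_seed(seed, {
    truth <- list()
    reps <- lapply(seq_len(n_patients), function(p) {
      pid <- sprintf("PT%03d", p)
      base <- switch(abundance_model,
        power_law = (seq_len(n_clones))^(-exponent),
        log_normal = sort(rlnorm(n_clones, 0, sigma), decreasing = TRUE)
      )
      base <- base / sum(base)
      seqs <- .random_cdr3(n_clones)
      v_call <- sprintf("TRBV%02d-1", sample(1:30, n_clones, replace = TRUE))
      j_call <- sprintf("TRBJ%d-%d", sample(1:2, n_clones, replace = TRUE),
                        sample(1:7, n_clones, replace = TRUE))
      ids <- paste(seqs$nt, v_call, j_call, sep = "|")

      samples <- lapply(visits, function(vis) {
        lat <- base
        lat_ids <- ids
        meta <- list(nt = seqs$nt, aa = seqs$aa, v = v_call, j = j_call)
        if (!is.null(expansion_events)) {
          ev <- expansion_events[expansion_events$visit == vis, , drop = FALSE]
          for (k in seq_len(nrow(ev))) {
            if (is.na(ev$clone[k])) {
              tf <- ev$target_freq[k]
              if (is.na(tf) || tf <= 0 || tf >= 1) {
                abort("novel-clone events need target_freq in (0, 1)")
              }
              nov <- .random_cdr3(1)
              nid <- paste(nov$nt, "TRBV99-1", "TRBJ9-9", sep = "|")
              lat <- c(lat * (1 - tf), tf)
              lat_ids <- c(lat_ids, nid)
              meta$nt <- c(meta$nt, nov$nt)
              meta$aa <- c(meta$aa, nov$aa)
              meta$v <- c(meta$v, "TRBV99-1")
              meta$j <- c(meta$j, "TRBJ9-9")
              truth[[length(truth) + 1]] <<- tibble(
                patient_id = pid, visit = vis, rearrangement_id = nid,
                clone = NA_integer_, latent_freq = tf
              )
            } else {
              i <- ev$clone[k]
              f_new <- lat[i] * ev$fold[k]
              if (f_new >= 1) abort("expansion pushes a latent frequency above 1")
              lat[i] <- f_new
              truth[[length(truth) + 1]] <<- tibble(
                patient_id = pid, visit = vis, rearrangement_id = lat_ids[i],
                clone = as.integer(i), latent_freq = f_new / sum(lat)
              )
            }
          }
          lat <- lat / sum(lat)
        }
        counts <- as.vector(rmultinom(1, depth, lat))
        obs <- counts > 0
        clonotypes <- tibble(
          rearrangement_id = lat_ids[obs],
          cdr3_nt = meta$nt[obs],
          cdr3_aa = meta$aa[obs],
          v_call = meta$v[obs],
          j_call = meta$j[obs],
          template_count = counts[obs],
          frame_status = "in-frame"
        )
        new_repertoire_sample(pid, vis, clonotypes, productive = TRUE)
      })
      structure(
        list(patient_id = pid,
             samples = setNames(samples, visits),
             unpaired = length(visits) < 2L),
        class = "longitudinal_repertoire"
      )
    })
    list(
      repertoires = setNames(reps, vapply(reps, `[[`, character(1), "patient_id")),
      truth = if (length(truth)) dplyr::bind_rows(truth) else
        tibble(patient_id = character(), visit = character(),
               rearrangement_id = character(), clone = integer(),
               latent_freq = numeric())
    )
  })
}

#' Simulate an expression cohort with a group-shifted signature
#'
#' Log-normal TPM background: per-gene mean log2 expression drawn once,
#' per-sample noise on the log2 scale, and the signature genes up-shifted
#' in group 2 by `effect_size` noise standard deviations.
#'
#' @param n_per_group Samples per group (default 20).
#' @param signature A [gene_signature()] (default [tis_signature()]).
#' @param effect_size Shift of signature genes in group 2, in units of
#'   the per-sample noise SD (default 0; must be non-negative).
#' @param n_background_genes Number of non-signature genes (default 500).
#' @param noise_sd Per-sample log2 noise SD (default 1).
#' @param seed Mandatory RNG seed.
#' @return List with `matrix` (TPM, genes x samples), `labels` (named
#'   vector, `group_1`/`group_2`) and `truth` (effect size and signature
#'   genes).
#' @export
simulate_expression_cohort <- function(n_per_group = 20,
                                       signature = tis_signature(),
                                       effect_size = 0,
                                       n_background_genes = 500,
                                       noise_sd = 1,
                                       seed) {
  stopifnot(inherits(signature, "gene_signature"), effect_size >= 0,
            n_per_group >= 1, n_background_genes >= 1)
  with_seed(seed, {
    genes <- c(signature$genes,
               sprintf("BG%04d", seq_len(n_background_genes)))
    n_samples <- 2 * n_per_group
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    labels <- setNames(rep(c("group_1", "group_2"), each = n_per_group),
                       sample_ids)
    mu <- rnorm(length(genes), mean = 5, sd = 2)
    log2_expr <- matrix(
      mu + rnorm(length(genes) * n_samples, 0, noise_sd),
      nrow = length(genes), dimnames = list(genes, sample_ids)
    )
    in_sig <- seq_along(signature$genes)
    log2_expr[in_sig, labels == "group_2"] <-
      log2_expr[in_sig, labels == "group_2"] + effect_size * noise_sd
    list(
      matrix = 2^log2_expr,
      labels = labels,
      truth = list(effect_size = effect_size,
                   signature_genes = signature$genes)
    )
  })
}

#' Default simulated trial arms
#'
#' Arm sizes, responder probabilities and median PFS/OS (converted from
#' months to weeks at 52/12 weeks per month) matching the reported
#' module-level results: the ATR-inhibitor combination (11/79 responders,
#' median PFS 5.8 and OS 17.4 months) and the three pooled comparator
#' combinations (4/87, 0/45 and 1/57 responders; pooled median PFS 2.7
#' and OS 9.4 months).
#'
#' @return Tibble with `module`, `n`, `responder_prob`,
#'   `median_pfs_weeks`, `median_os_weeks`.
#' @export
default_trial_arms <- function() {
  wk <- 52 / 12
  tibble(
    module = c("durvalumab_ceralasertib", "durvalumab_olaparib",
               "durvalumab_danvatirsen", "durvalumab_oleclumab"),
    n = c(79L, 87L, 45L, 57L),
    responder_prob = c(11 / 79, 4 / 87, 0, 1 / 57),
    median_pfs_weeks = c(5.8, 2.7, 2.7, 2.7) * wk,
    median_os_weeks = c(17.4, 9.4, 9.4, 9.4) * wk
  )
}

#' Simulate a clinical cohort with scheduled assessments
#'
#' Event times are exponential, calibrated so that the minimum of
#' progression and death has the stated median PFS and death alone the
#' stated median OS. Responders receive a partial response at the first
#' scheduled assessment, confirmed at the next; non-responders hold stable
#' disease until progression. Progression is recorded at the first
#' scheduled assessment on or after the latent progression time;
#' assessments follow the protocol imaging schedule and are independently
#' missed with probability `miss_prob`. Censoring is the minimum of an
#' exponential dropout time and the administrative follow-up cap.
#'
#' @param arms Tibble as from [default_trial_arms()]; `responder_prob`
#'   must lie in `[0, 1]` and medians must be positive with
#'   `median_pfs_weeks < median_os_weeks`.
#' @param censoring_rate Dropout hazard per week (default 0.002).
#' @param followup_cap_weeks Administrative cutoff (default 104).
#' @param miss_prob Probability that a scheduled visit is missed
#'   (default 0.03).
#' @param schedule Assessment weeks (default [assessment_schedule()]).
#' @param seed Mandatory RNG seed.
#' @return List with `patients` (one row per patient, including
#'   covariates, `death_week`, `last_alive_week`), `assessments`
#'   (`patient_id`, `week`, `category`, `confirmed`) and `truth`
#'   (per-patient latent times and responder flags, plus the arm table).
#' @export
simulate_clinical_cohort <- function(arms = default_trial_arms(),
                                     censoring_rate = 0.002,
                                     followup_cap_weeks = 104,
                                     miss_prob = 0.03,
                                     schedule = assessment_schedule(),
                                     seed) {
  stopifnot(all(arms$responder_prob >= 0 & arms$responder_prob <= 1))
  stopifnot(all(arms$median_pfs_weeks > 0),
            all(arms$median_os_weeks > arms$median_pfs_weeks))
  with_seed(seed, {
    patients <- list()
    assessments <- list()
    truth_rows <- list()
    pid_counter <- 0L
    for (r in seq_len(nrow(arms))) {
      lambda_death <- log(2) / arms$median_os_weeks[r]
      lambda_prog <- log(2) / arms$median_pfs_weeks[r] - lambda_death
      for (i in seq_len(arms$n[r])) {
        pid_counter <- pid_counter + 1L
        pid <- sprintf("CL%04d", pid_counter)
        responder <- rbinom(1, 1, arms$responder_prob[r]) == 1
        t_prog <- rexp(1, lambda_prog)
        t_death <- rexp(1, lambda_death)
        t_cens <- min(rexp(1, censoring_rate), followup_cap_weeks)

        rows <- list()
        for (w in schedule) {
          if (w > t_cens || w >= t_death) break
          if (runif(1) < miss_prob) next
          if (w >= t_prog) {
            rows[[length(rows) + 1]] <-
              tibble(patient_id = pid, week = w, category = "PD",
                     confirmed = FALSE)
            break
          }
          cat_w <- if (responder) "PR" else "SD"
          rows[[length(rows) + 1]] <-
            tibble(patient_id = pid, week = w, category = cat_w,
                   confirmed = FALSE)
        }
        a <- dplyr::bind_rows(rows)
        if (nrow(a)) {
          pr_idx <- which(a$category == "PR")
          if (length(pr_idx) > 1) a$confirmed[pr_idx[-1]] <- TRUE
        }
        death_observed <- t_death <= t_cens
        prior_week <- runif(1, 4, 60)
        patients[[pid_counter]] <- tibble(
          patient_id = pid,
          module = arms$module[r],
          cohort = classify_resistance(prior_week),
          prior_icb_progression_week = prior_week,
          pd_l1_tc_percent = 100 * stats::rbeta(1, 0.6, 1.2),
          tmb_mut_per_mb = rlnorm(1, log(8), 0.6),
          histology = sample(c("adenocarcinoma", "squamous"), 1,
                             prob = c(0.7, 0.3)),
          bone_liver_mets = rbinom(1, 1, 0.4) == 1,
          stk11_altered = rbinom(1, 1, 0.15) == 1,
          death_week = if (death_observed) t_death else NA_real_,
          last_alive_week = if (death_observed) t_death else t_cens
        )
        assessments[[pid_counter]] <- a
        truth_rows[[pid_counter]] <- tibble(
          patient_id = pid, module = arms$module[r],
          responder = responder, t_prog = t_prog,
          t_death = t_death, t_cens = t_cens
        )
      }
    }
    list(
      patients = dplyr::bind_rows(patients),
      assessments = dplyr::bind_rows(assessments),
      truth = list(arms = arms, patients = dplyr::bind_rows(truth_rows))
    )
  })
}
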
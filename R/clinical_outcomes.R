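# Classification rules and endpoint statistics: resistance / TMB / PD-L1
# classification, objective response and disease-control rates,
# progression-free survival with the protocol's missed-visit censoring
# rule, and Kaplan-Meier estimation with 80% confidence intervals.

#' Classify resistance to prior checkpoint blockade
#'
#' Progression within 24 weeks or less from the start of the prior
#' anti-PD-(L)1 therapy is primary resistance; progression after more than
#' 24 weeks is acquired resistance.
#'
#' @param progression_week Positive weeks from start of prior therapy to
#'   progression (vectorized).
#' @param cutoff_weeks Boundary (default 24; the boundary itself is
#'   primary).
#' @return Character vector, `"primary"` or `"acquired"`.
#' @export
classify_resistance <- function(progression_week, cutoff_weeks = 24) {
  if (any(progression_week <= 0, na.rm = TRUE)) {
    abort("progression week must be positive")
  }
  ifelse(progression_week <= cutoff_weeks, "primary", "acquired")
}

#' Classify tumor mutational burden
#'
#' @param mut_per_mb Non-negative mutations per megabase (vectorized).
#' @param cutoff High is `>= cutoff` (default 10).
#' @return `"high"` or `"low"`.
#' @export
classify_tmb <- function(mut_per_mb, cutoff = 10) {
  if (any(mut_per_mb < 0, na.rm = TRUE)) abort("TMB must be non-negative")
  ifelse(mut_per_mb >= cutoff, "high", "low")
}

#' Classify PD-L1 tumor-cell expression
#'
#' @param tc_percent Percentage of neoplastic cells staining positive, in
#'   `[0, 100]` (vectorized).
#' @param cutoff Positive is `>= cutoff` percent (default 1).
#' @return `"positive"` or `"negative"`.
#' @export
classify_pdl1 <- function(tc_percent, cutoff = 1) {
  if (any(tc_percent < 0 | tc_percent > 100, na.rm = TRUE)) {
    abort("PD-L1 TC percentage must lie in [0, 100]")
  }
  ifelse(tc_percent >= cutoff, "positive", "negative")
}

#' Scheduled tumor-assessment weeks
#'
#' Imaging every 6 weeks for the first 24 weeks from treatment start, then
#' every 8 weeks, each with a +/- `window` week visit window.
#'
#' @param max_week Last scheduled week generated (default 160).
#' @return Numeric vector of scheduled assessment weeks.
#' @export
assessment_schedule <- function(max_week = 160) {
  c(seq(6, 24, by = 6), seq(32, max_week, by = 8))
}

# Best overall response for one patient's assessments. Confirmation is
# required for CR/PR; stable disease requires a minimum duration from
# treatment start (default 6 weeks, the first scheduled assessment).
.best_overall_response <- function(assess, sd_min_week = 6) {
  assess <- assess[order(assess$week), , drop = FALSE]
  pd_week <- assess$week[assess$category == "PD"][1]
  pre <- assess[assess$category != "NE" &
                  (is.na(pd_week) | assess$week <= pd_week), , drop = FALSE]
  if (any(pre$category == "CR" & pre$confirmed, na.rm = TRUE)) return("CR")
  if (any(pre$category == "PR" & pre$confirmed, na.rm = TRUE)) return("PR")
  if (any(pre$category %in% c("CR", "PR", "SD") & pre$week >= sd_min_week)) {
    return("SD")
  }
  if (!is.na(pd_week)) return("PD")
  "NE"
}

#' Objective response rate
#'
#' Proportion of treated patients whose best overall response is a
#' confirmed complete or partial response. All treated patients count in
#' the denominator.
#'
#' @param patients Tibble with one row per treated patient (needs
#'   `patient_id`).
#' @param assessments Tibble with `patient_id`, `week`, `category`
#'   (`CR`/`PR`/`SD`/`PD`/`NE`), `confirmed` (logical).
#' @param sd_min_week Minimum week for stable disease to count as a best
#'   response of SD (default 6).
#' @return A `rate_result`: list with `numerator`, `denominator`,
#'   `proportion` and `pct` (percentage rounded to 0.1).
#' @export
compute_orr <- function(patients, assessments, sd_min_week = 6) {
  if (!nrow(patients)) abort("empty cohort")
  bor <- vapply(patients$patient_id, function(id) {
    a <- assessments[assessments$patient_id == id, , drop = FALSE]
    if (!nrow(a)) return("NE")
    .best_overall_response(a, sd_min_week)
  }, character(1))
  num <- sum(bor %in% c("CR", "PR"))
  rate_result(num, nrow(patients))
}

rate_result <- function(numerator, denominator) {
  structure(
    list(
      numerator = numerator, denominator = denominator,
      proportion = numerator / denominator,
      pct = round(100 * numerator / denominator, 1)
    ),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d)\n", x$pct, x$numerator, x$denominator))
  invisible(x)
}

#' Disease control rate at a landmark week
#'
#' A patient has disease control at the landmark when no progression and
#' no death has occurred by the landmark (within the assessment window)
#' and an evaluable CR/PR/SD assessment is available at or beyond the
#' landmark week (minus the window).
#'
#' @inheritParams compute_orr
#' @param landmark_week Landmark, 12 or 24 weeks.
#' @param window Assessment window in weeks (default 1).
#' @return A `rate_result`.
#' @export
compute_dcr <- function(patients, assessments, landmark_week = c(12, 24),
                        window = 1) {
  if (!nrow(patients)) abort("empty cohort")
  landmark_week <- match.arg(as.character(landmark_week[1]), c("12", "24"))
  lw <- as.numeric(landmark_week)
  controlled <- vapply(seq_len(nrow(patients)), function(i) {
    id <- patients$patient_id[i]
    a <- assessments[assessments$patient_id == id, , drop = FALSE]
    death <- patients$death_week[i] %||% NA_real_
    pd_week <- suppressWarnings(min(a$week[a$category == "PD"]))
    if (is.finite(pd_week) && pd_week <= lw + window) return(FALSE)
    if (!is.na(death) && death <= lw + window) return(FALSE)
    any(a$category %in% c("CR", "PR", "SD") & a$week >= lw - window)
  }, logical(1))
  rate_result(sum(controlled), nrow(patients))
}

#' Derive progression-free survival for one patient
#'
#' PFS is the time from treatment start to the first objective progression
#' or death from any cause. Patients with neither are censored at their
#' last evaluable assessment. The protocol's missed-visit rule applies: if
#' the event occurs after two or more consecutive missed scheduled visits
#' (no evaluable assessment within +/- `window` weeks of the scheduled
#' week) since the last evaluable assessment, the patient is instead
#' censored at that last evaluable assessment.
#'
#' @param assessments Tibble of one patient's assessments (`week`,
#'   `category`, `confirmed`).
#' @param death_week Week of death, or `NA`.
#' @param schedule Scheduled assessment weeks (see
#'   [assessment_schedule()]).
#' @param window Visit window in weeks (default 1).
#' @return One-row tibble with `time` (weeks) and `event` (1 progression
#'   or death, 0 censored). A patient with no assessments and no death is
#'   censored at time 0 with a warning.
#' @export
derive_pfs <- function(assessments, death_week = NA,
                       schedule = assessment_schedule(), window = 1) {
  a <- assessments[order(assessments$week), , drop = FALSE]
  eval_weeks <- a$week[a$category != "NE"]
  pd_week <- a$week[a$category == "PD"][1]
  event_week <- suppressWarnings(min(pd_week, death_week, na.rm = TRUE))
  if (!is.finite(event_week)) {
    if (!length(eval_weeks)) {
      warn("no assessments and no death: censored at time 0")
      return(tibble(time = 0, event = 0L))
    }
    return(tibble(time = max(eval_weeks), event = 0L))
  }
  prior_eval <- eval_weeks[eval_weeks < event_week]
  last_eval <- if (length(prior_eval)) max(prior_eval) else 0
  # scheduled visits due after the last evaluable assessment and before the
  # event, with no evaluable assessment inside their window
  due <- schedule[schedule > last_eval + window & schedule < event_week - window]
  missed <- vapply(due, function(w) {
    !any(eval_weeks >= w - window & eval_weeks <= w + window)
  }, logical(1))
  if (sum(missed) >= 2) {
    return(tibble(time = last_eval, event = 0L))
  }
  tibble(time = event_week, event = 1L)
}

#' Progression-free and overall survival for a cohort
#'
#' Applies [derive_pfs()] per patient and derives OS (time to death from
#' any cause; patients not known to have died are censored at the last
#' week known alive).
#'
#' @inheritParams compute_orr
#' @param schedule,window Passed to [derive_pfs()].
#' @return Tibble with `patient_id`, `pfs_time`, `pfs_event`, `os_time`,
#'   `os_event` (times in weeks).
#' @export
derive_survival <- function(patients, assessments,
                            schedule = assessment_schedule(), window = 1) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    id <- patients$patient_id[i]
    a <- assessments[assessments$patient_id == id, , drop = FALSE]
    death <- patients$death_week[i] %||% NA_real_
    pfs <- derive_pfs(a, death, schedule, window)
    os_event <- as.integer(!is.na(death))
    os_time <- if (os_event == 1L) death else patients$last_alive_week[i]
    tibble(
      patient_id = id,
      pfs_time = pfs$time, pfs_event = pfs$event,
      os_time = os_time, os_event = os_event
    )
  })
  dplyr::bind_rows(rows)
}

#' Kaplan-Meier estimate with median and confidence interval
#'
#' Product-limit estimator via [survival::survfit()] with Greenwood
#' pointwise variance on the log(-log) scale. The median is the smallest
#' observed event time with `S(t) <= 0.5` (step-function convention), and
#' its confidence interval is the Brookmeyer-Crowley construction: the
#' times at which the pointwise confidence bands first drop to 0.5.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 event, 0 censored).
#' @param ci_level Confidence level (default 0.80, as commonly reported
#'   for signal-finding cohorts; use 0.95 for conventional intervals).
#' @return A `survival_curve`: list with `time`, `surv`, `n_risk`,
#'   `lower`, `upper`, `median`, `median_ci`, `ci_level`, `n`. `median`
#'   is `NA` when the curve never reaches 0.5.
#' @export
km_estimate <- function(time, event, ci_level = 0.80) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) abort("times must be non-negative")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    conf.int = ci_level, conf.type = "log-log"
  )
  cross <- function(s) {
    i <- which(!is.na(s) & s <= 0.5 + 1e-12)
    if (length(i)) fit$time[i[1]] else NA_real_
  }
  structure(
    list(
      time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
      lower = fit$lower, upper = fit$upper,
      median = cross(fit$surv),
      # lower band crosses 0.5 first (lower bound), upper band last
      median_ci = c(cross(fit$lower), cross(fit$upper)),
      ci_level = ci_level, n = length(time), n_events = sum(event)
    ),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve> n = %d, events = %d; median = %s (%d%% CI %s-%s)\n",
    x$n, x$n_events,
    format(x$median, digits = 3), round(100 * x$ci_level),
    format(x$median_ci[1], digits = 3), format(x$median_ci[2], digits = 3)
  ))
  invisible(x)
}
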
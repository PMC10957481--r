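test_that("resistance, TMB and PD-L1 classifications honor their boundaries", {
  expect_equal(classify_resistance(24), "primary")   # within <= 24 weeks
  expect_equal(classify_resistance(24.1), "acquired") # after > 24 weeks
  expect_equal(classify_resistance(1), "primary")
  expect_error(classify_resistance(0), "positive")

  expect_equal(classify_tmb(10), "high")   # >= 10 mut/Mb
  expect_equal(classify_tmb(9.99), "low")
  expect_equal(classify_tmb(0), "low")
  expect_error(classify_tmb(-1), "non-negative")

  expect_equal(classify_pdl1(1), "positive") # >= 1% tumor cells
  expect_equal(classify_pdl1(0.5), "negative")
  expect_equal(classify_pdl1(100), "positive")
  expect_error(classify_pdl1(101), "\\[0, 100\\]")
})

# small helper to build a one-patient assessment table
assess <- function(weeks, cats, confirmed = FALSE, id = "P1") {
  tibble::tibble(patient_id = id, week = weeks, category = cats,
                 confirmed = rep_len(confirmed, length(weeks)))
}

test_that("ORR counts only confirmed responses over all treated patients", {
  patients <- tibble::tibble(patient_id = c("P1", "P2", "P3"),
                             death_week = NA_real_,
                             last_alive_week = 40)
  assessments <- dplyr::bind_rows(
    assess(c(6, 12), c("PR", "PR"), confirmed = c(FALSE, TRUE), id = "P1"),
    assess(c(6, 12), c("PR", "PD"), confirmed = FALSE, id = "P2"), # unconfirmed
    assess(c(6, 12), c("SD", "SD"), id = "P3")
  )
  orr <- compute_orr(patients, assessments)
  expect_equal(orr$numerator, 1)
  expect_equal(orr$denominator, 3)
  expect_equal(orr$pct, 33.3)

  none <- compute_orr(patients[3, ], assessments)
  expect_equal(none$pct, 0)
  expect_error(compute_orr(patients[0, ], assessments), "empty")
})

test_that("pooled ORR numerators are conserved under cohort partition", {
  sim <- simulate_clinical_cohort(seed = 77)
  pooled <- compute_orr(sim$patients, sim$assessments)
  per_module <- vapply(unique(sim$patients$module), function(m) {
    p <- sim$patients[sim$patients$module == m, ]
    compute_orr(p, sim$assessments)$numerator
  }, numeric(1))
  expect_equal(sum(per_module), pooled$numerator)
})

test_that("disease control requires holding through the landmark", {
  patients <- tibble::tibble(patient_id = c("A", "B"),
                             death_week = NA_real_, last_alive_week = 40)
  assessments <- dplyr::bind_rows(
    assess(6, "PD", id = "A"), # progressed at week 6
    assess(c(6, 12, 18, 24, 30), rep("SD", 5), id = "B") # held through 30
  )
  dcr12 <- compute_dcr(patients, assessments, 12)
  dcr24 <- compute_dcr(patients, assessments, 24)
  expect_equal(dcr12$numerator, 1)
  expect_equal(dcr24$numerator, 1)
  expect_equal(compute_dcr(patients[1, ], assessments, 12)$numerator, 0)
})

test_that("PFS applies the two-missed-visit censoring rule", {
  # progression at the first scheduled assessment: event at week 6
  expect_equal(
    derive_pfs(assess(6, "PD")),
    tibble::tibble(time = 6, event = 1L)
  )
  # no progression: censored at the last evaluable assessment
  expect_equal(
    derive_pfs(assess(c(6, 12, 20), c("SD", "SD", "SD"))),
    tibble::tibble(time = 20, event = 0L)
  )
  # PD at week 32 after missing ~weeks 18 and 24: censored back at week 12
  expect_equal(
    derive_pfs(assess(c(6, 12, 32), c("SD", "SD", "PD"))),
    tibble::tibble(time = 12, event = 0L)
  )
  # a single missed visit does not censor the event
  expect_equal(
    derive_pfs(assess(c(6, 12, 24), c("SD", "SD", "PD"))),
    tibble::tibble(time = 24, event = 1L)
  )
  # death with no assessments at all: event unless visits were missed
  expect_equal(derive_pfs(assess(numeric(0), character(0)), death_week = 4),
               tibble::tibble(time = 4, event = 1L))
  # nothing at all: censored at 0 with a warning
  expect_warning(
    res <- derive_pfs(assess(numeric(0), character(0))),
    "censored at time 0"
  )
  expect_equal(res$time, 0)
})

test_that("KM estimate matches hand computation and empirical limits", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2) # smallest event time with S <= 0.5

  # no events: flat curve, median undefined
  km0 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))

  # without censoring KM equals the empirical survivor function
  set.seed(12)
  t <- rexp(100, 0.2)
  km1 <- km_estimate(t, rep(1, 100))
  emp <- vapply(km1$time, function(u) mean(t > u), numeric(1))
  expect_equal(km1$surv, emp, tolerance = 1e-12)

  # censor times beyond the last event are irrelevant: shifting them later
  # leaves S at earlier times unchanged
  km2 <- km_estimate(c(t, max(t) + 1:5), c(rep(1, 100), rep(0, 5)))
  km3 <- km_estimate(c(t, max(t) + 101:105), c(rep(1, 100), rep(0, 5)))
  keep2 <- km2$time <= max(t)
  keep3 <- km3$time <= max(t)
  expect_equal(km2$surv[keep2], km3$surv[keep3], tolerance = 1e-12)
})

test_that("KM median recovers the exponential closed form at n = 2000", {
  set.seed(123)
  lambda <- log(2) / 6
  t <- rexp(2000, lambda)
  km <- km_estimate(t, rep(1, 2000))
  expect_equal(km$median, 6, tolerance = 0.12) # ~ Monte-Carlo error at n = 2000
  expect_lt(km$median_ci[1], km$median)
  expect_gt(km$median_ci[2], km$median)
})

test_that("cohort survival derivation is unbiased against generator truth", {
  sim <- simulate_clinical_cohort(
    arms = tibble::tibble(module = "arm", n = 400, responder_prob = 0.1,
                          median_pfs_weeks = 24, median_os_weeks = 70),
    miss_prob = 0, seed = 42
  )
  surv <- derive_survival(sim$patients, sim$assessments)
  km_os <- km_estimate(surv$os_time, surv$os_event)
  expect_equal(km_os$median, 70, tolerance = 0.12 * 70)

  # PFS events are read off the assessment grid, so compare the KM median
  # with the empirical median of the grid-discretized latent times
  truth <- sim$truth$patients
  grid <- c(assessment_schedule(1000))
  detect <- pmin(
    vapply(truth$t_prog, function(x) grid[grid >= x][1], numeric(1)),
    truth$t_death,
    na.rm = TRUE
  )
  km_pfs <- km_estimate(surv$pfs_time, surv$pfs_event)
  expect_equal(km_pfs$median, median(detect), tolerance = 0.15 * median(detect))
})
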
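# Build a response cohort with a known number of confirmed partial
# responders; the remaining patients hold stable disease then progress.
build_response_cohort <- function(n, responders, prefix = "P") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  patients <- tibble::tibble(
    patient_id = ids, death_week = NA_real_, last_alive_week = 30
  )
  assessments <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    if (i <= responders) {
      tibble::tibble(patient_id = ids[i], week = c(6, 12),
                     category = c("PR", "PR"), confirmed = c(FALSE, TRUE))
    } else {
      tibble::tibble(patient_id = ids[i], week = c(6, 12),
                     category = c("SD", "PD"), confirmed = FALSE)
    }
  }))
  list(patients = patients, assessments = assessments)
}
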
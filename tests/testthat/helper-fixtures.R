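# Shared fixture builders. MONDAY is a known Monday so weekday-dependent
# schedule tests are readable.
MONDAY <- as.POSIXct("2016-07-04 00:00:00", tz = "UTC")

make_readings <- function(days, sbp, dbp, patient_id = "p1", enrollment = MONDAY,
                          hour = 10) {
  n <- length(days)
  data.frame(patient_id = rep_len(patient_id, n),
             timestamp = enrollment + days * 86400 + hour * 3600,
             sbp = rep_len(sbp, n), dbp = rep_len(dbp, n),
             stringsAsFactors = FALSE)
}

make_cohort <- function(readings, patient_ids = unique(readings$patient_id),
                        enrollment = MONDAY, channel = "sms", prompts = NULL) {
  n <- length(patient_ids)
  structure(list(
    patients = data.frame(patient_id = patient_ids,
                          enrollment = rep(enrollment, length.out = n)[seq_len(n)],
                          channel = rep_len(channel, n),
                          stringsAsFactors = FALSE),
    prompts = prompts,
    readings = readings
  ), class = "cohort_dataset")
}

# A patient reporting the same value at every daily prompt for n_weeks.
constant_patient_readings <- function(sbp, dbp, patient_id = "p1",
                                      enrollment = MONDAY, n_weeks = 12) {
  make_readings(0:(n_weeks * 7 - 1), sbp, dbp, patient_id, enrollment)
}
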
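cfg <- threshold_config()

test_that("baseline is the mean of the first five responses within two weeks", {
  rd <- make_readings(0:4, 140, 90)
  bl <- compute_baseline(rd, MONDAY, cfg)
  expect_equal(bl$mean_sbp, 140)
  expect_equal(bl$mean_dbp, 90)
  expect_equal(bl$status, "complete")

  # four in the window plus three in week 3: later readings never contribute
  rd <- make_readings(c(0, 3, 6, 9, 15, 16, 17), 150, 95)
  bl <- compute_baseline(rd, MONDAY, cfg)
  expect_equal(bl$status, "insufficient")
  expect_equal(bl$n_used, 4)

  # seven in-window readings: exactly the first five by timestamp, checked
  # against an independent sort-then-slice oracle
  set.seed(7)
  days <- sort(sample(seq(0, 13.5, by = 0.5), 7))
  sbp <- sample(110:180, 7); dbp <- sample(60:100, 7)
  rd <- make_readings(days, sbp, dbp)
  bl <- compute_baseline(rd, MONDAY, cfg)
  ord <- order(as.numeric(rd$timestamp))
  first5 <- ord[1:5]
  expect_equal(bl$mean_sbp, sum(sbp[first5]) / 5)
  expect_equal(bl$mean_dbp, sum(dbp[first5]) / 5)
  expect_equal(bl$n_used, 5)
})

test_that("baseline rejects unordered input and handles empty input as insufficient", {
  expect_equal(compute_baseline(make_readings(numeric(0), numeric(0), numeric(0)),
                                MONDAY, cfg)$status, "insufficient")
  rd <- make_readings(c(3, 1, 2), 120, 80)
  expect_error(compute_baseline(rd, MONDAY, cfg), "chronological")
  expect_error(compute_baseline(make_readings(1, 120, 80), MONDAY + 2 * 86400, cfg),
               "before enrollment")
})

test_that("initial frequency uses inclusive 140/110 cuts", {
  bl <- function(s, d) data.frame(mean_sbp = s, mean_dbp = d, n_used = 5,
                                  status = "complete")
  expect_equal(initial_frequency(bl(140.0, 80.0), cfg), "daily")
  expect_equal(initial_frequency(bl(139.9, 109.9), cfg), "thrice_weekly")
  expect_equal(initial_frequency(bl(120.0, 110.0), cfg), "daily")
  insuff <- data.frame(mean_sbp = 150, mean_dbp = 90, n_used = 3,
                       status = "insufficient")
  expect_error(initial_frequency(insuff, cfg), "insufficient")
})

test_that("biweekly update relaxes only when both means are controlled", {
  win <- function(s, d, n = 5) data.frame(mean_sbp = s, mean_dbp = d, n_responses = n)
  expect_equal(biweekly_frequency_update(win(139, 99), "daily", cfg), "thrice_weekly")
  expect_equal(biweekly_frequency_update(win(140, 100), "thrice_weekly", cfg), "daily")
  # mixed cases: either elevated keeps daily monitoring
  expect_equal(biweekly_frequency_update(win(139, 100), "thrice_weekly", cfg), "daily")
  expect_equal(biweekly_frequency_update(win(140, 99), "thrice_weekly", cfg), "daily")
  # empty window carries the current frequency forward
  expect_equal(biweekly_frequency_update(win(NA, NA, 0), "daily", cfg), "daily")
  expect_equal(biweekly_frequency_update(win(NA, NA, 0), "thrice_weekly", cfg),
               "thrice_weekly")
})

test_that("one-time alerts fire strictly outside the closed threshold ranges", {
  rd <- make_readings(c(0, 1, 2, 3, 4), c(120, 185, 85, 90, 180),
                      c(80, 95, 55, 60, 110))
  al <- check_reading_alerts(rd, cfg)
  # 120/80 nothing; 185/95 sbp_high; 85/55 both lows; 90/60 and 180/110 boundary
  expect_setequal(al$kind, c("sbp_high", "sbp_low", "dbp_low"))
  expect_equal(sort(al$value[al$kind %in% c("sbp_low", "dbp_low")]), c(55, 85))
  expect_equal(al$value[al$kind == "sbp_high"], 185)
})

test_that("alerts match an independent re-evaluation of each inequality on random readings", {
  set.seed(11)
  n <- 5000
  rd <- make_readings(seq_len(n) / 24, sample(50:300, n, TRUE), NA)
  rd$dbp <- pmin(rd$sbp - 1, sample(30:200, n, TRUE))
  al <- check_reading_alerts(rd, cfg)
  got <- sort(paste(round(as.numeric(al$timestamp)), al$kind))
  want <- character(0)
  for (i in seq_len(n)) {  # deliberately scalar: independent of the vector path
    t <- round(as.numeric(rd$timestamp[i]))
    if (rd$sbp[i] > 180) want <- c(want, paste(t, "sbp_high"))
    if (rd$sbp[i] < 90) want <- c(want, paste(t, "sbp_low"))
    if (rd$dbp[i] > 110) want <- c(want, paste(t, "dbp_high"))
    if (rd$dbp[i] < 60) want <- c(want, paste(t, "dbp_low"))
  }
  expect_identical(got, sort(want))
})

test_that("biweekly mean-DBP alert is strictly greater-than", {
  win <- data.frame(patient_id = c("a", "b", "c"), index = 0,
                    start = MONDAY, end = MONDAY + 14 * 86400,
                    mean_sbp = 130, mean_dbp = c(100.0, 100.5, NA),
                    n_responses = c(4, 4, 0))
  al <- check_window_alerts(win, cfg)
  expect_equal(al$patient_id, "b")
  expect_equal(al$kind, "biweekly_dbp_mean_high")
  expect_equal(al$value, 100.5)
})

test_that("prompt schedules are deterministic and follow the weekday rule", {
  daily <- generate_prompt_schedule("daily", MONDAY, 14, cfg)
  expect_length(daily, 14)
  expect_true(all(format(daily, "%H") == "10"))
  thrice <- generate_prompt_schedule("thrice_weekly", MONDAY, 14, cfg)
  expect_length(thrice, 6)
  expect_setequal(unique(weekdays(thrice)), c("Monday", "Wednesday", "Friday"))
  tue <- MONDAY + 86400
  expect_length(generate_prompt_schedule("thrice_weekly", tue, 1, cfg), 0)
  expect_identical(generate_prompt_schedule("thrice_weekly", tue, 30, cfg),
                   generate_prompt_schedule("thrice_weekly", tue, 30, cfg))
})

test_that("biweekly windows tile the follow-up and each reading lands in exactly one", {
  coh <- simulate_cohort(simulation_params(n_patients = 25, seed = 3))
  prot <- run_protocol(coh)
  for (pid in coh$patients$patient_id) {
    w <- prot$windows[prot$windows$patient_id == pid, ]
    w <- w[order(w$index), ]
    enr <- coh$patients$enrollment[coh$patients$patient_id == pid]
    expect_equal(as.numeric(w$end - w$start, units = "days"), rep(14, nrow(w)))
    expect_equal(w$start[1], enr)
    expect_equal(w$start[-1], w$end[-nrow(w)])  # no gap, no overlap
  }
  # every reading maps to exactly one window, and window counts add up
  expect_equal(sum(prot$windows$n_responses), nrow(coh$readings))
})

test_that("run_protocol replays the documented hand-traces", {
  # controlled patient: daily then thrice-weekly from day 14, no alerts
  coh <- make_cohort(constant_patient_readings(120, 80))
  prot <- run_protocol(coh, cfg)
  expect_equal(prot$baselines$status, "complete")
  expect_equal(nrow(prot$transitions), 1)
  expect_equal(prot$transitions$frequency, "thrice_weekly")
  expect_equal(as.numeric(prot$transitions$effective_from - MONDAY, units = "days"), 14)
  expect_equal(prot$windows$frequency, c("daily", rep("thrice_weekly", 5)))
  expect_equal(nrow(prot$alerts), 0)

  # elevated patient at 150/95: daily throughout, still no alerts
  coh <- make_cohort(constant_patient_readings(150, 95))
  prot <- run_protocol(coh, cfg)
  expect_equal(prot$windows$frequency, rep("daily", 6))
  expect_equal(nrow(prot$transitions), 0)
  expect_equal(nrow(prot$alerts), 0)

  # never-responder: insufficient baseline, no transitions, no alerts
  coh <- make_cohort(make_readings(numeric(0), numeric(0), numeric(0)),
                     patient_ids = "p1")
  prot <- run_protocol(coh, cfg)
  expect_equal(prot$baselines$status, "insufficient")
  expect_equal(nrow(prot$transitions), 0)
  expect_equal(nrow(prot$alerts), 0)
})

test_that("run_protocol is deterministic and rejects malformed rows with diagnostics", {
  rd <- rbind(constant_patient_readings(130, 85),
              make_readings(5, 80, 120, patient_id = "p1"),   # implausible
              make_readings(6, 120, 80, patient_id = "ghost")) # unknown patient
  coh <- make_cohort(rd, patient_ids = "p1")
  p1 <- run_protocol(coh, cfg)
  p2 <- run_protocol(coh, cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$rejected), 2)
  expect_setequal(p1$rejected$reason, c("implausible BP values", "unknown patient_id"))
  # the valid stream was still processed in full
  expect_equal(p1$baselines$status, "complete")
  expect_equal(sum(p1$windows$n_responses), 84)
})

test_that("triage report orders by descending SBP, then DBP, then id, silent last", {
  rd <- rbind(make_readings(0:1, 150, 90, "a"),
              make_readings(0:1, 130, 80, "b"),
              make_readings(0:1, 150, 95, "c"))
  coh <- make_cohort(rd, patient_ids = c("a", "b", "c", "silent"))
  rep <- build_triage_report(coh, MONDAY, cfg)
  expect_equal(rep$patient_id, c("c", "a", "b", "silent"))
  expect_true(rep$no_response[4])
  expect_false(any(rep$no_response[1:3]))

  # random fixture against a re-sort by the documented key
  set.seed(21)
  ids <- sprintf("r%02d", 1:12)
  rd <- do.call(rbind, lapply(ids, function(id)
    make_readings(0:3, sample(c(120, 140, 150), 4, TRUE),
                  sample(c(80, 90), 4, TRUE), id)))
  coh <- make_cohort(rd, patient_ids = ids)
  rep <- build_triage_report(coh, MONDAY, cfg)
  oracle <- rep[order(rep$no_response, -rep$mean_sbp, -rep$mean_dbp, rep$patient_id), ]
  expect_equal(rep$patient_id, oracle$patient_id)
  # and the documented invariant directly on the responding rows
  resp <- rep[!rep$no_response, ]
  expect_true(all(diff(resp$mean_sbp) <= 0))
})
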
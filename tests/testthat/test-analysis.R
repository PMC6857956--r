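cfg <- threshold_config()

test_that("response rates and percentages reproduce hand arithmetic", {
  expect_equal(response_rate(4781, 7345), 65.09)
  expect_equal(response_rate(969, 1545), 62.72)
  expect_equal(response_rate(0, 100), 0)
  expect_error(response_rate(1, 0), "positive")
  expect_error(response_rate(5, 4), "n_responses")
  expect_equal(percentage(102, 174), 58.6)
  expect_equal(percentage(14, 22, 0), 64)
})

test_that("risk stratification cuts at 140 inclusive and excludes insufficient baselines", {
  df <- data.frame(patient_id = c("a", "b", "c", "d"),
                   baseline_sbp = c(147.3, 140.0, 125.2, 150),
                   baseline_complete = c(TRUE, TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  expect_message(out <- stratify_patients(df, cfg), "excluded")
  expect_equal(out$stratum, c("high", "high", "low"))
  expect_equal(attr(out, "excluded"), "d")
})

test_that("analyzability requires 5 baseline and 2 final readings", {
  mk <- function(id, base_days, final_days) {
    make_readings(c(base_days, final_days), 130, 85, id)
  }
  rd <- rbind(mk("in", 0:4, c(75, 80)),     # 5 + 2: included
              mk("few_final", 0:4, 75),      # 5 + 1: excluded
              mk("few_base", 0:3, 70:79))    # 4 + 10: excluded
  coh <- make_cohort(rd)
  an <- select_analyzable(coh, cfg)
  expect_equal(an$patient_id, "in")
  expect_equal(an$n_baseline, 5)
  expect_equal(an$n_final, 2)

  # a fully adherent simulated cohort is analyzable in its entirety
  p <- simulation_params(n_patients = 15, prop_never_responder = 0,
                         p_malformed = 0, resp_beta_shape1 = 1e5,
                         resp_beta_shape2 = 1e-2, seed = 8)
  coh <- simulate_cohort(p)
  an <- select_analyzable(coh, cfg)
  # oracle: direct count filter on the readings table
  day <- as.numeric(difftime(coh$readings$timestamp,
                             coh$patients$enrollment[match(coh$readings$patient_id,
                                                           coh$patients$patient_id)],
                             units = "days"))
  n_base <- tapply(day < 14, coh$readings$patient_id, sum)
  n_fin <- tapply(day >= 70, coh$readings$patient_id, sum)
  expect_setequal(an$patient_id,
                  names(n_base)[n_base >= 5 & n_fin >= 2])
  expect_equal(nrow(an), 15)
})

test_that("selection and stratification are order-independent", {
  coh <- simulate_cohort(simulation_params(n_patients = 40, seed = 50))
  shuffled <- coh
  set.seed(1)
  shuffled$patients <- shuffled$patients[sample(nrow(shuffled$patients)), ]
  shuffled$readings <- shuffled$readings[sample(nrow(shuffled$readings)), ]
  a <- select_analyzable(coh, cfg)
  b <- select_analyzable(shuffled, cfg)
  expect_setequal(a$patient_id, b$patient_id)
  sa <- suppressMessages(stratify_patients(a, cfg))
  sb <- suppressMessages(stratify_patients(b, cfg))
  expect_setequal(sa$patient_id[sa$stratum == "high"],
                  sb$patient_id[sb$stratum == "high"])
})

test_that("paired comparison matches the closed-form t computation", {
  # identical pairs: difference 0, p = 1
  same <- paired_comparison(c(120, 125, 130), c(120, 125, 130))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  base <- c(150, 148, 146); fin <- c(140, 139, 137)
  pc <- paired_comparison(base, fin)
  d <- fin - base
  tstat <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(pc$difference, mean(d))  # -9.333...
  expect_equal(pc$p_value, 2 * pt(-abs(tstat), df = 2))
  half <- qt(0.975, 2) * sd(d) / sqrt(3)
  expect_equal(pc$ci_low, mean(d) - half)
  expect_equal(pc$ci_high, mean(d) + half)
  expect_true(pc$ci_low <= pc$difference && pc$difference <= pc$ci_high)

  # degenerate: constant nonzero differences floor at <.001
  z <- paired_comparison(c(120, 130, 140), c(119, 129, 139))
  expect_equal(z$p_value, 0)
  expect_equal(z$p_label, "<.001")
  expect_error(paired_comparison(120, 119), "at least 2")
})

test_that("paired comparison recovers a programmed decline in a small high-risk group", {
  set.seed(300)
  true <- rnorm(22, 147.3, 10)
  base <- true + rnorm(22, 0, 1)
  fin <- true - 10.8 + rnorm(22, 0, 1)
  pc <- paired_comparison(base, fin, "high")
  expect_true(pc$ci_low <= -10.8 && -10.8 <= pc$ci_high)
})

test_that("cross-product odds ratio and Woolf interval behave as documented", {
  res <- odds_ratio_fisher(a = 10, b = 37, c = 5, d = 53)
  expect_equal(res$or, (10 * 53) / (37 * 5))
  expect_equal(res$or_reported, 2.9)
  expect_false(res$continuity_corrected)
  expect_equal(res$ci_low, exp(log(res$or) - qnorm(0.975) * sqrt(1/10 + 1/37 + 1/5 + 1/53)))

  sym <- odds_ratio_fisher(a = 7, b = 7, c = 7, d = 7)
  expect_equal(sym$or, 1)
  expect_equal(sym$p_value, 1)

  zc <- odds_ratio_fisher(a = 0, b = 10, c = 5, d = 5)
  expect_true(zc$continuity_corrected)
  expect_equal(zc$or, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio_fisher(a = 0, b = 0, c = 5, d = 5), "margins")
})

test_that("Fisher p agrees with enumeration and the reference implementation on random tables", {
  set.seed(60)
  enum_oracle <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
    support <- max(0, k - n2):min(k, m)
    pmf <- choose(m, support) * choose(n2, k - support) / choose(N, k)
    sum(pmf[pmf <= pmf[a - support[1] + 1] * (1 + 1e-7)])
  }
  for (i in 1:200) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
      if (all(cells[1] + cells[2] > 0, cells[3] + cells[4] > 0,
              cells[1] + cells[3] > 0, cells[2] + cells[4] > 0)) break
    }
    p <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, enum_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("biweekly proportion series matches manual counts and sums to one", {
  rd <- rbind(make_readings(c(1, 2), 150, 90, "a"),
              make_readings(c(1, 2), 120, 80, "b"))
  coh <- make_cohort(rd, patient_ids = c("a", "b", "c"))
  w <- rbind(biweekly_windows(rd[rd$patient_id == "a", ], MONDAY, "a", 2),
             biweekly_windows(rd[rd$patient_id == "b", ], MONDAY, "b", 2),
             biweekly_windows(rd[0, ], MONDAY, "c", 2))
  s <- biweekly_proportion_series(w, c("a", "b", "c"))
  expect_equal(s$prop_at_or_above[1], 1 / 3)
  expect_equal(s$prop_below[1], 1 / 3)
  expect_equal(s$prop_no_response[1], 1 / 3)
  # second window: everyone silent
  expect_equal(s$prop_no_response[2], 1)
  # rows sum to one on a simulated cohort too
  coh2 <- simulate_cohort(simulation_params(n_patients = 60, seed = 14))
  prot <- run_protocol(coh2)
  responders <- unique(coh2$readings$patient_id)
  s2 <- biweekly_proportion_series(prot$windows, responders)
  expect_true(all(abs(s2$prop_at_or_above + s2$prop_below + s2$prop_no_response - 1)
                  < 1e-9))
})

test_that("flow counts track the cohort stages and their inequalities", {
  rd <- rbind(make_readings(0:5, 130, 85, "a"), make_readings(0:5, 150, 95, "b"))
  prompts <- data.frame(patient_id = rep(c("a", "b", "c"), each = 6),
                        timestamp = MONDAY + rep(0:5, 3) * 86400,
                        channel = "sms",
                        responded = c(rep(1, 12), rep(0, 6)),
                        stringsAsFactors = FALSE)
  coh <- make_cohort(rd, patient_ids = c("a", "b", "c"), prompts = prompts)
  fc <- flow_counts(coh, cfg, contacted = 10)
  expect_equal(fc$contacted, 10)
  expect_equal(fc$consented, 3)
  expect_equal(fc$never_responded, 1)
  expect_equal(fc$completed_baseline, 2)
  expect_equal(fc$completed_week12, 0)  # nobody has final-fortnight readings

  empty <- make_cohort(make_readings(numeric(0), numeric(0), numeric(0)),
                       patient_ids = character(0))
  fc0 <- flow_counts(empty, cfg)
  expect_equal(fc0$consented, 0)
  expect_equal(fc0$never_responded, 0)

  # at study scale, a quarter of patients never answer the initial sequence
  coh2 <- simulate_cohort(simulation_params(n_patients = 174, seed = 4))
  fc2 <- flow_counts(coh2, cfg)
  expect_lt(abs(fc2$never_responded - 44), 18)  # 3 binomial SEs plus slack
  expect_equal(fc2$enrolled_sms + fc2$enrolled_call, 174)
  expect_lte(fc2$completed_week12, fc2$completed_baseline)
})

test_that("satisfaction summaries report means and category shares to one decimal", {
  expect_equal(satisfaction_summary(rep(9, 12))$mean, 9)
  mixed <- c(9, 9, 9, 8, 8, 7, 9, 9, 6, 9)
  expect_equal(satisfaction_summary(mixed)$mean, round(mean(mixed), 1))
  expect_warning(out <- satisfaction_summary(c(9, 9, 11, 0)), "out-of-scale")
  expect_equal(out$n, 2)
  ratings <- c(rep("perfect", 167), rep("too_frequent", 50),
               rep("not_frequent_enough", 31))
  res <- satisfaction_summary(rep(9, 248), ratings)
  expect_equal(res$frequency_pct$perfect, 67.3)
})

test_that("unpaired comparison and Pearson correlation cover the documented cases", {
  expect_equal(unpaired_comparison(c(1, 2, 3), c(1, 2, 3))$difference, 0)
  set.seed(70)
  x <- rnorm(58, 0, 3) ; x <- x - mean(x) + 130.9
  y <- rnorm(47, 0, 3) ; y <- y - mean(y) + 128.4
  uc <- unpaired_comparison(x, y)
  expect_equal(uc$difference, 2.5)
  expect_equal(uc$p_value,
               stats::t.test(x, y, var.equal = TRUE)$p.value)

  lin <- pearson_r(1:10, 2 * (1:10) + 3)
  expect_equal(lin$r, 1)
  expect_warning(res <- pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(res$r))
})

test_that("the assembled cohort report carries every analysis block", {
  coh <- simulate_cohort(simulation_params(n_patients = 80, seed = 23))
  rep <- suppressMessages(analyze_cohort(coh, cfg, contacted = 160))
  expect_s3_class(rep, "cohort_report")
  expect_equal(rep$flow$contacted, 160)
  expect_true(rep$response_rates$overall > 0 && rep$response_rates$overall < 100)
  expect_equal(nrow(rep$comparisons), 6)
  expect_true(all(rep$comparisons$ci_low <= rep$comparisons$difference &
                    rep$comparisons$difference <= rep$comparisons$ci_high))
  expect_equal(sum(rep$odds_ratio$table), rep$flow$completed_week12)
  expect_equal(nrow(rep$series$all), 6)
  expect_true(rep$satisfaction$mean >= 1 && rep$satisfaction$mean <= 9)
})
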
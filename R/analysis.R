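#' Response rate as a percentage
#'
#' @param n_responses Answered prompts.
#' @param n_prompts Sent prompts (> 0).
#' @return `100 * n_responses / n_prompts`, rounded to 2 decimals.
#' @examples
#' response_rate(4781, 7345)  # 65.09
#' @export
response_rate <- function(n_responses, n_prompts) {
  if (any(n_prompts <= 0)) stop("response_rate: n_prompts must be positive", call. = FALSE)
  if (any(n_responses > n_prompts) || any(n_responses < 0)) {
    stop("response_rate: n_responses must lie in [0, n_prompts]", call. = FALSE)
  }
  round(100 * n_responses / n_prompts, 2)
}

#' Percentage of a count over a denominator
#'
#' @param num,den Counts.
#' @param digits Decimal places to report.
#' @return `100 * num / den` rounded to `digits`.
#' @export
percentage <- function(num, den, digits = 1) {
  if (any(den <= 0)) stop("percentage: denominator must be positive", call. = FALSE)
  round(100 * num / den, digits)
}

#' Per-patient summary of a monitored cohort
#'
#' The workhorse table behind selection, stratification and the paired
#' comparisons: for each patient, the number of baseline-phase readings
#' (days 0--13) and of final-fortnight readings (the last two weeks of the
#' follow-up), the baseline mean (first five baseline-phase readings), the
#' final mean (all final-fortnight readings), and the prompt/response
#' counts.
#'
#' @param cohort A `cohort_dataset` (or any list with `patients`, `readings`
#'   and optionally `prompts`).
#' @param cfg A [threshold_config()].
#' @param n_weeks Follow-up length in weeks.
#' @return Data frame, one row per patient.
#' @export
patient_summary <- function(cohort, cfg = threshold_config(), n_weeks = 12) {
  patients <- cohort$patients
  readings <- cohort$readings
  total_days <- n_weeks * 7
  f_levels <- patients$patient_id

  rd <- readings[order(readings$patient_id, readings$timestamp), , drop = FALSE]
  day <- days_since(rd$timestamp, patients$enrollment[match(rd$patient_id,
                                                            patients$patient_id)])
  fac <- factor(rd$patient_id, levels = f_levels)
  in_base <- day >= 0 & day < cfg$baseline_phase_days
  in_final <- day >= total_days - 14 & day < total_days

  cnt <- function(flag) {
    as.integer(table(fac[flag]))
  }
  # rank of each reading within its patient's baseline-phase sequence
  rank_in_base <- stats::ave(as.numeric(in_base), fac, FUN = cumsum)
  use_base <- in_base & rank_in_base <= cfg$baseline_min_responses
  mean_by <- function(x, flag) {
    s <- tapply(x[flag], fac[flag], mean)
    as.numeric(s[f_levels])
  }

  n_prompts <- n_responses <- rep(NA_integer_, nrow(patients))
  if (!is.null(cohort$prompts) && nrow(cohort$prompts) > 0) {
    pf <- factor(cohort$prompts$patient_id, levels = f_levels)
    n_prompts <- as.integer(table(pf))
    n_responses <- as.integer(rowsum(cohort$prompts$responded, pf,
                                     reorder = FALSE)[, 1][f_levels])
    n_responses[is.na(n_responses)] <- 0L
  }

  out <- data.frame(
    patient_id = f_levels,
    n_baseline = cnt(in_base),
    n_final = cnt(in_final),
    baseline_sbp = mean_by(rd$sbp, use_base),
    baseline_dbp = mean_by(rd$dbp, use_base),
    final_sbp = mean_by(rd$sbp, in_final),
    final_dbp = mean_by(rd$dbp, in_final),
    n_prompts = n_prompts,
    n_responses = n_responses,
    stringsAsFactors = FALSE
  )
  out$baseline_complete <- out$n_baseline >= cfg$baseline_min_responses
  out$response_rate <- ifelse(out$n_prompts > 0,
                              100 * out$n_responses / out$n_prompts, NA_real_)
  out
}

#' Select patients eligible for the before/after analysis
#'
#' Keeps patients with at least five baseline-phase readings (days 0--13)
#' and at least two readings in the final two weeks of follow-up.
#'
#' @inheritParams patient_summary
#' @param min_final Minimum final-fortnight readings (default 2).
#' @return The [patient_summary()] rows of the analyzable patients.
#' @export
select_analyzable <- function(cohort, cfg = threshold_config(), n_weeks = 12,
                              min_final = 2) {
  ps <- patient_summary(cohort, cfg, n_weeks)
  keep <- ps$n_baseline >= cfg$baseline_min_responses & ps$n_final >= min_final
  out <- ps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Risk-stratify patients at the systolic cut
#'
#' Partitions patients with a complete baseline into a high stratum
#' (baseline SBP at or above the cut, 140 mm Hg by default) and a low
#' stratum (below). Patients with an insufficient baseline are excluded with
#' a diagnostic.
#'
#' @param summaries Data frame with `patient_id`, `baseline_sbp` and either
#'   `baseline_complete` or `status` columns (e.g. [patient_summary()] rows
#'   or [run_protocol()] baselines).
#' @param cfg A [threshold_config()].
#' @return The input rows with a `stratum` column (`"high"`/`"low"`);
#'   excluded patient ids in attribute `"excluded"`.
#' @export
stratify_patients <- function(summaries, cfg = threshold_config()) {
  if ("mean_sbp" %in% names(summaries) && !"baseline_sbp" %in% names(summaries)) {
    summaries$baseline_sbp <- summaries$mean_sbp
  }
  complete <- if ("baseline_complete" %in% names(summaries)) {
    summaries$baseline_complete
  } else if ("status" %in% names(summaries)) {
    summaries$status == "complete"
  } else {
    !is.na(summaries$baseline_sbp)
  }
  excluded <- summaries$patient_id[!complete]
  if (length(excluded) > 0) {
    message(length(excluded), " patient(s) excluded from stratification: insufficient baseline")
  }
  out <- summaries[complete, , drop = FALSE]
  out$stratum <- ifelse(out$baseline_sbp >= cfg$sbp_risk_cut, "high", "low")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

format_p <- function(p) {
  ifelse(p < 0.001, "<.001",
         sub("^0\\.", ".", ifelse(p < 0.01, sprintf("%.3f", p), sprintf("%.2f", p))))
}

#' Paired before/after comparison
#'
#' Mean within-patient difference (final minus baseline) with a two-sided
#' 95% confidence interval and p-value from the paired Student t-test on
#' n - 1 degrees of freedom. When all differences are identical and nonzero
#' the t statistic is unbounded and the p-value is floored at `<.001`
#' (`p_value` 0 in machine output).
#'
#' @param baseline,final Equal-length numeric vectors of per-patient means.
#' @param group Label for the output row.
#' @return One-row data frame: `group`, `n`, `baseline_mean`, `final_mean`,
#'   `difference`, `ci_low`, `ci_high`, `p_value`, `p_label`.
#' @examples
#' paired_comparison(c(150, 148, 146), c(140, 139, 137))
#' @export
paired_comparison <- function(baseline, final, group = "all") {
  stopifnot(length(baseline) == length(final))
  ok <- !is.na(baseline) & !is.na(final)
  baseline <- baseline[ok]; final <- final[ok]
  n <- length(baseline)
  if (n < 2) stop("paired_comparison: need at least 2 pairs", call. = FALSE)
  d <- final - baseline
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    ci <- c(mean(d), mean(d))
  } else {
    tt <- stats::t.test(final, baseline, paired = TRUE, conf.level = 0.95)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  data.frame(group = group, n = n,
             baseline_mean = mean(baseline), final_mean = mean(final),
             difference = mean(d), ci_low = ci[1], ci_high = ci[2],
             p_value = p, p_label = format_p(p), stringsAsFactors = FALSE)
}

#' Unpaired two-group comparison
#'
#' Student (equal-variance) unpaired t-test by default, Welch optionally.
#'
#' @param x,y Numeric vectors (n >= 2 each).
#' @param var_equal Use the pooled-variance Student test (default) or Welch.
#' @return One-row data frame with group means, `difference`
#'   (`mean(x) - mean(y)`), 95% CI for the difference, `p_value`, `p_label`.
#' @export
unpaired_comparison <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("unpaired_comparison: need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    d <- mean(x) - mean(y)
    return(data.frame(n_x = length(x), n_y = length(y),
                      mean_x = mean(x), mean_y = mean(y), difference = d,
                      ci_low = d, ci_high = d,
                      p_value = if (d == 0) 1 else 0,
                      p_label = format_p(if (d == 0) 1 else 0),
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, conf.level = 0.95)
  data.frame(n_x = length(x), n_y = length(y),
             mean_x = mean(x), mean_y = mean(y),
             difference = mean(x) - mean(y),
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             p_value = tt$p.value, p_label = format_p(tt$p.value),
             stringsAsFactors = FALSE)
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 2.
#' @return One-row data frame `r`, `p_value`; if either vector has zero
#'   variance the correlation is undefined and `NA` is returned with a
#'   warning.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("pearson_r: need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_r: zero variance; correlation undefined")
    return(data.frame(r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test: with margins fixed, sums the hypergeometric
#' probabilities of all tables no more probable than the observed one (the
#' usual two-sided convention, with a 1e-7 relative tolerance for ties).
#'
#' @param a,b,c,d Cell counts, rows = exposure group, cols = outcome.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  pmf <- stats::dhyper(support, m, n2, k)
  p_obs <- pmf[a - lo + 1]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

#' Odds ratio with Woolf interval and Fisher exact p
#'
#' The odds ratio is the sample cross-product `(a*d)/(b*c)`; with any zero
#' cell a 0.5 continuity correction is added to every cell and the result
#' flagged. The 95% CI uses the Woolf log-odds method; the p-value is the
#' exact conditional (hypergeometric) two-sided test.
#'
#' @param table 2x2 matrix `rbind(c(a, b), c(c, d))`, or the four counts via
#'   `a`, `b`, `c`, `d`.
#' @param a,b,c,d Cell counts (used when `table` is missing).
#' @return List: `or`, `or_reported` (rounded to 1 decimal), `ci_low`,
#'   `ci_high`, `p_value`, `continuity_corrected`.
#' @examples
#' odds_ratio_fisher(a = 10, b = 37, c = 5, d = 53)  # or_reported 2.9
#' @export
odds_ratio_fisher <- function(table = NULL, a, b, c, d) {
  # row-major cells: x[1]=a, x[2]=b, x[3]=c, x[4]=d
  x <- if (!is.null(table)) {
    stopifnot(nrow(table) == 2, ncol(table) == 2)
    as.vector(t(table))
  } else {
    base::c(a, b, c, d)
  }
  if (x[1] + x[2] == 0 || x[3] + x[4] == 0 || x[1] + x[3] == 0 || x[2] + x[4] == 0) {
    stop("odds_ratio_fisher: all margins must be positive", call. = FALSE)
  }
  corrected <- any(x == 0)
  xc <- x + 0.5 * corrected
  or <- (xc[1] * xc[4]) / (xc[2] * xc[3])
  se <- sqrt(sum(1 / xc))
  ci <- exp(log(or) + base::c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, or_reported = round(or, 1),
       ci_low = ci[1], ci_high = ci[2],
       p_value = fisher_exact_p(x[1], x[2], x[3], x[4]),
       continuity_corrected = corrected)
}

#' Biweekly proportion series
#'
#' For each biweekly window, the proportions of denominator patients whose
#' window mean SBP was at/above the cut, below the cut, or who reported
#' nothing during the window. The three proportions sum to 1.
#'
#' @param windows Window data frame from [run_protocol()] (field `windows`)
#'   or [biweekly_windows()].
#' @param denominator Character vector of patient ids forming the
#'   denominator (typically patients who completed baseline, i.e. ever
#'   responded).
#' @param cut SBP cut in mm Hg (default 140).
#' @return Data frame per window `index`: `n`, `prop_at_or_above`,
#'   `prop_below`, `prop_no_response`.
#' @export
biweekly_proportion_series <- function(windows, denominator, cut = 140) {
  w <- windows[windows$patient_id %in% denominator, , drop = FALSE]
  n_den <- length(unique(denominator))
  idx <- sort(unique(windows$index))
  if (length(idx) == 0 || n_den == 0) {
    return(data.frame(index = integer(0), n = integer(0),
                      prop_at_or_above = numeric(0), prop_below = numeric(0),
                      prop_no_response = numeric(0)))
  }
  out <- do.call(rbind, lapply(idx, function(i) {
    wi <- w[w$index == i, , drop = FALSE]
    resp <- wi$n_responses > 0
    hi <- sum(resp & wi$mean_sbp >= cut)
    lo <- sum(resp & wi$mean_sbp < cut)
    data.frame(index = i, n = n_den,
               prop_at_or_above = hi / n_den,
               prop_below = lo / n_den,
               prop_no_response = (n_den - hi - lo) / n_den)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort flow counts
#'
#' Counts the stages of the cohort flow: contacted, consented, enrollment by
#' channel, never-responders (no answered prompt at all), patients who
#' completed baseline (answered at least once) and patients analyzable at
#' the final fortnight. The stage inequalities are asserted.
#'
#' @inheritParams patient_summary
#' @param contacted Number of patients contacted before consent, if known
#'   (defaults to the number enrolled).
#' @return Named list of counts.
#' @export
flow_counts <- function(cohort, cfg = threshold_config(), n_weeks = 12,
                        contacted = NULL) {
  patients <- cohort$patients
  consented <- nrow(patients)
  if (is.null(contacted)) contacted <- consented
  if (consented == 0) {
    return(list(contacted = as.integer(contacted), consented = 0L,
                enrolled_sms = 0L, enrolled_call = 0L, never_responded = 0L,
                completed_baseline = 0L, completed_week12 = 0L))
  }
  ps <- patient_summary(cohort, cfg, n_weeks)
  answered <- if (all(is.na(ps$n_responses))) {
    # no prompt log: fall back to valid readings
    tabulate(factor(cohort$readings$patient_id, levels = patients$patient_id),
             nbins = consented)
  } else ps$n_responses
  never <- sum(answered == 0)
  analyzable <- sum(ps$n_baseline >= cfg$baseline_min_responses & ps$n_final >= 2)
  out <- list(
    contacted = contacted,
    consented = consented,
    enrolled_sms = sum(patients$channel == "sms"),
    enrolled_call = sum(patients$channel == "call"),
    never_responded = never,
    completed_baseline = consented - never,
    completed_week12 = analyzable
  )
  stopifnot(out$consented <= out$contacted,
            out$enrolled_sms + out$enrolled_call == out$consented,
            out$completed_baseline <= out$consented,
            out$completed_week12 <= out$completed_baseline)
  out
}

#' Satisfaction survey summary
#'
#' @param likert Numeric vector of 1--9 Likert responses; out-of-scale
#'   values are dropped with a warning.
#' @param frequency_ratings Optional categorical vector of
#'   message-frequency ratings.
#' @return List: `n`, `mean` (1 decimal), and `frequency_pct` (percent
#'   shares, 1 decimal) when ratings are supplied.
#' @export
satisfaction_summary <- function(likert, frequency_ratings = NULL) {
  bad <- is.na(likert) | likert < 1 | likert > 9 | likert != round(likert)
  if (any(bad)) {
    warning(sum(bad), " out-of-scale satisfaction value(s) dropped")
    likert <- likert[!bad]
  }
  out <- list(n = length(likert),
              mean = if (length(likert)) round(mean(likert), 1) else NA_real_)
  if (!is.null(frequency_ratings)) {
    frequency_ratings <- frequency_ratings[!is.na(frequency_ratings)]
    tab <- table(frequency_ratings)
    out$frequency_n <- as.list(as.integer(tab))
    names(out$frequency_n) <- names(tab)
    pct <- round(100 * as.integer(tab) / sum(tab), 1)
    out$frequency_pct <- as.list(pct)
    names(out$frequency_pct) <- names(tab)
  }
  out
}

#' Baseline-versus-final comparisons by risk stratum
#'
#' The before/after table: paired comparisons for the high stratum, low
#' stratum and all analyzable patients. Strata come from the measured
#' baseline by default; `by = "true"` uses the simulator's stratum label
#' when present (useful to check recovery of a programmed decline without
#' misclassification at the cut).
#'
#' @inheritParams patient_summary
#' @param by `"measured"` (baseline SBP >= cut) or `"true"` (simulator
#'   stratum label).
#' @return Data frame with one [paired_comparison()] row per group and
#'   measure (SBP and DBP).
#' @export
table1_comparisons <- function(cohort, cfg = threshold_config(), n_weeks = 12,
                               by = c("measured", "true")) {
  by <- match.arg(by)
  an <- select_analyzable(cohort, cfg, n_weeks)
  if (by == "measured") {
    an <- stratify_patients(an, cfg)
  } else {
    stopifnot("group" %in% names(cohort$patients))
    an$stratum <- cohort$patients$group[match(an$patient_id, cohort$patients$patient_id)]
  }
  one <- function(rows, label) {
    rbind(
      cbind(measure = "sbp",
            paired_comparison(rows$baseline_sbp, rows$final_sbp, label)),
      cbind(measure = "dbp",
            paired_comparison(rows$baseline_dbp, rows$final_dbp, label))
    )
  }
  out <- rbind(
    one(an[an$stratum == "high", ], "baseline_sbp_high"),
    one(an[an$stratum == "low", ], "baseline_sbp_low"),
    one(an, "all")
  )
  rownames(out) <- NULL
  out
}

#' Response-rate by final-control contingency table
#'
#' Cross-classifies analyzable patients by overall response rate (below
#' versus at/above `rate_cut` percent) and final-fortnight mean SBP
#' (at/above versus below `sbp_cut`). Row 1 is the low-response group and
#' column 1 the uncontrolled (SBP at/above cut) outcome, so the
#' cross-product odds ratio is the odds of an uncontrolled final SBP in
#' low responders relative to high responders.
#'
#' @inheritParams patient_summary
#' @param rate_cut Response-rate cut, percent (default 80).
#' @param sbp_cut Final SBP cut, mm Hg (default 140).
#' @return 2x2 integer matrix with informative dimnames.
#' @export
response_control_table <- function(cohort, cfg = threshold_config(), n_weeks = 12,
                                   rate_cut = 80, sbp_cut = 140) {
  an <- select_analyzable(cohort, cfg, n_weeks)
  low_resp <- an$response_rate < rate_cut
  uncontrolled <- an$final_sbp >= sbp_cut
  m <- matrix(c(sum(low_resp & uncontrolled), sum(low_resp & !uncontrolled),
                sum(!low_resp & uncontrolled), sum(!low_resp & !uncontrolled)),
              nrow = 2, byrow = TRUE,
              dimnames = list(response = c("lt_cut", "ge_cut"),
                              final_sbp = c("ge_140", "lt_140")))
  m
}

#' Full study analysis of a monitored cohort
#'
#' Runs the protocol replay and assembles the feasibility-study report:
#' cohort flow, response rates overall and by baseline stratum, the
#' before/after comparisons by stratum, the response-rate odds-ratio block,
#' the biweekly SBP proportion series (all baseline completers and the high
#' stratum), and the satisfaction summary.
#'
#' @inheritParams patient_summary
#' @param contacted Optional contacted count for the flow block.
#' @return An object of class `cohort_report` (a nested list).
#' @export
analyze_cohort <- function(cohort, cfg = threshold_config(), n_weeks = 12,
                           contacted = NULL) {
  prot <- run_protocol(cohort, cfg, n_weeks)
  ps <- patient_summary(cohort, cfg, n_weeks)
  flow <- flow_counts(cohort, cfg, n_weeks, contacted)

  strat <- suppressMessages(stratify_patients(ps[ps$baseline_complete, , drop = FALSE], cfg))
  responders <- ps[ps$n_responses > 0 & !is.na(ps$n_responses), , drop = FALSE]
  rate_block <- list(
    overall = if (nrow(ps) > 0 && sum(ps$n_prompts, na.rm = TRUE) > 0)
      response_rate(sum(ps$n_responses, na.rm = TRUE), sum(ps$n_prompts, na.rm = TRUE))
      else NA_real_,
    baseline_completers = if (nrow(responders) > 0)
      response_rate(sum(responders$n_responses), sum(responders$n_prompts))
      else NA_real_
  )
  for (s in c("high", "low")) {
    ids <- strat$patient_id[strat$stratum == s]
    sub <- responders[responders$patient_id %in% ids, , drop = FALSE]
    rate_block[[paste0("stratum_", s)]] <- if (nrow(sub) > 0)
      response_rate(sum(sub$n_responses), sum(sub$n_prompts)) else NA_real_
  }

  comparisons <- tryCatch(table1_comparisons(cohort, cfg, n_weeks),
                          error = function(e) NULL)
  or_block <- tryCatch({
    tab <- response_control_table(cohort, cfg, n_weeks)
    c(list(table = tab), odds_ratio_fisher(tab))
  }, error = function(e) NULL)

  completers <- ps$patient_id[ps$n_responses > 0 & !is.na(ps$n_responses)]
  high_ids <- strat$patient_id[strat$stratum == "high"]
  series <- list(
    all = biweekly_proportion_series(prot$windows, completers, cfg$sbp_risk_cut),
    high = if (length(high_ids) > 0)
      biweekly_proportion_series(prot$windows, high_ids, cfg$sbp_risk_cut) else NULL
  )

  satisfaction <- if (!is.null(cohort$satisfaction) && nrow(cohort$satisfaction) > 0) {
    satisfaction_summary(cohort$satisfaction$likert,
                         cohort$satisfaction$frequency_rating)
  } else NULL

  structure(list(flow = flow, response_rates = rate_block,
                 comparisons = comparisons, odds_ratio = or_block,
                 series = series, satisfaction = satisfaction,
                 n_alerts = nrow(prot$alerts)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  flow: %d consented, %d never responded, %d analyzable at final fortnight\n",
              x$flow$consented, x$flow$never_responded, x$flow$completed_week12))
  cat(sprintf("  overall response rate: %s%%\n", format(x$response_rates$overall)))
  if (!is.null(x$comparisons)) {
    hi <- x$comparisons[x$comparisons$group == "baseline_sbp_high" &
                          x$comparisons$measure == "sbp", ]
    if (nrow(hi) == 1) {
      cat(sprintf("  high-stratum SBP change: %.1f mm Hg (95%% CI %.1f to %.1f, p %s)\n",
                  hi$difference, hi$ci_low, hi$ci_high, hi$p_label))
    }
  }
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  OR (uncontrolled final SBP, low vs high responders): %.1f (95%% CI %.2f-%.2f, p %s)\n",
                x$odds_ratio$or_reported, x$odds_ratio$ci_low, x$odds_ratio$ci_high,
                format_p(x$odds_ratio$p_value)))
  }
  if (!is.null(x$satisfaction)) {
    cat(sprintf("  satisfaction: mean %.1f / 9 over %d responses\n",
                x$satisfaction$mean, x$satisfaction$n))
  }
  invisible(x)
}
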
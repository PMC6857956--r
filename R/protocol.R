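#' @title Protocol engine
#' @description Deterministic rules of the monitoring protocol: baseline
#'   computation, the smart schedule, alert generation and triaged reporting.
#' @name protocol_engine
#' @keywords internal
NULL

days_since <- function(timestamp, origin) {
  as.numeric(difftime(timestamp, origin, units = "days"))
}

#' Compute a patient's baseline blood pressure
#'
#' Baseline is the mean of the chronologically first five readings reported
#' within the first two weeks after enrollment. With fewer than five such
#' readings the baseline is `"insufficient"` (the means are still reported
#' over what is available, but no schedule decision can be made from them).
#' Readings after the baseline phase never contribute, regardless of how few
#' arrived in time.
#'
#' @param readings Data frame of one patient's readings with columns
#'   `timestamp` (POSIXct), `sbp`, `dbp`, in chronological order.
#' @param enrollment Enrollment datetime (POSIXct).
#' @param cfg A [threshold_config()].
#' @return A one-row data frame: `mean_sbp`, `mean_dbp`, `n_used`, `status`
#'   (`"complete"` or `"insufficient"`).
#' @examples
#' cfg <- threshold_config()
#' e <- as.POSIXct("2016-07-01 10:00:00", tz = "UTC")
#' rd <- data.frame(timestamp = e + (0:6) * 86400,
#'                  sbp = c(150, 148, 146, 144, 142, 140, 138),
#'                  dbp = c(95, 94, 93, 92, 91, 90, 89))
#' compute_baseline(rd, e, cfg)  # mean of the first five only
#' @export
compute_baseline <- function(readings, enrollment, cfg = threshold_config()) {
  stopifnot(is.data.frame(readings))
  if (nrow(readings) > 0) {
    if (any(days_since(readings$timestamp, enrollment) < 0)) {
      stop("compute_baseline: reading before enrollment", call. = FALSE)
    }
    if (is.unsorted(as.numeric(readings$timestamp))) {
      stop("compute_baseline: readings must be in chronological order",
           call. = FALSE)
    }
  }
  in_phase <- if (nrow(readings) == 0) logical(0) else
    days_since(readings$timestamp, enrollment) < cfg$baseline_phase_days
  first <- utils::head(which(in_phase), cfg$baseline_min_responses)
  n_used <- length(first)
  data.frame(
    mean_sbp = if (n_used > 0) mean(readings$sbp[first]) else NA_real_,
    mean_dbp = if (n_used > 0) mean(readings$dbp[first]) else NA_real_,
    n_used = n_used,
    status = if (n_used >= cfg$baseline_min_responses) "complete" else "insufficient",
    stringsAsFactors = FALSE
  )
}

#' Initial prompt frequency from a completed baseline
#'
#' Daily prompting continues when baseline SBP is 140 mm Hg or higher or
#' baseline DBP is 110 mm Hg or higher (both cuts inclusive, both
#' configurable); otherwise the schedule drops to three prompts a week.
#'
#' @param baseline One-row data frame from [compute_baseline()].
#' @inheritParams compute_baseline
#' @return `"daily"` or `"thrice_weekly"`.
#' @export
initial_frequency <- function(baseline, cfg = threshold_config()) {
  if (!identical(baseline$status, "complete")) {
    stop("initial_frequency: baseline is insufficient; no schedule decision possible",
         call. = FALSE)
  }
  if (baseline$mean_sbp >= cfg$schedule_sbp_cut ||
      baseline$mean_dbp >= cfg$baseline_dbp_daily_cut) "daily" else "thrice_weekly"
}

#' Smart-schedule update from the most recent biweekly window
#'
#' The schedule relaxes to thrice-weekly only when the window's mean SBP and
#' mean DBP are both below their cuts (140 and 100 mm Hg by default); if
#' either is at or above its cut the patient is prompted daily. A window with
#' no responses leaves the current frequency unchanged.
#'
#' @param window One-row data frame with `mean_sbp`, `mean_dbp`,
#'   `n_responses` (as produced by [biweekly_windows()]).
#' @param current Current frequency, `"daily"` or `"thrice_weekly"`.
#' @inheritParams compute_baseline
#' @return `"daily"` or `"thrice_weekly"`.
#' @export
biweekly_frequency_update <- function(window, current, cfg = threshold_config()) {
  stopifnot(current %in% c("daily", "thrice_weekly"))
  if (window$n_responses == 0) return(current)
  controlled <- window$mean_sbp < cfg$schedule_sbp_cut &&
    window$mean_dbp < cfg$schedule_dbp_cut
  if (controlled) "thrice_weekly" else "daily"
}

#' One-time alerts for self-reported readings
#'
#' A reading alerts when SBP falls strictly outside the closed interval
#' `[sbp_alert_low, sbp_alert_high]` or DBP strictly outside
#' `[dbp_alert_low, dbp_alert_high]`; boundary values do not alert, and one
#' reading can raise several alerts.
#'
#' @param readings Data frame with columns `patient_id`, `timestamp`, `sbp`,
#'   `dbp` (one or many readings).
#' @inheritParams compute_baseline
#' @return Data frame `patient_id`, `timestamp`, `kind`, `value`, one row per
#'   alert, time-ordered.
#' @examples
#' cfg <- threshold_config()
#' rd <- data.frame(patient_id = "p1",
#'                  timestamp = as.POSIXct("2016-07-01 10:00:00", tz = "UTC"),
#'                  sbp = 185, dbp = 95)
#' check_reading_alerts(rd, cfg)
#' @export
check_reading_alerts <- function(readings, cfg = threshold_config()) {
  stopifnot(is.data.frame(readings))
  empty <- data.frame(patient_id = character(0), timestamp = readings$timestamp[0],
                      kind = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(readings) == 0) return(empty)
  rules <- list(
    sbp_high = readings$sbp > cfg$sbp_alert_high,
    sbp_low  = readings$sbp < cfg$sbp_alert_low,
    dbp_high = readings$dbp > cfg$dbp_alert_high,
    dbp_low  = readings$dbp < cfg$dbp_alert_low
  )
  vals <- list(sbp_high = readings$sbp, sbp_low = readings$sbp,
               dbp_high = readings$dbp, dbp_low = readings$dbp)
  out <- lapply(names(rules), function(k) {
    i <- which(rules[[k]])
    if (length(i) == 0) return(NULL)
    data.frame(patient_id = readings$patient_id[i],
               timestamp = readings$timestamp[i],
               kind = k, value = vals[[k]][i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$timestamp, out$patient_id, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Biweekly mean-DBP alerts
#'
#' A completed biweekly window alerts when its mean DBP is strictly greater
#' than the configured cut (100 mm Hg by default). Windows with no responses
#' have no mean and emit nothing.
#'
#' @param windows Data frame from [biweekly_windows()] (may span patients).
#' @inheritParams compute_baseline
#' @return Data frame `patient_id`, `timestamp` (window end), `kind`,
#'   `value`.
#' @export
check_window_alerts <- function(windows, cfg = threshold_config()) {
  hit <- windows$n_responses > 0 &
    !is.na(windows$mean_dbp) &
    windows$mean_dbp > cfg$biweekly_dbp_mean_alert
  out <- data.frame(patient_id = windows$patient_id[hit],
                    timestamp = windows$end[hit],
                    kind = if (any(hit)) "biweekly_dbp_mean_high" else character(0),
                    value = windows$mean_dbp[hit],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Day offsets (relative to a window start) on which prompts fall, given the
# weekday of the window start (0 = Sunday). Thrice-weekly prompts go out on
# Monday, Wednesday and Friday.
prompt_day_offsets <- function(frequency, start_wday, horizon_days) {
  stopifnot(horizon_days >= 1)
  if (frequency == "daily") return(seq_len(horizon_days) - 1L)
  offs <- seq_len(horizon_days) - 1L
  wd <- (start_wday + offs) %% 7L
  offs[wd %in% c(1L, 3L, 5L)]
}

#' Generate the prompt schedule over a horizon
#'
#' Daily frequency yields one prompt per calendar day at the configured hour;
#' thrice-weekly yields prompts on Mondays, Wednesdays and Fridays.
#' Deterministic in its inputs.
#'
#' @param frequency `"daily"` or `"thrice_weekly"`.
#' @param window_start POSIXct; prompts are generated for the
#'   `horizon_days` calendar days starting on this date.
#' @param horizon_days Number of days covered (>= 1).
#' @inheritParams compute_baseline
#' @return POSIXct vector of prompt datetimes.
#' @examples
#' generate_prompt_schedule("thrice_weekly",
#'   as.POSIXct("2016-07-04 00:00:00", tz = "UTC"), 14)  # a Monday: 6 prompts
#' @export
generate_prompt_schedule <- function(frequency, window_start, horizon_days,
                                     cfg = threshold_config()) {
  stopifnot(frequency %in% c("daily", "thrice_weekly"), horizon_days >= 1)
  day0 <- as.POSIXct(trunc(window_start, "days"))
  wd <- as.POSIXlt(day0)$wday
  offs <- prompt_day_offsets(frequency, wd, horizon_days)
  day0 + offs * 86400 + cfg$prompt_hour * 3600
}

#' Partition a patient's readings into biweekly windows
#'
#' Windows are 14-day half-open intervals `[start, end)` anchored at
#' enrollment (window 0 covers days 0--13, window 1 days 14--27, ...). They
#' tile the follow-up period with no gaps or overlap, so every reading maps
#' to exactly one window. Windows with no responses carry `NA` means.
#'
#' @inheritParams compute_baseline
#' @param patient_id Identifier copied into the output.
#' @param n_windows Number of windows (6 for a 12-week study).
#' @return Data frame: `patient_id`, `index`, `start`, `end`, `mean_sbp`,
#'   `mean_dbp`, `n_responses`.
#' @export
biweekly_windows <- function(readings, enrollment, patient_id, n_windows = 6) {
  d <- if (nrow(readings) == 0) numeric(0) else days_since(readings$timestamp, enrollment)
  idx <- floor(d / 14)
  f <- factor(idx, levels = 0:(n_windows - 1))
  n_resp <- as.integer(table(f))
  mean_by <- function(x) {
    s <- tapply(x, f, mean)
    as.numeric(s)
  }
  data.frame(
    patient_id = patient_id,
    index = 0:(n_windows - 1),
    start = enrollment + (0:(n_windows - 1)) * 14 * 86400,
    end = enrollment + (1:n_windows) * 14 * 86400,
    mean_sbp = if (nrow(readings) == 0) NA_real_ else mean_by(readings$sbp),
    mean_dbp = if (nrow(readings) == 0) NA_real_ else mean_by(readings$dbp),
    n_responses = n_resp,
    stringsAsFactors = FALSE
  )
}

#' Replay the full monitoring protocol over a cohort's events
#'
#' Deterministically replays the protocol for every enrolled patient: daily
#' prompting through the 14-day baseline phase, baseline computation at day
#' 14, the initial frequency decision, then a smart-schedule update at every
#' subsequent biweekly window boundary; one-time and biweekly-mean alerts are
#' collected along the way. Malformed reading rows (implausible values,
#' missing fields) are rejected with per-row diagnostics and processing
#' continues. Running twice on the same input gives identical output.
#'
#' Patients with an insufficient baseline stay on daily prompting (the
#' pre-baseline default); patients who never respond keep no transitions at
#' all. Empty windows carry the current frequency forward.
#'
#' @param cohort A cohort list with `patients` (columns `patient_id`,
#'   `enrollment`) and `readings` (columns `patient_id`, `timestamp`, `sbp`,
#'   `dbp`), e.g. from [simulate_cohort()] or [read_cohort()].
#' @inheritParams compute_baseline
#' @param n_weeks Follow-up length in weeks (default 12, i.e. 6 windows).
#' @return An object of class `protocol_result`: list with `baselines`,
#'   `windows` (with the frequency in effect during each window), `alerts`,
#'   `transitions`, `schedule_states` (final per-patient frequency) and
#'   `rejected` (readings that failed validation, with reasons).
#' @export
run_protocol <- function(cohort, cfg = threshold_config(), n_weeks = 12) {
  patients <- cohort$patients
  readings <- cohort$readings
  stopifnot(is.data.frame(patients), all(c("patient_id", "enrollment") %in% names(patients)))
  if (nrow(patients) == 0) {
    empty_alerts <- data.frame(patient_id = character(0),
                               timestamp = patients$enrollment[0],
                               kind = character(0), value = numeric(0),
                               stringsAsFactors = FALSE)
    return(structure(list(
      baselines = data.frame(patient_id = character(0), mean_sbp = numeric(0),
                             mean_dbp = numeric(0), n_used = integer(0),
                             status = character(0), stringsAsFactors = FALSE),
      windows = data.frame(patient_id = character(0), index = integer(0),
                           start = patients$enrollment[0],
                           end = patients$enrollment[0],
                           mean_sbp = numeric(0), mean_dbp = numeric(0),
                           n_responses = integer(0), frequency = character(0),
                           stringsAsFactors = FALSE),
      alerts = empty_alerts,
      transitions = data.frame(patient_id = character(0),
                               effective_from = patients$enrollment[0],
                               frequency = character(0), reason = character(0),
                               stringsAsFactors = FALSE),
      schedule_states = data.frame(patient_id = character(0),
                                   frequency = character(0),
                                   stringsAsFactors = FALSE),
      rejected = if (is.null(readings)) data.frame() else readings[0, , drop = FALSE]
    ), class = "protocol_result"))
  }
  if (is.null(readings) || nrow(readings) == 0) {
    readings <- data.frame(patient_id = character(0),
                           timestamp = patients$enrollment[0],
                           sbp = numeric(0), dbp = numeric(0),
                           stringsAsFactors = FALSE)
  }

  bad <- !is_plausible_bp(readings$sbp, readings$dbp) |
    is.na(readings$timestamp) | is.na(readings$patient_id) |
    !(readings$patient_id %in% patients$patient_id)
  rejected <- readings[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(
      is.na(readings$timestamp[bad]), "missing timestamp",
      ifelse(!(readings$patient_id[bad] %in% patients$patient_id),
             "unknown patient_id", "implausible BP values"))
  }
  readings <- readings[!bad, , drop = FALSE]
  readings <- readings[order(readings$patient_id, readings$timestamp), , drop = FALSE]

  n_windows <- as.integer(n_weeks * 7 / 14)
  by_patient <- split(seq_len(nrow(readings)), factor(readings$patient_id,
                                                      levels = patients$patient_id))

  baselines <- vector("list", nrow(patients))
  windows <- vector("list", nrow(patients))
  transitions <- vector("list", nrow(patients))
  final_freq <- character(nrow(patients))

  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    enr <- patients$enrollment[i]
    rd <- readings[by_patient[[i]], , drop = FALSE]

    bl <- compute_baseline(rd, enr, cfg)
    win <- biweekly_windows(rd, enr, pid, n_windows)

    freq <- character(n_windows)
    freq[1] <- "daily"  # baseline phase is always daily
    trans <- list()
    if (n_windows >= 2) {
      if (bl$status == "complete") {
        freq[2] <- initial_frequency(bl, cfg)
        if (freq[2] != freq[1]) {
          trans[[length(trans) + 1]] <- data.frame(
            patient_id = pid, effective_from = enr + cfg$baseline_phase_days * 86400,
            frequency = freq[2], reason = "baseline_controlled",
            stringsAsFactors = FALSE)
        }
      } else {
        freq[2] <- "daily"  # insufficient baseline: stay on the default
      }
      for (w in seq_len(n_windows - 1)[-1]) {
        freq[w + 1] <- biweekly_frequency_update(win[w, ], freq[w], cfg)
        if (freq[w + 1] != freq[w]) {
          reason <- if (freq[w + 1] == "daily") "biweekly_elevated" else "biweekly_controlled"
          trans[[length(trans) + 1]] <- data.frame(
            patient_id = pid, effective_from = enr + w * 14 * 86400,
            frequency = freq[w + 1], reason = reason, stringsAsFactors = FALSE)
        }
      }
    }
    win$frequency <- freq
    baselines[[i]] <- cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE), bl)
    windows[[i]] <- win
    transitions[[i]] <- if (length(trans)) do.call(rbind, trans) else NULL
    final_freq[i] <- freq[n_windows]
  }

  baselines <- do.call(rbind, baselines)
  windows <- do.call(rbind, windows)
  transitions <- do.call(rbind, transitions)
  if (is.null(transitions)) {
    transitions <- data.frame(patient_id = character(0),
                              effective_from = patients$enrollment[0],
                              frequency = character(0), reason = character(0),
                              stringsAsFactors = FALSE)
  }
  alerts <- rbind(check_reading_alerts(readings, cfg),
                  check_window_alerts(windows, cfg))
  alerts <- alerts[order(alerts$timestamp, alerts$patient_id, alerts$kind), , drop = FALSE]
  rownames(baselines) <- rownames(windows) <- rownames(alerts) <- NULL

  structure(list(
    baselines = baselines,
    windows = windows,
    alerts = alerts,
    transitions = transitions,
    schedule_states = data.frame(patient_id = patients$patient_id,
                                 frequency = final_freq, stringsAsFactors = FALSE),
    rejected = rejected
  ), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  cat(sprintf("  %d patients, %d complete baselines, %d alerts, %d schedule transitions\n",
              nrow(x$baselines), sum(x$baselines$status == "complete"),
              nrow(x$alerts), nrow(x$transitions)))
  if (nrow(x$rejected) > 0) cat(sprintf("  %d readings rejected\n", nrow(x$rejected)))
  invisible(x)
}

#' Build a triaged biweekly provider report
#'
#' One row per enrolled patient summarising the 14-day reporting period,
#' ordered so the most worrying patients come first: descending mean SBP,
#' ties broken by descending mean DBP, then patient id. Patients with no
#' responses in the period are listed last and flagged.
#'
#' @inheritParams run_protocol
#' @param period_start POSIXct; the report covers `[period_start,
#'   period_start + 14 days)`.
#' @param protocol Optional [run_protocol()] result supplying each patient's
#'   current prompt frequency.
#' @return Data frame: `patient_id`, `mean_sbp`, `mean_dbp`, `n_responses`,
#'   `current_frequency`, `no_response`.
#' @export
build_triage_report <- function(cohort, period_start, cfg = threshold_config(),
                                protocol = NULL) {
  patients <- cohort$patients
  readings <- cohort$readings
  period_end <- period_start + 14 * 86400
  keep <- readings$timestamp >= period_start & readings$timestamp < period_end
  rd <- readings[keep & is_plausible_bp(readings$sbp, readings$dbp), , drop = FALSE]
  f <- factor(rd$patient_id, levels = patients$patient_id)
  n <- as.integer(table(f))
  mean_sbp <- as.numeric(tapply(rd$sbp, f, mean))
  mean_dbp <- as.numeric(tapply(rd$dbp, f, mean))
  freq <- rep(NA_character_, nrow(patients))
  if (!is.null(protocol)) {
    freq <- protocol$schedule_states$frequency[
      match(patients$patient_id, protocol$schedule_states$patient_id)]
  }
  rep_df <- data.frame(patient_id = patients$patient_id,
                       mean_sbp = mean_sbp, mean_dbp = mean_dbp,
                       n_responses = n, current_frequency = freq,
                       no_response = n == 0, stringsAsFactors = FALSE)
  ord <- order(rep_df$no_response,
               -ifelse(is.na(rep_df$mean_sbp), -Inf, rep_df$mean_sbp),
               -ifelse(is.na(rep_df$mean_dbp), -Inf, rep_df$mean_dbp),
               rep_df$patient_id)
  rep_df <- rep_df[ord, , drop = FALSE]
  rownames(rep_df) <- NULL
  attr(rep_df, "period") <- c(start = period_start, end = period_end)
  rep_df
}
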
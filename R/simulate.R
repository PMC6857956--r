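#' Simulation parameters for a synthetic monitoring cohort
#'
#' Defaults describe a 174-patient, 12-week feasibility cohort: 58.6% of
#' patients on SMS (the rest on automated calls), a high-baseline stratum
#' (28/130 of responders) centred at 147.3/82.4 mm Hg that declines by
#' 10.8/6.6 mm Hg over the follow-up, a controlled stratum at 125.2/74.8
#' mm Hg with no drift, per-patient adherence drawn from a Beta distribution
#' with mean 0.65, and a 44/174 mass of patients who never answer the
#' initial daily sequence and receive no further prompts.
#'
#' The programmed decline is a ramp: flat at the group mean through the
#' 14-day baseline phase, linear through week 10, and flat at
#' `mean + drift` over the final two weeks, so both the week-0 to week-12
#' reading difference and the baseline-versus-final-fortnight contrast equal
#' the programmed drift exactly.
#'
#' @param n_patients Number of consenting patients.
#' @param prop_sms Probability a patient chooses SMS over phone calls.
#' @param prop_high_baseline Probability of the high-baseline stratum.
#' @param low_group_mean,high_group_mean Named vectors `c(sbp=, dbp=)`, mm Hg.
#' @param between_patient_sd Between-patient SD of the stable BP level, mm Hg.
#' @param within_patient_sd Within-patient measurement SD, mm Hg.
#' @param high_group_drift,low_group_drift Named vectors `c(sbp=, dbp=)`:
#'   programmed 12-week change, mm Hg (negative = decline).
#' @param resp_beta_shape1,resp_beta_shape2 Beta shape parameters for
#'   per-patient response probability (defaults give mean 0.65, SD 0.18).
#' @param prop_never_responder Mass of patients who never respond at all.
#' @param p_malformed Probability a response string is malformed.
#' @param satisfaction_probs Probabilities of Likert scores 1..9 (defaults
#'   give mean 8.68).
#' @param freq_rating_probs Named probabilities for the message-frequency
#'   rating categories (default "perfect" mass 0.673).
#' @param n_weeks Follow-up length, weeks.
#' @param enrollment_start First enrollment date (character or Date).
#' @param enrollment_span_days Days over which enrollment is spread.
#' @param seed Integer seed; every per-patient stream is derived from
#'   `(seed, patient_index)`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 174,
                              prop_sms = 0.586,
                              prop_high_baseline = 28 / 130,
                              low_group_mean = c(sbp = 125.2, dbp = 74.8),
                              high_group_mean = c(sbp = 147.3, dbp = 82.4),
                              between_patient_sd = 10,
                              within_patient_sd = 8,
                              high_group_drift = c(sbp = -10.8, dbp = -6.6),
                              low_group_drift = c(sbp = 0, dbp = 0),
                              resp_beta_shape1 = 3.9,
                              resp_beta_shape2 = 2.1,
                              prop_never_responder = 44 / 174,
                              p_malformed = 0.02,
                              satisfaction_probs = c(0, 0, 0, 0, 0.01, 0.02, 0.05, 0.12, 0.80),
                              freq_rating_probs = c(too_frequent = 0.17,
                                                    perfect = 0.673,
                                                    not_frequent_enough = 0.157),
                              n_weeks = 12,
                              enrollment_start = "2016-06-27",
                              enrollment_span_days = 76,
                              seed = 1L) {
  p <- list(n_patients = n_patients, prop_sms = prop_sms,
            prop_high_baseline = prop_high_baseline,
            low_group_mean = low_group_mean, high_group_mean = high_group_mean,
            between_patient_sd = between_patient_sd,
            within_patient_sd = within_patient_sd,
            high_group_drift = high_group_drift, low_group_drift = low_group_drift,
            resp_beta_shape1 = resp_beta_shape1, resp_beta_shape2 = resp_beta_shape2,
            prop_never_responder = prop_never_responder,
            p_malformed = p_malformed,
            satisfaction_probs = satisfaction_probs,
            freq_rating_probs = freq_rating_probs,
            n_weeks = n_weeks, enrollment_start = as.character(enrollment_start),
            enrollment_span_days = enrollment_span_days, seed = as.integer(seed))
  validate_simulation_params(p)
}

validate_simulation_params <- function(p) {
  probs <- c(p$prop_sms, p$prop_high_baseline, p$prop_never_responder, p$p_malformed)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("simulation_params: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_patients < 0 || p$n_patients != round(p$n_patients)) {
    stop("simulation_params: n_patients must be a nonnegative integer", call. = FALSE)
  }
  if (p$between_patient_sd < 0 || p$within_patient_sd < 0) {
    stop("simulation_params: standard deviations must be nonnegative", call. = FALSE)
  }
  if (p$resp_beta_shape1 <= 0 || p$resp_beta_shape2 <= 0) {
    stop("simulation_params: Beta shapes must be positive", call. = FALSE)
  }
  for (nm in c("low_group_mean", "high_group_mean", "high_group_drift", "low_group_drift")) {
    if (!all(c("sbp", "dbp") %in% names(p[[nm]]))) {
      stop("simulation_params: ", nm, " needs named sbp and dbp entries", call. = FALSE)
    }
  }
  if (abs(sum(p$satisfaction_probs) - 1) > 1e-8 || length(p$satisfaction_probs) != 9) {
    stop("simulation_params: satisfaction_probs must be 9 probabilities summing to 1",
         call. = FALSE)
  }
  if (abs(sum(p$freq_rating_probs) - 1) > 1e-8) {
    stop("simulation_params: freq_rating_probs must sum to 1", call. = FALSE)
  }
  if (p$n_weeks < 2) stop("simulation_params: n_weeks must be at least 2", call. = FALSE)
  structure(p, class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params>\n")
  cat(sprintf("  %d patients over %d weeks, seed %d\n", x$n_patients, x$n_weeks, x$seed))
  cat(sprintf("  strata: high %.3f at %.1f/%.1f (drift %+.1f/%+.1f), low at %.1f/%.1f\n",
              x$prop_high_baseline, x$high_group_mean["sbp"], x$high_group_mean["dbp"],
              x$high_group_drift["sbp"], x$high_group_drift["dbp"],
              x$low_group_mean["sbp"], x$low_group_mean["dbp"]))
  cat(sprintf("  adherence Beta(%.2f, %.2f), never-responder mass %.3f, malformed %.3f\n",
              x$resp_beta_shape1, x$resp_beta_shape2, x$prop_never_responder,
              x$p_malformed))
  invisible(x)
}

patient_seed <- function(seed, patient_index) {
  as.integer((as.double(seed) * 48271 + patient_index * 7919) %% 2147483647)
}

# Programmed trajectory multiplier: 0 through the baseline phase, linear to
# 1 by the start of the final fortnight, then flat.
drift_ramp <- function(day, total_days) {
  ramp_start <- 14
  ramp_end <- max(total_days - 14, ramp_start + 1)
  pmin(pmax((day - ramp_start) / (ramp_end - ramp_start), 0), 1)
}

# All per-patient randomness, in numeric (days / seconds) form. Uses the
# protocol engine's own rules for the prompt cadence so the feedback loop
# between reported BP and message frequency is the real one.
sim_patient_raw <- function(params, patient_index, cfg) {
  set.seed(patient_seed(params$seed, patient_index))
  total_days <- params$n_weeks * 7

  channel <- if (stats::runif(1) < params$prop_sms) "sms" else "call"
  group <- if (stats::runif(1) < params$prop_high_baseline) "high" else "low"
  never <- stats::runif(1) < params$prop_never_responder
  p_respond <- if (never) 0 else
    round(stats::rbeta(1, params$resp_beta_shape1, params$resp_beta_shape2), 6)
  gm <- if (group == "high") params$high_group_mean else params$low_group_mean
  drift <- if (group == "high") params$high_group_drift else params$low_group_drift
  true_sbp <- round(gm[["sbp"]] + stats::rnorm(1, 0, params$between_patient_sd), 4)
  true_dbp <- round(gm[["dbp"]] + stats::rnorm(1, 0, params$between_patient_sd), 4)
  enroll_day <- floor(stats::runif(1) * params$enrollment_span_days)
  enroll_wday <- (as.integer(as.Date(params$enrollment_start)) + 4 + enroll_day) %% 7

  n_windows <- as.integer(total_days / 14)
  freq <- "daily"
  prompt_days <- integer(0)
  responded <- logical(0)
  resp_days <- integer(0)
  resp_sbp <- integer(0)
  resp_dbp <- integer(0)
  resp_malformed <- logical(0)
  stopped <- FALSE

  for (w in seq_len(n_windows) - 1L) {
    if (stopped) break
    offs <- 14L * w + prompt_day_offsets(freq, enroll_wday, 14L)
    ans <- stats::runif(length(offs)) < p_respond
    prompt_days <- c(prompt_days, offs)
    responded <- c(responded, ans)
    rday <- offs[ans]
    if (length(rday) > 0) {
      ramp <- drift_ramp(rday, total_days)
      sbp <- as.integer(round(true_sbp + drift[["sbp"]] * ramp +
                                stats::rnorm(length(rday), 0, params$within_patient_sd)))
      dbp <- as.integer(round(true_dbp + drift[["dbp"]] * ramp +
                                stats::rnorm(length(rday), 0, params$within_patient_sd)))
      mal <- stats::runif(length(rday)) < params$p_malformed
    } else {
      sbp <- dbp <- integer(0)
      mal <- logical(0)
    }
    resp_days <- c(resp_days, rday)
    resp_sbp <- c(resp_sbp, sbp)
    resp_dbp <- c(resp_dbp, dbp)
    resp_malformed <- c(resp_malformed, mal)

    # Valid (parseable and plausible) readings drive the schedule.
    valid <- !resp_malformed & is_plausible_bp(resp_sbp, resp_dbp)
    in_w <- resp_days >= 14 * w & resp_days < 14 * (w + 1) & valid
    if (w == 0L) {
      if (sum(in_w) == 0) { stopped <- TRUE; next }  # never answered the initial sequence
      bl_idx <- utils::head(which(resp_days < cfg$baseline_phase_days & valid),
                            cfg$baseline_min_responses)
      if (length(bl_idx) >= cfg$baseline_min_responses) {
        bl <- list(mean_sbp = mean(resp_sbp[bl_idx]), mean_dbp = mean(resp_dbp[bl_idx]),
                   n_used = length(bl_idx), status = "complete")
        freq <- initial_frequency(bl, cfg)
      }  # insufficient baseline: stay daily
    } else {
      win <- list(mean_sbp = if (sum(in_w)) mean(resp_sbp[in_w]) else NA_real_,
                  mean_dbp = if (sum(in_w)) mean(resp_dbp[in_w]) else NA_real_,
                  n_responses = sum(in_w))
      freq <- biweekly_frequency_update(win, freq, cfg)
    }
  }

  # Response timestamps: prompt hour plus a delay of up to two hours.
  delay <- if (length(resp_days)) floor(stats::runif(length(resp_days)) * 7200) else numeric(0)
  raw_text <- format_bp(resp_sbp, resp_dbp)
  if (any(resp_malformed)) {
    raw_text[resp_malformed] <- corrupt_message(resp_sbp[resp_malformed],
                                                resp_dbp[resp_malformed])
  }

  # Monthly satisfaction surveys at the end of weeks 4, 8, ... while active.
  surv_days <- if (total_days >= 28) seq(28, total_days, by = 28) - 1 else numeric(0)
  surv_days <- surv_days[!stopped | surv_days < 14]
  surv_ans <- stats::runif(length(surv_days)) < p_respond
  likert <- sample.int(9, sum(surv_ans), replace = TRUE, prob = params$satisfaction_probs)
  freq_rating <- sample(names(params$freq_rating_probs), sum(surv_ans),
                        replace = TRUE, prob = params$freq_rating_probs)

  list(channel = channel, group = group, p_respond = p_respond,
       true_sbp = true_sbp, true_dbp = true_dbp,
       drift_sbp = drift[["sbp"]], drift_dbp = drift[["dbp"]],
       enroll_day = enroll_day,
       prompt_days = prompt_days, responded = responded,
       resp_days = resp_days, resp_delay = delay, raw_text = raw_text,
       resp_sbp = resp_sbp, resp_dbp = resp_dbp, resp_malformed = resp_malformed,
       surv_days = surv_days[surv_ans], likert = likert, freq_rating = freq_rating)
}

# Malformed message variants: separator-free digit run, truncated value, or
# free text with no numbers.
corrupt_message <- function(sbp, dbp) {
  pick <- (sbp + dbp) %% 3
  out <- character(length(sbp))
  out[pick == 0] <- sprintf("%d%d", sbp[pick == 0], dbp[pick == 0])
  out[pick == 1] <- sprintf("%d/", sbp[pick == 1])
  out[pick == 2] <- "took it this morning"
  out
}

#' Simulate a single patient's event stream
#'
#' Deterministic in `(params$seed, patient_index)`. The prompt cadence is
#' driven by the protocol engine's schedule rules applied to the patient's
#' own (simulated) reports, so elevated patients end up prompted daily and
#' controlled patients three times a week. Patients who answer nothing in
#' the initial 14-day daily sequence are sent no further prompts.
#'
#' @param params A [simulation_params()] object.
#' @param patient_index 1-based patient index.
#' @param cfg A [threshold_config()].
#' @return List with `patient` (one-row data frame), `prompts`, `messages`,
#'   `readings` and `satisfaction` data frames (POSIXct timestamps, UTC).
#' @export
simulate_patient <- function(params, patient_index, cfg = threshold_config()) {
  raw <- sim_patient_raw(params, patient_index, cfg)
  assemble_cohort(params, list(raw), sprintf("P%04d", patient_index), cfg)
}

#' Simulate a full synthetic cohort
#'
#' Generates `params$n_patients` independent patient streams (channel,
#' stratum, adherence, BP trajectory, prompts, raw response messages,
#' satisfaction surveys). Fully reproducible: the same `params` (including
#' `seed`) give byte-identical output.
#'
#' @inheritParams simulate_patient
#' @return An object of class `cohort_dataset`: list with data frames
#'   `patients`, `prompts`, `messages`, `readings` (the parseable, plausible
#'   subset of messages) and `satisfaction`.
#' @examples
#' coh <- simulate_cohort(simulation_params(n_patients = 5, seed = 42))
#' coh$patients
#' head(coh$readings)
#' @export
simulate_cohort <- function(params = simulation_params(), cfg = threshold_config()) {
  stopifnot(inherits(params, "simulation_params"))
  raws <- lapply(seq_len(params$n_patients), function(i) sim_patient_raw(params, i, cfg))
  ids <- sprintf("P%04d", seq_len(params$n_patients))
  assemble_cohort(params, raws, ids, cfg)
}

assemble_cohort <- function(params, raws, ids, cfg) {
  origin <- as.POSIXct(paste0(params$enrollment_start, " 00:00:00"), tz = "UTC")
  o_num <- as.numeric(origin)
  hour_s <- cfg$prompt_hour * 3600

  n_per <- function(field) vapply(raws, function(r) length(r[[field]]), integer(1))
  pull <- function(field) unlist(lapply(raws, `[[`, field), use.names = FALSE)
  pid_rep <- function(field) rep(ids, n_per(field))

  enroll_day <- vapply(raws, `[[`, numeric(1), "enroll_day")
  patients <- data.frame(
    patient_id = ids,
    enrollment = .POSIXct(o_num + enroll_day * 86400, tz = "UTC"),
    channel = vapply(raws, `[[`, character(1), "channel"),
    group = vapply(raws, `[[`, character(1), "group"),
    p_respond = vapply(raws, `[[`, numeric(1), "p_respond"),
    true_sbp = vapply(raws, `[[`, numeric(1), "true_sbp"),
    true_dbp = vapply(raws, `[[`, numeric(1), "true_dbp"),
    drift_sbp = vapply(raws, `[[`, numeric(1), "drift_sbp"),
    drift_dbp = vapply(raws, `[[`, numeric(1), "drift_dbp"),
    stringsAsFactors = FALSE
  )

  enr_num <- o_num + rep(enroll_day, n_per("prompt_days")) * 86400
  prompts <- data.frame(
    patient_id = pid_rep("prompt_days"),
    timestamp = .POSIXct(enr_num + pull("prompt_days") * 86400 + hour_s, tz = "UTC"),
    channel = rep(patients$channel, n_per("prompt_days")),
    responded = as.integer(pull("responded")),
    stringsAsFactors = FALSE
  )

  enr_r <- o_num + rep(enroll_day, n_per("resp_days")) * 86400
  msg_ts <- .POSIXct(enr_r + pull("resp_days") * 86400 + hour_s + pull("resp_delay"),
                     tz = "UTC")
  messages <- data.frame(
    patient_id = pid_rep("resp_days"),
    timestamp = msg_ts,
    channel = rep(patients$channel, n_per("resp_days")),
    raw_text = as.character(pull("raw_text")),
    stringsAsFactors = FALSE
  )

  mal <- as.logical(pull("resp_malformed"))
  all_sbp <- as.integer(pull("resp_sbp"))
  all_dbp <- as.integer(pull("resp_dbp"))
  valid <- !mal & is_plausible_bp(all_sbp, all_dbp)
  if (length(valid) == 0) valid <- logical(0)
  readings <- data.frame(
    patient_id = messages$patient_id[valid],
    timestamp = messages$timestamp[valid],
    sbp = all_sbp[valid],
    dbp = all_dbp[valid],
    channel = messages$channel[valid],
    raw_text = messages$raw_text[valid],
    stringsAsFactors = FALSE
  )

  enr_s <- o_num + rep(enroll_day, n_per("surv_days")) * 86400
  satisfaction <- data.frame(
    patient_id = pid_rep("surv_days"),
    timestamp = .POSIXct(enr_s + pull("surv_days") * 86400 + hour_s, tz = "UTC"),
    likert = as.integer(pull("likert")),
    frequency_rating = as.character(pull("freq_rating")),
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, prompts = prompts, messages = messages,
                 readings = readings, satisfaction = satisfaction,
                 params = params),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat(sprintf("  %d patients, %d prompts, %d messages (%d valid readings), %d survey responses\n",
              nrow(x$patients), nrow(x$prompts), nrow(x$messages),
              nrow(x$readings), nrow(x$satisfaction)))
  invisible(x)
}
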
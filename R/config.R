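#' Protocol threshold configuration
#'
#' All cut-offs used by the monitoring protocol live in one object so that a
#' provider override never requires touching rule code. Defaults are the
#' system defaults: one-time alerts fire strictly outside the closed interval
#' 90--180 mm Hg for systolic blood pressure (SBP) and 60--110 mm Hg for
#' diastolic (DBP); a biweekly mean DBP strictly above 100 mm Hg also alerts.
#' Risk stratification and the smart schedule use the 140 mm Hg systolic cut.
#'
#' Note the protocol deliberately carries two different DBP cuts: the
#' baseline rule prompts daily when baseline DBP >= 110 mm Hg
#' (`baseline_dbp_daily_cut`), while the ongoing biweekly rule uses
#' 100 mm Hg (`schedule_dbp_cut`). The two are kept as separate fields.
#'
#' @param sbp_alert_low,sbp_alert_high One-time SBP alert bounds, mm Hg.
#' @param dbp_alert_low,dbp_alert_high One-time DBP alert bounds, mm Hg.
#' @param biweekly_dbp_mean_alert Biweekly mean DBP alert cut (strict >), mm Hg.
#' @param sbp_risk_cut Risk-stratification SBP cut (inclusive >=), mm Hg.
#' @param baseline_dbp_daily_cut Baseline DBP cut for daily prompting, mm Hg.
#' @param schedule_sbp_cut,schedule_dbp_cut Biweekly smart-schedule cuts, mm Hg.
#' @param baseline_phase_days Length of the daily baseline phase, days.
#' @param baseline_min_responses Readings required for a complete baseline.
#' @param prompt_hour Local hour of day at which prompts are sent.
#'
#' @return An object of class `threshold_config` (a validated named list).
#' @examples
#' cfg <- threshold_config()
#' cfg$sbp_alert_high
#' threshold_config(sbp_alert_high = 200)$sbp_alert_high
#' @export
threshold_config <- function(sbp_alert_low = 90,
                             sbp_alert_high = 180,
                             dbp_alert_low = 60,
                             dbp_alert_high = 110,
                             biweekly_dbp_mean_alert = 100,
                             sbp_risk_cut = 140,
                             baseline_dbp_daily_cut = 110,
                             schedule_sbp_cut = 140,
                             schedule_dbp_cut = 100,
                             baseline_phase_days = 14,
                             baseline_min_responses = 5,
                             prompt_hour = 10) {
  cfg <- list(
    sbp_alert_low = sbp_alert_low,
    sbp_alert_high = sbp_alert_high,
    dbp_alert_low = dbp_alert_low,
    dbp_alert_high = dbp_alert_high,
    biweekly_dbp_mean_alert = biweekly_dbp_mean_alert,
    sbp_risk_cut = sbp_risk_cut,
    baseline_dbp_daily_cut = baseline_dbp_daily_cut,
    schedule_sbp_cut = schedule_sbp_cut,
    schedule_dbp_cut = schedule_dbp_cut,
    baseline_phase_days = baseline_phase_days,
    baseline_min_responses = baseline_min_responses,
    prompt_hour = prompt_hour
  )
  validate_threshold_config(cfg)
}

validate_threshold_config <- function(cfg) {
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("threshold_config: non-numeric or missing fields: ",
         paste(names(cfg)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(cfg) <= 0)) {
    stop("threshold_config: all values must be positive", call. = FALSE)
  }
  if (cfg$sbp_alert_low >= cfg$sbp_alert_high) {
    stop("threshold_config: sbp_alert_low must be < sbp_alert_high", call. = FALSE)
  }
  if (cfg$dbp_alert_low >= cfg$dbp_alert_high) {
    stop("threshold_config: dbp_alert_low must be < dbp_alert_high", call. = FALSE)
  }
  if (cfg$prompt_hour < 0 || cfg$prompt_hour > 23) {
    stop("threshold_config: prompt_hour must be in 0..23", call. = FALSE)
  }
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  one-time alerts: SBP outside [%g, %g], DBP outside [%g, %g] mm Hg\n",
              x$sbp_alert_low, x$sbp_alert_high, x$dbp_alert_low, x$dbp_alert_high))
  cat(sprintf("  biweekly mean DBP alert: > %g mm Hg\n", x$biweekly_dbp_mean_alert))
  cat(sprintf("  smart schedule cuts: SBP %g / DBP %g mm Hg\n",
              x$schedule_sbp_cut, x$schedule_dbp_cut))
  cat(sprintf("  baseline: first %g responses within %g days (daily DBP cut %g)\n",
              x$baseline_min_responses, x$baseline_phase_days,
              x$baseline_dbp_daily_cut))
  invisible(x)
}

# Plausibility bounds for a single self-reported reading. Wide enough to keep
# genuine hypertensive urgencies, narrow enough to exclude the physically
# impossible.
BP_BOUNDS <- list(sbp_min = 50, sbp_max = 300, dbp_min = 30, dbp_max = 200)

#' Validate self-reported blood-pressure values
#'
#' A reading is plausible when both numbers are positive integers within
#' 50--300 mm Hg (SBP) and 30--200 mm Hg (DBP) and SBP exceeds DBP.
#' Vectorised; `NA` values are implausible.
#'
#' @param sbp,dbp Numeric vectors, mm Hg.
#' @return Logical vector.
#' @export
is_plausible_bp <- function(sbp, dbp) {
  ok <- !is.na(sbp) & !is.na(dbp) &
    sbp == round(sbp) & dbp == round(dbp) &
    sbp >= BP_BOUNDS$sbp_min & sbp <= BP_BOUNDS$sbp_max &
    dbp >= BP_BOUNDS$dbp_min & dbp <= BP_BOUNDS$dbp_max &
    sbp > dbp
  ok & !is.na(ok)
}
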
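#' @title Dataset and configuration I/O
#' @description CSV round-tripping of cohort datasets, JSON/YAML
#'   configuration loading with strict key checking, and run manifests.
#' @name cli_io
#' @keywords internal
NULL

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

parse_ts <- function(x) {
  as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
}

#' Load a configuration file
#'
#' Reads a JSON or YAML file (by extension) holding either protocol
#' thresholds or simulation parameters. Omitted keys take the documented
#' defaults; unknown keys are an error listing the offenders, as are values
#' violating the configuration invariants.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @param kind `"threshold"` for a [threshold_config()], `"simulation"` for
#'   [simulation_params()].
#' @return A validated `threshold_config` or `simulation_params` object.
#' @export
load_config <- function(path, kind = c("threshold", "simulation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()  # empty file: all defaults
  ctor <- if (kind == "threshold") threshold_config else simulation_params
  known <- names(formals(ctor))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("load_config: unknown ", kind, " key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # YAML/JSON give group means and drifts as named lists or vectors
  for (nm in intersect(names(vals),
                       c("low_group_mean", "high_group_mean",
                         "high_group_drift", "low_group_drift",
                         "freq_rating_probs", "satisfaction_probs"))) {
    vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(ctor, vals)
}

write_csv_iso <- function(df, path) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_ts(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Write a cohort dataset to a directory of CSV files
#'
#' Emits `patients.csv`, `prompts.csv`, `messages.csv`, `readings.csv` and
#' `satisfaction.csv` with ISO-8601 timestamps. [read_cohort()] is the exact
#' inverse on valid datasets.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("patients", "prompts", "messages", "readings", "satisfaction")) {
    if (!is.null(cohort[[nm]])) {
      write_csv_iso(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  invisible(dir)
}

read_csv_checked <- function(path, ts_cols, required, optional = character(0)) {
  if (!file.exists(path)) return(NULL)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(basename(path), ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    for (tc in intersect(ts_cols, names(df))) df[[tc]] <- parse_ts(character(0))
    return(list(data = df, rejected = integer(0)))
  }
  bad <- rep(FALSE, nrow(df))
  for (tc in intersect(ts_cols, names(df))) {
    parsed <- parse_ts(df[[tc]])
    bad <- bad | is.na(parsed)
    df[[tc]] <- parsed
  }
  if (any(bad)) {
    warning(sprintf("%s: dropped %d row(s) with unparseable timestamps (rows %s)",
                    basename(path), sum(bad),
                    paste(utils::head(which(bad), 10), collapse = ", ")))
  }
  list(data = df[!bad, , drop = FALSE], rejected = which(bad))
}

num_cols <- function(df, cols, integer = FALSE) {
  for (nm in intersect(cols, names(df))) {
    df[[nm]] <- if (integer) as.integer(df[[nm]]) else as.numeric(df[[nm]])
  }
  df
}

#' Read a cohort dataset from a directory of CSV files
#'
#' Inverse of [write_cohort()]. Rows with unparseable timestamps are dropped
#' with a warning naming the row numbers; missing required columns are an
#' error. Missing optional files (`messages.csv`, `satisfaction.csv`) give
#' empty components.
#'
#' @param dir Directory holding the CSV files.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  pt <- read_csv_checked(file.path(dir, "patients.csv"), "enrollment",
                         c("patient_id", "enrollment"))
  if (is.null(pt)) stop("read_cohort: patients.csv not found in ", dir, call. = FALSE)
  patients <- num_cols(pt$data, c("p_respond", "true_sbp", "true_dbp",
                                  "drift_sbp", "drift_dbp"))

  pr <- read_csv_checked(file.path(dir, "prompts.csv"), "timestamp",
                         c("patient_id", "timestamp", "responded"))
  prompts <- if (is.null(pr)) NULL else num_cols(pr$data, "responded", integer = TRUE)

  ms <- read_csv_checked(file.path(dir, "messages.csv"), "timestamp",
                         c("patient_id", "timestamp", "raw_text"))
  messages <- if (is.null(ms)) NULL else ms$data

  rd <- read_csv_checked(file.path(dir, "readings.csv"), "timestamp",
                         c("patient_id", "timestamp", "sbp", "dbp"))
  readings <- if (is.null(rd)) {
    data.frame(patient_id = character(0), timestamp = parse_ts(character(0)),
               sbp = integer(0), dbp = integer(0), stringsAsFactors = FALSE)
  } else num_cols(rd$data, c("sbp", "dbp"), integer = TRUE)

  st <- read_csv_checked(file.path(dir, "satisfaction.csv"), "timestamp",
                         c("patient_id", "timestamp", "likert"))
  satisfaction <- if (is.null(st)) NULL else num_cols(st$data, "likert", integer = TRUE)

  structure(list(patients = patients, prompts = prompts, messages = messages,
                 readings = readings, satisfaction = satisfaction),
            class = "cohort_dataset")
}

#' Write alert events to CSV
#'
#' @param alerts Alert data frame from [run_protocol()].
#' @param path Output file.
#' @export
write_alerts <- function(alerts, path) {
  write_csv_iso(alerts, path)
  invisible(path)
}

#' Write a triage report as JSON
#'
#' @param report Data frame from [build_triage_report()].
#' @param path Output file.
#' @export
write_triage_report <- function(report, path) {
  period <- attr(report, "period")
  obj <- list(period = list(start = format_ts(period[1]), end = format_ts(period[2])),
              rows = report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       POSIXt = "ISO8601", pretty = TRUE)
  invisible(path)
}

#' Build a run manifest
#'
#' Records what was run with which inputs so identical manifests imply
#' identical outputs: command name, seed, an MD5 of the serialized
#' configuration, MD5 digests of any input files, the package version and a
#' timestamp.
#'
#' @param command Command name.
#' @param seed Integer seed used (or `NA`).
#' @param config Configuration object (hashed via its JSON serialization).
#' @param input_files Character vector of input file paths.
#' @return Named list.
#' @export
run_manifest <- function(command, seed = NA, config = NULL,
                         input_files = character(0)) {
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  digests <- if (length(input_files) > 0) {
    as.list(tools::md5sum(input_files))
  } else list()
  list(command = command,
       seed = seed,
       config_hash = cfg_hash,
       input_digests = digests,
       tool_version = as.character(utils::packageVersion("smartbp")),
       timestamp = format_ts(Sys.time()))
}

#' Simulate, replay and analyze in one call
#'
#' The full pipeline: [simulate_cohort()] with `seed` injected into the
#' parameters, re-derivation of readings from the raw message strings
#' through [parse_messages()], [run_protocol()], and [analyze_cohort()].
#' Deterministic: the same seed and parameters give an identical report.
#'
#' @param seed Integer seed overriding `params$seed` (optional).
#' @param params A [simulation_params()].
#' @param cfg A [threshold_config()].
#' @param out_dir Optional directory; when given, the cohort CSVs, the alert
#'   CSV, the report JSON and a run manifest are written there.
#' @return List with `cohort`, `protocol`, `report` and `manifest`.
#' @export
end_to_end <- function(seed = NULL, params = simulation_params(),
                       cfg = threshold_config(), out_dir = NULL) {
  if (!is.null(seed)) {
    params$seed <- as.integer(seed)
    params <- validate_simulation_params(unclass(params))
  }
  cohort <- simulate_cohort(params, cfg)
  # Route the raw strings through the parser: the simulator's readings must
  # be exactly the parseable, plausible subset of its messages.
  parsed <- parse_messages(cohort$messages)
  cohort$readings <- parsed$readings
  protocol <- run_protocol(cohort, cfg, params$n_weeks)
  report <- analyze_cohort(cohort, cfg, params$n_weeks)
  manifest <- run_manifest("end_to_end", seed = params$seed, config = params)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, out_dir)
    write_alerts(protocol$alerts, file.path(out_dir, "alerts.csv"))
    jsonlite::write_json(report_to_json(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, protocol = protocol, report = report, manifest = manifest)
}

report_to_json <- function(report) {
  out <- unclass(report)
  if (!is.null(out$odds_ratio$table)) {
    out$odds_ratio$table <- as.data.frame(as.table(out$odds_ratio$table))
  }
  out
}
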
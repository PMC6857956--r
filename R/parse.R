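#' Parse a raw patient message into a blood-pressure reading
#'
#' Patients report readings as free text over SMS or transcribed phone
#' keypresses. The accepted grammar is two integers separated by `/`, a
#' comma, the word `over` (case-insensitive), or whitespace, with arbitrary
#' surrounding text tolerated; the first number is systolic, the second
#' diastolic. Values then pass plausibility validation
#' (see [is_plausible_bp()]). Separator-free digit runs such as `"12080"`
#' are rejected rather than guessed at: a silent mis-split is worse than a
#' re-prompt. Decimals are rejected for the same reason (keypads produce
#' integers).
#'
#' The function is total: any character input yields one of the three
#' outcomes, never an error.
#'
#' @param text Character vector of raw messages.
#' @return A data frame with one row per input: `outcome` (one of `"ok"`,
#'   `"invalid_format"`, `"implausible"`), `sbp`, `dbp` (integer, `NA`
#'   unless `outcome == "ok"`), and `reason` (diagnostic, `NA` when ok).
#' @examples
#' parse_bp_message(c("120/80", "my bp is 135 over 85 today", "80/120", "12080"))
#' @export
parse_bp_message <- function(text) {
  if (length(text) == 0) {
    return(data.frame(outcome = character(0), sbp = integer(0),
                      dbp = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  text <- as.character(text)
  # Defend against invalid encodings from raw byte streams.
  text <- vapply(text, function(s) {
    if (is.na(s)) return(NA_character_)
    s2 <- iconv(s, to = "UTF-8", sub = "")
    if (is.na(s2)) "" else s2
  }, character(1), USE.NAMES = FALSE)

  # Two integer tokens (not embedded in longer digit runs or decimals)
  # joined by /, comma, "over", or bare whitespace.
  pat <- "(?i)(?<![0-9.])([0-9]+)(?:[\\t ]*(?:/|,|over)[\\t ]*|[\\t ]+)([0-9]+)(?![0-9.])"
  m <- regexpr(pat, text, perl = TRUE)

  n <- length(text)
  outcome <- rep("invalid_format", n)
  sbp <- rep(NA_integer_, n)
  dbp <- rep(NA_integer_, n)
  reason <- rep("no SBP/DBP number pair found", n)

  hit <- !is.na(m) & m != -1L
  if (any(hit)) {
    starts <- attr(m, "capture.start")[hit, , drop = FALSE]
    lens <- attr(m, "capture.length")[hit, , drop = FALSE]
    s_txt <- substr(text[hit], starts[, 1], starts[, 1] + lens[, 1] - 1)
    d_txt <- substr(text[hit], starts[, 2], starts[, 2] + lens[, 2] - 1)
    s_num <- suppressWarnings(as.numeric(s_txt))
    d_num <- suppressWarnings(as.numeric(d_txt))
    ok <- is_plausible_bp(s_num, d_num)
    idx <- which(hit)
    outcome[idx] <- ifelse(ok, "ok", "implausible")
    sbp[idx[ok]] <- as.integer(s_num[ok])
    dbp[idx[ok]] <- as.integer(d_num[ok])
    reason[idx] <- ifelse(ok, NA_character_,
                          implausibility_reason(s_num, d_num))
  }
  data.frame(outcome = outcome, sbp = sbp, dbp = dbp, reason = reason,
             stringsAsFactors = FALSE)
}

implausibility_reason <- function(sbp, dbp) {
  reason <- rep("values outside plausible range", length(sbp))
  reason[!is.na(sbp) & !is.na(dbp) & sbp <= dbp] <- "SBP not greater than DBP"
  reason[is.na(sbp) | is.na(dbp)] <- "number too large to represent"
  reason
}

#' Parse a table of raw messages into validated readings
#'
#' Applies [parse_bp_message()] to a message table (as produced by the
#' simulator or read from `messages.csv`) and splits the result into
#' accepted readings and rejects with reasons.
#'
#' @param messages Data frame with columns `patient_id`, `timestamp`,
#'   `channel`, `raw_text`.
#' @return List with `readings` (columns `patient_id`, `timestamp`, `sbp`,
#'   `dbp`, `channel`, `raw_text`) and `rejects` (the failing rows plus
#'   `outcome` and `reason`).
#' @export
parse_messages <- function(messages) {
  stopifnot(is.data.frame(messages),
            all(c("patient_id", "timestamp", "raw_text") %in% names(messages)))
  res <- parse_bp_message(messages$raw_text)
  ok <- res$outcome == "ok"
  channel <- if ("channel" %in% names(messages)) {
    messages$channel[ok]
  } else {
    rep(NA_character_, sum(ok))
  }
  readings <- data.frame(
    patient_id = messages$patient_id[ok],
    timestamp = messages$timestamp[ok],
    sbp = res$sbp[ok],
    dbp = res$dbp[ok],
    channel = channel,
    raw_text = messages$raw_text[ok],
    stringsAsFactors = FALSE
  )
  rejects <- cbind(messages[!ok, , drop = FALSE],
                   outcome = res$outcome[!ok],
                   reason = res$reason[!ok])
  rownames(readings) <- rownames(rejects) <- NULL
  list(readings = readings, rejects = rejects)
}

#' Format a reading in canonical "SBP/DBP" form
#'
#' @param sbp,dbp Integer vectors, mm Hg.
#' @return Character vector like `"120/80"`.
#' @export
format_bp <- function(sbp, dbp) {
  sprintf("%d/%d", as.integer(sbp), as.integer(dbp))
}
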
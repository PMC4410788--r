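# tap-log and cohort file handling ---------------------------------------

CONDITIONS <- c("externally_paced", "self_paced")
TAP_LOG_COLS <- c("participant_id", "group", "condition", "event_type", "time_ms")
COHORT_COLS <- c("participant_id", "group", "age", "gender")
COHORT_SCORE_COLS <- c("stroop_interference_s", "digit_span_backwards")

#' Construct a single tapping session
#'
#' A `tap_session` holds one participant-by-condition recording: the stimulus
#' onsets the computer produced and the tap times the response device captured,
#' all in milliseconds from an arbitrary session origin.
#'
#' @param participant_id Participant identifier (string).
#' @param group Group label (free string, e.g. `"control"` or `"bvFTD"`;
#'   validated against the cohort table downstream, not against a fixed set).
#' @param condition `"externally_paced"` (metronome throughout) or
#'   `"self_paced"` (short synchronization phase, then unpaced continuation).
#' @param stimulus_onsets_ms Strictly increasing onset times (ms).
#' @param tap_times_ms Strictly increasing tap times (ms).
#' @param target_interval_ms Nominal inter-stimulus interval (ms), default 1500.
#'
#' @return An object of class `tap_session`.
#' @export
#' @examples
#' tap_session("p1", "control", "externally_paced",
#'             stimulus_onsets_ms = seq(0, by = 1500, length.out = 5),
#'             tap_times_ms = c(20, 1490, 3010, 4485, 6010))
tap_session <- function(participant_id, group, condition,
                        stimulus_onsets_ms, tap_times_ms,
                        target_interval_ms = 1500) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            is.character(group), length(group) == 1L)
  condition <- match.arg(condition, CONDITIONS)
  stimulus_onsets_ms <- as.numeric(stimulus_onsets_ms)
  tap_times_ms <- as.numeric(tap_times_ms)
  if (!is_scalar_num(target_interval_ms) || target_interval_ms <= 0)
    wk_stop("wktap_invalid_session", "target_interval_ms must be a positive number")
  for (nm in c("stimulus_onsets_ms", "tap_times_ms")) {
    x <- get(nm)
    if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
      wk_stop("wktap_invalid_session",
              "%s: all times must be finite and >= 0 (participant %s)", nm, participant_id)
    if (is.unsorted(x, strictly = TRUE))
      wk_stop("wktap_invalid_session",
              "%s: times must be strictly increasing (participant %s)", nm, participant_id)
  }
  structure(
    list(participant_id = participant_id, group = group, condition = condition,
         stimulus_onsets_ms = stimulus_onsets_ms, tap_times_ms = tap_times_ms,
         target_interval_ms = target_interval_ms),
    class = "tap_session")
}

#' @export
print.tap_session <- function(x, ...) {
  cat(sprintf("<tap_session> %s / %s / %s\n  %d stimuli, %d taps, target interval %g ms\n",
              x$participant_id, x$group, x$condition,
              length(x$stimulus_onsets_ms), length(x$tap_times_ms),
              x$target_interval_ms))
  invisible(x)
}

#' Read a tap-log file
#'
#' The tap log is a flat comma-separated table with one event per row and
#' header `participant_id,group,condition,event_type,time_ms`. Events are
#' partitioned into stimulus onsets and taps and assembled into one
#' [tap_session()] per (participant, condition), with times sorted ascending.
#' Row order in the file is immaterial.
#'
#' @param path Path to a CSV tap log.
#' @param target_interval_ms Nominal inter-stimulus interval assigned to every
#'   session (ms).
#' @return A list of [tap_session()] objects (empty for a header-only file),
#'   ordered by (participant, condition).
#' @export
read_tap_log <- function(path, target_interval_ms = 1500) {
  if (!file.exists(path)) wk_format_error("tap log not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(TAP_LOG_COLS, names(df))
  if (length(missing))
    wk_format_error("tap log %s: missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())

  bad_type <- !df$event_type %in% c("stimulus", "tap")
  if (any(bad_type))
    wk_record_error("tap log %s: unknown event_type '%s' at data row %d",
                    path, df$event_type[which(bad_type)[1]], which(bad_type)[1])
  t_num <- suppressWarnings(as.numeric(df$time_ms))
  bad_t <- is.na(t_num) | !is.finite(t_num) | t_num < 0
  if (any(bad_t))
    wk_record_error("tap log %s: non-numeric or negative time_ms '%s' at data row %d",
                    path, df$time_ms[which(bad_t)[1]], which(bad_t)[1])
  df$time_ms <- t_num

  key <- paste(df$participant_id, df$condition, df$event_type, format_time_ms(df$time_ms))
  if (anyDuplicated(key))
    wk_record_error("tap log %s: duplicate event at data row %d (%s)",
                    path, which(duplicated(key))[1], key[which(duplicated(key))[1]])

  split_key <- paste(df$participant_id, df$condition, sep = "\r")
  sessions <- lapply(split(df, split_key), function(d) {
    grp <- unique(d$group)
    if (length(grp) > 1L)
      wk_record_error("participant %s has conflicting group labels: %s",
                      d$participant_id[1], paste(grp, collapse = ", "))
    tap_session(
      participant_id = d$participant_id[1], group = grp,
      condition = d$condition[1],
      stimulus_onsets_ms = sort(d$time_ms[d$event_type == "stimulus"]),
      tap_times_ms = sort(d$time_ms[d$event_type == "tap"]),
      target_interval_ms = target_interval_ms)
  })
  ord <- order(vapply(sessions, `[[`, "", "participant_id"),
               vapply(sessions, `[[`, "", "condition"), method = "radix")
  unname(sessions[ord])
}

session_events <- function(s) {
  tibble::tibble(
    participant_id = s$participant_id,
    group = s$group,
    condition = s$condition,
    event_type = rep(c("stimulus", "tap"),
                     c(length(s$stimulus_onsets_ms), length(s$tap_times_ms))),
    time_ms = c(s$stimulus_onsets_ms, s$tap_times_ms))
}

#' Write sessions to a tap-log file
#'
#' Serialization is deterministic: fixed column order, rows sorted by
#' (participant, condition, time, event type), and times written at 0.1 ms
#' granularity, so writing the same sessions twice yields byte-identical files.
#'
#' @param sessions List of [tap_session()] objects (may be empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tap_log <- function(sessions, path) {
  stopifnot(is.list(sessions))
  rows <- if (length(sessions)) {
    do.call(rbind, lapply(sessions, session_events))
  } else {
    tibble::tibble(participant_id = character(), group = character(),
                   condition = character(), event_type = character(),
                   time_ms = numeric())
  }
  ord <- order(rows$participant_id, rows$condition, rows$time_ms,
               match(rows$event_type, c("stimulus", "tap")), method = "radix")
  rows <- rows[ord, , drop = FALSE]
  lines <- c(paste(TAP_LOG_COLS, collapse = ","),
             if (nrow(rows)) paste(rows$participant_id, rows$group, rows$condition,
                                   rows$event_type, format_time_ms(rows$time_ms),
                                   sep = ","))
  con <- tryCatch(file(path, "wb"), error = function(e)
    wk_stop("wktap_io_error", "cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a cohort table
#'
#' Expects a CSV with header
#' `participant_id,group,age,gender[,stroop_interference_s,digit_span_backwards]`.
#' Optional cognitive-score columns are preserved; blank scores become `NA`
#' (never zero).
#'
#' @param path Path to the cohort CSV.
#' @return A tibble of class `cohort_table` with one validated row per
#'   participant.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) wk_format_error("cohort file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = c("", "NA"))
  missing <- setdiff(COHORT_COLS, names(df))
  if (length(missing))
    wk_format_error("cohort %s: missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  as_cohort_table(df, source = path)
}

#' Validate a cohort data frame
#'
#' @param df Data frame with at least the required cohort columns.
#' @param source Label used in error messages.
#' @return A `cohort_table` tibble.
#' @export
as_cohort_table <- function(df, source = "cohort") {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$participant_id))
    wk_record_error("%s: duplicate participant_id '%s'", source,
                    df$participant_id[duplicated(df$participant_id)][1])
  age <- suppressWarnings(as.numeric(df$age))
  bad <- (is.na(age) & !is.na(df$age)) | (!is.na(age) & age <= 0)
  if (any(bad))
    wk_record_error("%s: invalid age '%s' at row %d", source,
                    df$age[which(bad)[1]], which(bad)[1])
  df$age <- age
  bad_g <- !df$gender %in% c("M", "F")
  if (any(bad_g))
    wk_record_error("%s: unknown gender code '%s' at row %d (expected M or F)",
                    source, df$gender[which(bad_g)[1]], which(bad_g)[1])
  for (sc in intersect(COHORT_SCORE_COLS, names(df))) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    if (any(is.na(v) & !is.na(df[[sc]])))
      wk_record_error("%s: non-numeric %s at row %d", source, sc,
                      which(is.na(v) & !is.na(df[[sc]]))[1])
    df[[sc]] <- v
  }
  class(df) <- c("cohort_table", class(df))
  df
}

#' Write a cohort table
#'
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, intersect(c(COHORT_COLS, COHORT_SCORE_COLS),
                                          names(cohort)), drop = FALSE]
  df <- df[order(df$participant_id, method = "radix"), , drop = FALSE]
  con <- tryCatch(file(path, "wb"), error = function(e)
    wk_stop("wktap_io_error", "cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  cells <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x)) ifelse(is.na(x), "", format(x, trim = TRUE, digits = 10))
    else as.character(x)
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cells, sep = ",")))
  writeLines(lines, con)
  invisible(path)
}
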
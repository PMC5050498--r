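# Data model and I/O for keystroke event logs and hold-time series.

# Key classes whose hold times enter the signal: letters, digits, printable
# punctuation and the space bar. Modifier, navigation and editing keys have
# intentionally long or task-driven holds and are excluded.
ELIGIBLE_KEY_CLASSES <- c("alphanumeric", "symbol", "space")

INELIGIBLE_KEYS <- c(
  "shift", "shift_l", "shift_r", "ctrl", "control", "ctrl_l", "ctrl_r",
  "alt", "alt_l", "alt_r", "altgr", "meta", "cmd", "super", "win",
  "caps_lock", "capslock", "tab", "enter", "return", "backspace", "delete",
  "del", "insert", "home", "end", "page_up", "page_down", "pageup",
  "pagedown", "up", "down", "left", "right", "arrow_up", "arrow_down",
  "arrow_left", "arrow_right", "esc", "escape", "menu", "print_screen",
  "num_lock", "scroll_lock", paste0("f", 1:24)
)

#' Classify key labels into hold-time eligibility classes
#'
#' Maps raw key labels to one of `"alphanumeric"`, `"symbol"`, `"space"` or
#' `"other"`. Single letters and digits are alphanumeric; the space bar is
#' its own class; any other single printable character is a symbol; named
#' modifier, navigation, function and editing keys (shift, ctrl, arrows,
#' enter, backspace, ...) and unrecognized multi-character tokens are
#' `"other"` and excluded from the hold-time signal.
#'
#' @param key Character vector of key labels.
#' @return Character vector of key classes, same length as `key`.
#' @export
#' @examples
#' classify_key(c("a", "7", ";", "space", "shift", "enter"))
classify_key <- function(key) {
  k <- tolower(as.character(key))
  out <- rep("other", length(k))
  out[k %in% c("space", "spacebar", " ")] <- "space"
  single <- nchar(k) == 1L & !(k %in% INELIGIBLE_KEYS)
  out[single & grepl("^[a-z0-9]$", k)] <- "alphanumeric"
  out[single & grepl("^[[:punct:]]$", k)] <- "symbol"
  out
}

validate_key_events <- function(events) {
  needed <- c("subject_id", "key", "key_class", "press_time", "release_time")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    stop("key event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(events)
}

#' Read a keystroke event log
#'
#' Reads a CSV of per-key press/release timestamps with header
#' `subject_id,key,press_time,release_time` (times in decimal seconds). An
#' optional `key_class` column overrides the automatic [classify_key()]
#' classification. Rows with missing fields, negative press times, or
#' `release_time < press_time` (a negative hold) are dropped with a warning;
#' the number of dropped rows is stored in the `"n_rejected"` attribute.
#'
#' @param path Path to the event CSV.
#' @return A tibble with columns `subject_id`, `key`, `key_class`,
#'   `press_time`, `release_time`, sorted by press time within subject.
#' @export
read_key_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  # read everything as character and convert timestamps with as.numeric
  # (strtod): the fast float parser is not exactly rounded, which would
  # break byte-exact round trips
  ev <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("subject_id", "key", "press_time", "release_time")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    stop("event file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- dplyr::mutate(
    ev,
    press_time = as.numeric(.data$press_time),
    release_time = as.numeric(.data$release_time)
  )
  if (!"key_class" %in% names(ev)) {
    ev$key_class <- classify_key(ev$key)
  } else {
    ev$key_class <- as.character(ev$key_class)
    bad_class <- !ev$key_class %in% c(ELIGIBLE_KEY_CLASSES, "other")
    if (any(bad_class)) {
      stop("unknown key_class value(s): ",
           paste(unique(ev$key_class[bad_class]), collapse = ", "),
           call. = FALSE)
    }
  }
  ok <- !is.na(ev$subject_id) & !is.na(ev$press_time) &
    !is.na(ev$release_time) & ev$press_time >= 0 &
    ev$release_time >= ev$press_time
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " malformed row(s) dropped from ", path,
            " (missing fields or release before press)", call. = FALSE)
  }
  ev <- ev[ok, c("subject_id", "key", "key_class", "press_time",
                 "release_time")]
  ev <- dplyr::arrange(ev, .data$subject_id, .data$press_time)
  ev <- tibble::as_tibble(ev)
  attr(ev, "n_rejected") <- n_rejected
  ev
}

#' Write a keystroke event log in the canonical dialect
#'
#' Comma-separated, header row, UTF-8, times as decimal seconds. Reading the
#' file back with [read_key_events()] and writing again reproduces it
#' byte-identically.
#'
#' @param events Event tibble as returned by [read_key_events()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_key_events <- function(events, path) {
  validate_key_events(events)
  out <- dplyr::arrange(events, .data$subject_id, .data$press_time)
  readr::write_csv(
    out[, c("subject_id", "key", "key_class", "press_time", "release_time")],
    path
  )
  invisible(path)
}

#' Read per-subject metadata
#'
#' Reads a CSV with header
#' `subject_id,group,updrs3,age,sex,education_years,typing_speed,dataset_tag`.
#' `group` must be `PD` or `control`; `updrs3` is the UPDRS part-III motor
#' score on its 0-108 scale; `typing_speed` is keys pressed per minute.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble, one row per subject.
#' @export
read_subject_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "updrs3")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("metadata file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta$subject_id <- as.character(meta$subject_id)
  meta$group <- as.character(meta$group)
  if (!all(meta$group %in% c("PD", "control"))) {
    stop("group must be 'PD' or 'control'", call. = FALSE)
  }
  if (any(meta$updrs3 < 0, na.rm = TRUE)) {
    stop("updrs3 must be non-negative", call. = FALSE)
  }
  if ("typing_speed" %in% names(meta) &&
      any(meta$typing_speed <= 0, na.rm = TRUE)) {
    stop("typing_speed must be positive when present", call. = FALSE)
  }
  tibble::as_tibble(meta)
}

#' Write per-subject metadata
#'
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_meta <- function(meta, path) {
  readr::write_csv(meta, path)
  invisible(path)
}

#' Derive the hold-time series from keystroke events
#'
#' The hold time of a key is `release_time - press_time`. Only keys with an
#' expected short hold enter the series: by default alphanumeric characters,
#' symbols and the space bar; modifier/navigation/editing keys are excluded.
#' Press times are re-anchored so that `t = 0` is the first retained key
#' press of each subject's session.
#'
#' @param events Event tibble (columns `subject_id`, `key_class`,
#'   `press_time`, `release_time`), sorted by press time within subject.
#' @param eligible Character vector of key classes to retain.
#' @return A tibble with columns `subject_id`, `t` (session-relative press
#'   time, seconds) and `hold_time` (seconds), ordered by `t` within
#'   subject, with attribute `"source_event_count"` (rows in `events`).
#' @export
compute_hold_times <- function(events, eligible = ELIGIBLE_KEY_CLASSES) {
  validate_key_events(events)
  n_source <- nrow(events)
  ht <- events |>
    dplyr::filter(.data$key_class %in% eligible) |>
    dplyr::arrange(.data$subject_id, .data$press_time) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      t = .data$press_time - min(.data$press_time),
      hold_time = .data$release_time - .data$press_time
    ) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "t", "hold_time")
  stopifnot(all(ht$hold_time >= 0))
  attr(ht, "source_event_count") <- n_source
  ht
}
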
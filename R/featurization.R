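# Windowing of the hold-time signal and the 7-element feature vector.

#' Windowing and feature configuration
#'
#' @param window_seconds Window length in seconds (non-overlapping, half-open
#'   spans anchored at the first retained key press). Default 90.
#' @param min_samples Minimum hold-time samples for a window to be retained;
#'   sparser windows (typing pauses) are discarded. Default
#'   `window_seconds / 3` = 30.
#' @param histogram_range Hold-time range covered by the histogram features,
#'   seconds. Default `c(0, 0.5)`; holds outside the range fall in no bin.
#' @param histogram_bins Number of equally spaced histogram bins. Default 4.
#' @param outlier_iqr_factor Tukey fence multiplier for the outlier-fraction
#'   feature. Default 1.5.
#' @return A list of class `nqi_window_config`.
#' @export
window_config <- function(window_seconds = 90,
                          min_samples = ceiling(window_seconds / 3),
                          histogram_range = c(0, 0.5),
                          histogram_bins = 4,
                          outlier_iqr_factor = 1.5) {
  stopifnot(window_seconds > 0, min_samples >= 1, histogram_bins >= 1,
            length(histogram_range) == 2,
            histogram_range[2] > histogram_range[1])
  structure(
    list(window_seconds = window_seconds,
         min_samples = min_samples,
         histogram_range = histogram_range,
         histogram_bins = histogram_bins,
         outlier_iqr_factor = outlier_iqr_factor),
    class = "nqi_window_config"
  )
}

#' Partition a hold-time series into retained windows
#'
#' Assigns each hold-time sample to the non-overlapping window
#' `[i * window_seconds, (i + 1) * window_seconds)` containing its press
#' time (half-open, so a press exactly on a boundary belongs to the later
#' window), then drops windows with fewer than `min_samples` samples — the
#' sparsity filter that removes typing pauses.
#'
#' @param hold_times Tibble from [compute_hold_times()] (columns
#'   `subject_id`, `t`, `hold_time`).
#' @param cfg A [window_config()].
#' @return The input with a `window_index` column, restricted to retained
#'   windows, original sample order preserved.
#' @export
partition_windows <- function(hold_times, cfg = window_config()) {
  stopifnot(all(c("subject_id", "t", "hold_time") %in% names(hold_times)))
  if (nrow(hold_times) == 0) {
    return(dplyr::mutate(hold_times, window_index = integer(0)))
  }
  hold_times |>
    dplyr::mutate(window_index = as.integer(floor(.data$t / cfg$window_seconds))) |>
    dplyr::group_by(.data$subject_id, .data$window_index) |>
    dplyr::filter(dplyr::n() >= cfg$min_samples) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$t)
}

#' Fraction of hold-time outliers in a window
#'
#' An outlier lies more than `factor` interquartile ranges below the first
#' quartile or above the third quartile (quartiles by linear interpolation,
#' the type-7 rule).
#'
#' @param x Numeric vector of hold times (at least 4 values).
#' @param factor IQR multiplier, default 1.5.
#' @return Fraction of outliers in `[0, 1]`.
#' @export
outlier_fraction <- function(x, factor = 1.5) {
  if (length(x) < 4) {
    stop("outlier_fraction needs at least 4 samples", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  mean(x < q[1] - factor * iqr | x > q[2] + factor * iqr)
}

#' Quartile skewness of a window's hold times
#'
#' `(q2 - q1) / (q3 - q1)` with quartiles by linear interpolation (type 7).
#' Lies in `[0, 1]`; 0.5 indicates a symmetric interquartile spread. When
#' the distribution is degenerate (`q3 == q1`) the symmetric value 0.5 is
#' returned, with attribute `degenerate = TRUE`.
#'
#' @param x Numeric vector of hold times (at least 4 values).
#' @return Quartile skewness.
#' @export
quartile_skewness <- function(x) {
  if (length(x) < 4) {
    stop("quartile_skewness needs at least 4 samples", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (q[3] == q[1]) {
    return(structure(0.5, degenerate = TRUE))
  }
  (q[2] - q[1]) / (q[3] - q[1])
}

#' Normalized hold-time histogram features
#'
#' Counts in `histogram_bins` equally spaced half-open bins spanning
#' `histogram_range` (default 4 bins over 0 to 0.5 s), each divided by the
#' total number of samples in the window. Holds outside the range contribute
#' to no bin, so the bin masses sum to at most 1.
#'
#' @param x Numeric vector of hold times (non-empty).
#' @param cfg A [window_config()].
#' @return Named numeric vector `h1 ... h<k>`.
#' @export
histogram_features <- function(x, cfg = window_config()) {
  if (length(x) < 1) {
    stop("histogram_features needs at least 1 sample", call. = FALSE)
  }
  edges <- seq(cfg$histogram_range[1], cfg$histogram_range[2],
               length.out = cfg$histogram_bins + 1)
  h <- vapply(seq_len(cfg$histogram_bins), function(k) {
    mean(x >= edges[k] & x < edges[k + 1])
  }, numeric(1))
  names(h) <- paste0("h", seq_len(cfg$histogram_bins))
  h
}

#' Key-overlap coordination feature
#'
#' For each pair of consecutive keystrokes the overlap is the release time
#' of the first key minus the press time of the second; negative values
#' (strictly sequential typing) are clamped to 0. The feature is the mean
#' clamped overlap over all consecutive pairs in the window, in seconds.
#' Positive values indicate key rollover — both keys down at once.
#'
#' @param press Press times of the window's keystrokes, in press order.
#' @param release Matching release times.
#' @return Mean clamped overlap in seconds (0 for a single-keystroke window,
#'   flagged with attribute `single = TRUE`).
#' @export
coordination_feature <- function(press, release) {
  stopifnot(length(press) == length(release))
  n <- length(press)
  if (n < 2) {
    return(structure(0, single = TRUE))
  }
  overlap <- release[-n] - press[-1]
  mean(pmax(overlap, 0))
}

#' Feature vector of a single retained window
#'
#' Assembles the 7 features in fixed order: outlier fraction `v_out`,
#' quartile skewness `v_skew`, the 4 normalized histogram bins `h1..h4`, and
#' the key-overlap coordination metric `v_de`.
#'
#' @param hold_time Hold times of the window, in press order.
#' @param press Press times of the same keystrokes (session-relative).
#' @param cfg A [window_config()].
#' @return Named numeric vector of length `6 + histogram_bins - 4 + 1`
#'   (7 with the default 4 bins).
#' @export
featurize_window <- function(hold_time, press, cfg = window_config()) {
  release <- press + hold_time
  c(v_out = as.numeric(outlier_fraction(hold_time, cfg$outlier_iqr_factor)),
    v_skew = as.numeric(quartile_skewness(hold_time)),
    histogram_features(hold_time, cfg),
    v_de = as.numeric(coordination_feature(press, release)))
}

FEATURE_COLUMNS <- c("v_out", "v_skew", "h1", "h2", "h3", "h4", "v_de")

#' Featurize keystroke events into per-window feature vectors
#'
#' The end-to-end featurization step: filters eligible keys, derives the
#' hold-time series ([compute_hold_times()]), partitions it into
#' non-overlapping windows with the sparsity filter
#' ([partition_windows()]), and computes the 7-element feature vector for
#' every retained window.
#'
#' @param events Event tibble (see [read_key_events()]).
#' @param cfg A [window_config()].
#' @param eligible Key classes entering the hold-time signal.
#' @return A tibble with one row per retained window: `subject_id`,
#'   `window_index`, `v_out`, `v_skew`, `h1`-`h4`, `v_de`, `n_samples`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_pd = 2, n_control = 2, seed = 1))
#' featurize(sim$events)
featurize <- function(events, cfg = window_config(),
                      eligible = ELIGIBLE_KEY_CLASSES) {
  ht <- compute_hold_times(events, eligible)
  win <- partition_windows(ht, cfg)
  if (nrow(win) == 0) {
    return(tibble::tibble(
      subject_id = character(0), window_index = integer(0),
      n_samples = integer(0),
      !!!rlang::set_names(rep(list(numeric(0)), length(FEATURE_COLUMNS)),
                          FEATURE_COLUMNS)
    ))
  }
  win |>
    dplyr::group_by(.data$subject_id, .data$window_index) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      feats = list(featurize_window(.data$hold_time, .data$t, cfg)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("feats") |>
    dplyr::arrange(.data$subject_id, .data$window_index) |>
    dplyr::relocate("n_samples", .after = dplyr::last_col())
}

#' Write / read a per-window feature table
#'
#' CSV with header
#' `subject_id,window_index,v_out,v_skew,h1,h2,h3,h4,v_de,n_samples`.
#'
#' @param features Feature tibble from [featurize()].
#' @param path File path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  cols <- c("subject_id", "window_index", FEATURE_COLUMNS, "n_samples")
  readr::write_csv(features[, cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("subject_id", "window_index", FEATURE_COLUMNS),
                     names(ft))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ft$subject_id <- as.character(ft$subject_id)
  tibble::as_tibble(ft)
}
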
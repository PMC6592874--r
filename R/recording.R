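# In-memory multi-channel recording container.

#' Construct an iEEG recording
#'
#' An `ieeg_recording` holds a multi-channel signal in physical units along
#' with per-channel metadata. Channels may have different sampling rates
#' (as EDF allows) provided all channels span the same duration, i.e.
#' per-channel sample counts are proportional to their rates.
#'
#' @param data Named list of numeric vectors, one per channel; names are
#'   the channel names (unique, non-empty).
#' @param sampling_frequency Per-channel sampling rate in Hz (recycled).
#' @param units Per-channel physical unit strings (recycled; default
#'   microvolts).
#' @param physical_range Per-channel two-column matrix or length-2 vector
#'   `c(min, max)` giving the representable physical range (used by the
#'   EDF writer for its 16-bit scaling). Defaults to a symmetric range
#'   just beyond the data.
#' @param markers Optional tibble of events embedded in the signal file
#'   (`type`, `description`, `onset_sample` 0-based, `duration` in
#'   samples); used by the BrainVision marker file.
#' @param source_format `"edf"`, `"brainvision"` or `NA`.
#' @param binary_encoding `"int16"`, `"float32"` or `NA`.
#' @return An object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(data, sampling_frequency, units = "\u00b5V",
                           physical_range = NULL, markers = NULL,
                           source_format = NA_character_,
                           binary_encoding = NA_character_) {
  if (!is.list(data) || length(data) == 0L) {
    stop_ieeg("bad_recording", "data must be a non-empty named list")
  }
  nm <- names(data)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop_ieeg("bad_recording", "channel names must be unique and non-empty")
  }
  nch <- length(data)
  sampling_frequency <- rep_len(as.numeric(sampling_frequency), nch)
  if (any(!is.finite(sampling_frequency)) || any(sampling_frequency <= 0)) {
    stop_ieeg("bad_recording", "sampling frequencies must be positive")
  }
  units <- rep_len(as.character(units), nch)
  n_samples <- unname(vapply(data, length, integer(1)))
  dur <- n_samples / sampling_frequency
  if (max(dur) - min(dur) > 1e-9) {
    stop_ieeg("bad_recording",
              "per-channel sample counts must be proportional to rates over a common duration")
  }
  if (is.null(physical_range)) {
    physical_range <- t(vapply(data, function(x) {
      m <- max(abs(x), 1e-6)
      c(-1.1 * m, 1.1 * m)
    }, numeric(2)))
  } else if (is.null(dim(physical_range))) {
    physical_range <- matrix(rep(as.numeric(physical_range), nch),
                             ncol = 2, byrow = TRUE)
  }
  if (any(physical_range[, 1] >= physical_range[, 2])) {
    stop_ieeg("bad_recording", "physical range min must be < max")
  }
  structure(
    list(channels = tibble::tibble(
           name = nm,
           sampling_frequency = sampling_frequency,
           units = units,
           physical_min = physical_range[, 1],
           physical_max = physical_range[, 2],
           n_samples = n_samples),
         data = data,
         markers = markers,
         source_format = source_format,
         binary_encoding = binary_encoding),
    class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channel(s), %.3g s, format=%s (%s)\n",
              nrow(x$channels), recording_duration(x),
              x$source_format, x$binary_encoding))
  rates <- sort_c(fmt_num(unique(x$channels$sampling_frequency)))
  cat("  rates (Hz): ", paste(rates, collapse = ", "), "\n", sep = "")
  cat("  channels:   ",
      paste(utils::head(x$channels$name, 8), collapse = ", "),
      if (nrow(x$channels) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x An `ieeg_recording`.
#' @return Length-1 numeric.
#' @export
recording_duration <- function(x) {
  stopifnot(inherits(x, "ieeg_recording"))
  x$channels$n_samples[1] / x$channels$sampling_frequency[1]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-channel summary of a recording
#' @param x An `ieeg_recording`.
#' @param ... Unused.
#' @return A tibble with one row per channel.
#' @export
tidy.ieeg_recording <- function(x, ...) x$channels

#' One-row summary of a recording
#' @param x An `ieeg_recording`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ieeg_recording <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$channels),
                 duration = recording_duration(x),
                 n_rates = length(unique(x$channels$sampling_frequency)),
                 source_format = x$source_format,
                 binary_encoding = x$binary_encoding)
}

#' Signal traces plot for a recording
#'
#' Draws stacked channel traces (physical units) over time.
#'
#' @param object An `ieeg_recording`.
#' @param channels Channel names to draw (default: first 8).
#' @param max_seconds Trim traces to this many seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ieeg_recording <- function(object, channels = NULL,
                                    max_seconds = 5, ...) {
  channels <- channels %||% utils::head(object$channels$name, 8)
  df <- purrr::map_dfr(channels, function(ch) {
    i <- match(ch, object$channels$name)
    fs <- object$channels$sampling_frequency[i]
    x <- object$data[[ch]]
    n <- min(length(x), ceiling(max_seconds * fs))
    tibble::tibble(channel = ch, time = (seq_len(n) - 1) / fs,
                   value = x[seq_len(n)])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = object$channels$units[1])
}
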
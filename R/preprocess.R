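#' Interpolate the electrical stimulation artifact
#'
#' Excises the samples in `window` ms around every stimulus onset and
#' replaces them by piecewise cubic Hermite interpolation (PCHIP), anchored
#' on the two samples flanking each edge of the excision window. All samples
#' outside the windows are left bit-identical. Events without enough context
#' on either side are skipped with a warning.
#'
#' @param rec a `sep_recording`
#' @param window ms pair relative to stimulus onset, default `c(-2, 4)`
#' @return a `sep_recording` with interpolated data
#' @export
interpolate_stimulus_artifact <- function(rec, window = c(-2, 4)) {
  stopifnot(inherits(rec, "sep_recording"), length(window) == 2L,
            window[1L] < window[2L], !is.null(rec$events))
  s0 <- ms_to_sample(window[1L], rec$srate)
  s1 <- ms_to_sample(window[2L], rec$srate)
  n <- ncol(rec$data)
  data <- rec$data
  skipped <- 0L
  for (ev in rec$events$sample) {
    lo <- ev + s0
    hi <- ev + s1
    if (lo - 2L < 1L || hi + 2L > n) {
      skipped <- skipped + 1L
      next
    }
    xi <- c(lo - 2L, lo - 1L, hi + 1L, hi + 2L)   # two anchors per edge
    inside <- lo:hi
    for (ch in seq_len(nrow(data))) {
      data[ch, inside] <- pracma::pchip(xi, data[ch, xi], inside)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d event(s) too close to the recording edge were not interpolated",
                    skipped))
  }
  rec$data <- data
  rec
}

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter of the given order (per band edge) and runs
#' it forward and backward (`signal::filtfilt`), cancelling the phase
#' response; the magnitude response is the squared single-pass response.
#' Band-pass when both edges are given, high- or low-pass when one is NULL.
#'
#' @param x numeric vector, or channels x samples matrix (filtered row-wise)
#' @param srate sampling rate, Hz
#' @param low lower edge in Hz, or NULL for a low-pass
#' @param high upper edge in Hz, or NULL for a high-pass
#' @param order filter order (default 4)
#' @return filtered data, same shape as `x`
#' @export
zero_phase_filter <- function(x, srate, low = NULL, high = NULL, order = 4) {
  stopifnot(srate > 0, !(is.null(low) && is.null(high)))
  nyq <- srate / 2
  stable <- function(flt) max(Mod(polyroot(rev(flt$a)))) < 1 - 1e-9
  if (!is.null(low) && !is.null(high)) {
    stopifnot(0 < low, low < high, high < nyq)
    flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
    if (!stable(flt)) {
      # a single transfer-function design of a band-pass with a tiny
      # normalized low edge is numerically unstable; an equivalent
      # high-pass + low-pass cascade is well conditioned for wide bands.
      # Narrow bands should be filtered at a decimated rate instead.
      if (high / low < 4) {
        stop(paste("band-pass numerically unstable at this sampling rate;",
                   "decimate before filtering a narrow band"), call. = FALSE)
      }
      fh <- signal::butter(order, low / nyq, type = "high")
      fl <- signal::butter(order, high / nyq, type = "low")
      stopifnot(stable(fh), stable(fl))
      flt <- list(cascade = list(fh, fl))
    }
  } else if (is.null(high)) {
    stopifnot(0 < low, low < nyq)
    flt <- signal::butter(order, low / nyq, type = "high")
  } else {
    stopifnot(0 < high, high < nyq)
    flt <- signal::butter(order, high / nyq, type = "low")
  }
  settle <- 3 * order / (if (is.null(low)) high else low) * srate
  run <- function(v) {
    if (length(v) < 3 * order + 1) {
      stop("segment too short to filter at this order", call. = FALSE)
    }
    if (!is.null(flt$cascade)) {
      signal::filtfilt(flt$cascade[[2L]], signal::filtfilt(flt$cascade[[1L]], v))
    } else {
      signal::filtfilt(flt, v)
    }
  }
  if (is.matrix(x)) {
    if (ncol(x) < settle) {
      warning("segment shorter than 3x the filter settle length; edge effects likely")
    }
    for (i in seq_len(nrow(x))) x[i, ] <- run(x[i, ])
    x
  } else {
    if (length(x) < settle) {
      warning("segment shorter than 3x the filter settle length; edge effects likely")
    }
    run(x)
  }
}

#' Band-pass filter a recording's channels
#'
#' Convenience wrapper applying [zero_phase_filter()] to a subset of a
#' recording's channels over the whole continuous data, so that subsequent
#' epochs see no filter edge artifacts.
#'
#' @param rec a `sep_recording`
#' @param low,high,order see [zero_phase_filter()]
#' @param channels channel names to filter (default: the scalp EEG channels)
#' @return filtered `sep_recording`
#' @export
filter_recording <- function(rec, low = NULL, high = NULL, order = 4,
                             channels = rec$eeg_channels) {
  stopifnot(inherits(rec, "sep_recording"))
  idx <- match(channels, rec$ch_names)
  stopifnot(!anyNA(idx))
  rec$data[idx, ] <- zero_phase_filter(rec$data[idx, , drop = FALSE],
                                       rec$srate, low, high, order)
  rec
}

#' Cut a recording into stimulus-locked epochs
#'
#' Pure indexing: the sample at 0 ms is the event's onset sample. Events
#' whose window exceeds the recording bounds are dropped with a message;
#' their rows are retained (tombstoned) in the returned `info` with
#' `kept = FALSE`.
#'
#' @param rec a `sep_recording` with events
#' @param window ms pair, default `c(-100, 600)`
#' @param metadata optional data.frame merged into the per-trial info (one
#'   row per event, e.g. responses and latents)
#' @return a `sep_epochs`; `info` has one row per kept trial, and the
#'   attribute `"dropped"` lists dropped trial indices
#' @export
epoch_data <- function(rec, window = c(-100, 600), metadata = NULL) {
  stopifnot(inherits(rec, "sep_recording"), !is.null(rec$events),
            length(window) == 2L, window[1L] < window[2L])
  s0 <- ms_to_sample(window[1L], rec$srate)
  s1 <- ms_to_sample(window[2L], rec$srate)
  n <- ncol(rec$data)
  keep <- rec$events$sample + s0 >= 1L & rec$events$sample + s1 <= n
  if (!any(keep)) stop("no event has full window coverage: empty epochs", call. = FALSE)
  if (any(!keep)) {
    message(sprintf("dropped %d event(s) without full window coverage", sum(!keep)))
  }
  events <- rec$events[keep, , drop = FALSE]
  n_trials <- nrow(events)
  n_ch <- nrow(rec$data)
  n_samp <- s1 - s0 + 1L
  data <- array(0, dim = c(n_trials, n_ch, n_samp))
  for (i in seq_len(n_trials)) {
    data[i, , ] <- rec$data[, (events$sample[i] + s0):(events$sample[i] + s1)]
  }
  info <- events
  if (!is.null(metadata)) {
    info <- cbind(info, metadata[keep, , drop = FALSE])
  }
  info$kept <- TRUE
  ep <- new_epochs(data, times = (s0:s1) / rec$srate * 1000,
                   srate = rec$srate, ch_names = rec$ch_names, info = info)
  attr(ep, "dropped") <- which(!keep)
  ep
}

#' Average re-reference
#'
#' Subtracts, at every sample, the mean over the scalp EEG channels from
#' each scalp channel; peripheral channels are untouched. Works on both
#' recordings and epochs. Idempotent.
#'
#' @param x a `sep_recording` or `sep_epochs`
#' @param channels channels entering (and receiving) the reference; defaults
#'   to the recording's scalp channels, or all channels for epochs
#' @return same class as `x`
#' @export
rereference_average <- function(x, channels = NULL) {
  if (inherits(x, "sep_recording")) {
    if (is.null(channels)) channels <- x$eeg_channels
    idx <- match(channels, x$ch_names)
    stopifnot(!anyNA(idx))
    if (length(idx) < 2L) stop("average reference needs >= 2 channels", call. = FALSE)
    x$data[idx, ] <- sweep(x$data[idx, , drop = FALSE], 2L,
                           colMeans(x$data[idx, , drop = FALSE]))
    x
  } else if (inherits(x, "sep_epochs")) {
    if (is.null(channels)) channels <- x$ch_names
    idx <- match(channels, x$ch_names)
    stopifnot(!anyNA(idx))
    if (length(idx) < 2L) stop("average reference needs >= 2 channels", call. = FALSE)
    ref <- apply(x$data[, idx, , drop = FALSE], c(1L, 3L), mean)
    for (ch in idx) x$data[, ch, ] <- x$data[, ch, ] - ref
    x
  } else {
    stop("rereference_average expects a sep_recording or sep_epochs", call. = FALSE)
  }
}

#' Optional amplitude-threshold trial rejection
#'
#' Flags trials whose absolute amplitude exceeds `threshold` uV on any scalp
#' channel. Stands in for manual artifact screening; disabled by default on
#' synthetic data.
#'
#' @param epochs a `sep_epochs`
#' @param threshold rejection threshold in uV
#' @param channels channels to screen
#' @return logical vector, TRUE for trials to keep
#' @export
amplitude_reject <- function(epochs, threshold, channels = epochs$ch_names) {
  stopifnot(inherits(epochs, "sep_epochs"), threshold > 0)
  idx <- match(channels, epochs$ch_names)
  stopifnot(!anyNA(idx))
  apply(epochs$data[, idx, , drop = FALSE], 1L, function(m) max(abs(m)) <= threshold)
}
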
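#' Continuous multichannel recording
#'
#' Lightweight container: a channels x samples matrix in uV (CMAP in mV),
#' the sampling rate, channel names, the subset of scalp EEG channels
#' (peripheral channels are excluded from re-referencing and CCA), and the
#' event table.
#'
#' @param data channels x samples numeric matrix
#' @param srate sampling rate, Hz
#' @param ch_names channel names (rownames of `data`)
#' @param eeg_channels names of the scalp channels
#' @param events data.frame with at least `sample` and `label`
#' @return object of class `sep_recording`
#' @export
new_recording <- function(data, srate, ch_names = rownames(data),
                          eeg_channels = ch_names, events = NULL) {
  stopifnot(is.matrix(data), srate > 0, length(ch_names) == nrow(data))
  if (!is.null(events)) {
    stopifnot(all(diff(events$sample) > 0),
              all(events$sample >= 1), all(events$sample <= ncol(data)))
  }
  rownames(data) <- ch_names
  structure(
    list(data = data, srate = srate, ch_names = ch_names,
         eeg_channels = eeg_channels, events = events),
    class = "sep_recording"
  )
}

#' @export
print.sep_recording <- function(x, ...) {
  cat(sprintf("<sep_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$srate,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Epoched data container
#'
#' @param data trials x channels x samples array
#' @param times time axis in ms relative to stimulus onset
#' @param srate sampling rate, Hz
#' @param ch_names channel names
#' @param info per-trial metadata data.frame (one row per trial)
#' @return object of class `sep_epochs`
#' @export
new_epochs <- function(data, times, srate, ch_names, info = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3L] == length(times),
            dim(data)[2L] == length(ch_names), !is.unsorted(times))
  structure(
    list(data = data, times = times, srate = srate,
         ch_names = ch_names, info = info),
    class = "sep_epochs"
  )
}

#' @export
print.sep_epochs <- function(x, ...) {
  cat(sprintf("<sep_epochs> %d trials x %d ch x %d samples, %g..%g ms\n",
              dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L],
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.sep_epochs <- function(x) dim(x$data)

#' Grand-average waveforms of an epochs object
#' @param x a `sep_epochs`
#' @return channels x samples matrix
#' @export
grand_average <- function(x) {
  stopifnot(inherits(x, "sep_epochs"))
  out <- apply(x$data, c(2L, 3L), mean)
  rownames(out) <- x$ch_names
  out
}
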
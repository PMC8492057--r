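#' Single-trial N20 peak amplitude
#'
#' Localizes the subject-level N20 latency `L` as the minimum of the average
#' waveform of the (sign-standardized) CCA component within `search_window`,
#' then measures each trial's amplitude as the minimum within `L +/-
#' peak_halfwidth` ms. A warning is raised when the average minimum sits on
#' the search-window boundary (possible mis-localization).
#'
#' @param component_epochs single-channel `sep_epochs` from
#'   [project_trials()]
#' @param search_window ms pair bracketing the average N20 (default
#'   `c(15, 30)`)
#' @param peak_halfwidth per-trial search half-width around `L` in ms
#'   (default 2)
#' @return data.frame with per-trial `amplitude` (uV) and `latency` (ms);
#'   attribute `"subject_latency"` holds `L`
#' @export
n20_peak_amplitude <- function(component_epochs, search_window = c(15, 30),
                               peak_halfwidth = 2) {
  stopifnot(inherits(component_epochs, "sep_epochs"),
            dim(component_epochs$data)[2L] == 1L)
  times <- component_epochs$times
  wi <- which(times >= search_window[1L] & times <= search_window[2L])
  stopifnot(length(wi) >= 3L)
  avg <- colMeans(component_matrix(component_epochs))
  Lidx <- wi[which.min(avg[wi])]
  if (Lidx == wi[1L] || Lidx == wi[length(wi)]) {
    warning("average N20 minimum lies on the search-window boundary; latency may be mis-localized")
  }
  L <- times[Lidx]
  pi_ <- which(times >= L - peak_halfwidth & times <= L + peak_halfwidth)
  n_trials <- dim(component_epochs$data)[1L]
  amp <- numeric(n_trials)
  lat <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    seg <- component_epochs$data[i, 1L, pi_]
    j <- which.min(seg)
    amp[i] <- seg[j]
    lat[i] <- times[pi_[j]]
  }
  out <- data.frame(amplitude = amp, latency = lat)
  attr(out, "subject_latency") <- L
  out
}

#' Mean amplitude in a fixed time window
#'
#' Arithmetic mean over the window samples, per trial — the measure used for
#' the P15 (±1 ms around its average latency) and the N140 (140-160 ms on
#' the 0.5-45 Hz stream).
#'
#' @param component_epochs single-channel `sep_epochs`
#' @param window ms pair
#' @return numeric vector, one mean amplitude per trial
#' @export
window_mean_amplitude <- function(component_epochs, window) {
  stopifnot(inherits(component_epochs, "sep_epochs"),
            dim(component_epochs$data)[2L] == 1L, length(window) == 2L)
  wi <- which(component_epochs$times >= window[1L] &
                component_epochs$times <= window[2L])
  if (length(wi) == 0L) stop("empty measurement window", call. = FALSE)
  apply(component_epochs$data[, 1L, wi, drop = FALSE], 1L, mean)
}

#' Per-trial pre-stimulus alpha amplitude (log-envelope)
#'
#' For each trial: cut the pre-stimulus segment (so no post-stimulus sample
#' can leak into the measure), project through the SEP spatial filter,
#' mirror-pad to both sides (full segment length), zero-phase band-pass in
#' the alpha band, take the amplitude envelope as the modulus of the
#' analytic signal (Hilbert transform), average the envelope over
#' `average_window`, and take the natural log.
#'
#' @param epochs_raw multichannel `sep_epochs` cut from the unfiltered
#'   recording; must cover `segment`
#' @param spatial_filter a `cca_result` (its selected, sign-standardized
#'   filter is used) or a bare channel-weight vector
#' @param band alpha band in Hz, default `c(8, 13)`
#' @param segment pre-stimulus cut in ms, default `c(-500, -5)`
#' @param average_window envelope averaging window in ms, default
#'   `c(-200, -10)`
#' @param order Butterworth order, default 4
#' @return numeric vector of per-trial log amplitudes (log-uV)
#' @export
prestimulus_alpha <- function(epochs_raw, spatial_filter, band = c(8, 13),
                              segment = c(-500, -5),
                              average_window = c(-200, -10), order = 4) {
  stopifnot(inherits(epochs_raw, "sep_epochs"), segment[2L] <= 0,
            average_window[1L] >= segment[1L],
            average_window[2L] <= segment[2L])
  if (inherits(spatial_filter, "cca_result")) {
    chi <- match(spatial_filter$channels, epochs_raw$ch_names)
    if (anyNA(chi)) stop("epochs lack channels of the spatial filter", call. = FALSE)
    sel <- spatial_filter$selected
    if (is.na(sel)) stop("no component selected in the cca_result", call. = FALSE)
    w <- spatial_filter$sign * spatial_filter$Wx[, sel]
  } else {
    w <- as.numeric(spatial_filter)
    stopifnot(length(w) == dim(epochs_raw$data)[2L])
    chi <- seq_len(dim(epochs_raw$data)[2L])
  }
  si <- which(epochs_raw$times >= segment[1L] & epochs_raw$times <= segment[2L])
  stopifnot(length(si) > 8L)
  seg_times <- epochs_raw$times[si]
  # a narrow-band IIR design is ill-conditioned when the band sits far below
  # Nyquist; work at a decimated rate (~16x the upper band edge) with a
  # zero-phase anti-alias low-pass before subsampling
  srate <- epochs_raw$srate
  k <- max(1L, floor(srate / (16 * band[2L])))
  di <- seq(1L, length(si), by = k)
  srate_d <- srate / k
  seg_times <- seg_times[di]
  ai <- which(seg_times >= average_window[1L] & seg_times <= average_window[2L])
  flt <- signal::butter(order, band / (srate_d / 2), type = "pass")
  aa <- if (k > 1L) signal::butter(order, 0.8 / k, type = "low") else NULL
  n_trials <- dim(epochs_raw$data)[1L]
  out <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    x <- as.numeric(crossprod(w, epochs_raw$data[i, chi, si]))
    if (k > 1L) x <- signal::filtfilt(aa, x)[di]
    px <- mirror_pad_periodic(x, reps = 3L)
    xf <- signal::filtfilt(flt, px$padded)
    env <- Mod(hilbert_analytic(xf))[(px$offset + 1L):(px$offset + length(di))]
    m <- mean(env[ai])
    if (!is.finite(m) || m <= 0) {
      stop("non-positive alpha envelope mean: degenerate input", call. = FALSE)
    }
    out[i] <- log(m)
  }
  out
}

#' Per-trial peripheral amplitudes (CNAP peak, CMAP peak-to-peak)
#'
#' CNAP: on the 70 Hz high-pass filtered nerve channel, the subject latency
#' is the maximum of the average between 5 and 9 ms; per-trial amplitude is
#' the maximum within ±1 ms of it. CMAP: after baseline correction (mean of
#' -20..-5 ms), the average's negative peak is searched in 5-11 ms and the
#' positive peak in 10-20 ms; per-trial peak-to-peak amplitude is
#' `max(pos ± 1 ms) - min(neg ± 1 ms)`.
#'
#' @param cnap_epochs single-channel `sep_epochs` of the filtered CNAP, or
#'   NULL (feature returned as NA)
#' @param cmap_epochs single-channel `sep_epochs` of the CMAP, or NULL
#' @param n_trials required when both inputs are NULL
#' @return data.frame with per-trial `cnap_amp` (uV) and `cmap_amp` (mV)
#' @export
peripheral_amplitudes <- function(cnap_epochs = NULL, cmap_epochs = NULL,
                                  n_trials = NULL) {
  peak_measure <- function(ep, search, halfwidth, fun) {
    times <- ep$times
    wi <- which(times >= search[1L] & times <= search[2L])
    avg <- colMeans(component_matrix(ep))
    L <- times[wi[fun(avg[wi])]]
    pi_ <- which(times >= L - halfwidth & times <= L + halfwidth)
    list(latency = L, idx = pi_)
  }
  if (!is.null(cnap_epochs)) n_trials <- dim(cnap_epochs$data)[1L]
  if (!is.null(cmap_epochs)) n_trials <- dim(cmap_epochs$data)[1L]
  if (is.null(n_trials)) stop("n_trials required when both channels are missing",
                              call. = FALSE)
  cnap <- rep(NA_real_, n_trials)
  cmap <- rep(NA_real_, n_trials)
  if (is.null(cnap_epochs)) {
    message("CNAP channel missing: cnap_amp set to NA")
  } else {
    stopifnot(dim(cnap_epochs$data)[2L] == 1L)
    pk <- peak_measure(cnap_epochs, c(5, 9), 1, which.max)
    for (i in seq_len(n_trials)) {
      cnap[i] <- max(cnap_epochs$data[i, 1L, pk$idx])
    }
  }
  if (is.null(cmap_epochs)) {
    message("CMAP channel missing: cmap_amp set to NA")
  } else {
    stopifnot(dim(cmap_epochs$data)[2L] == 1L)
    bi <- which(cmap_epochs$times >= -20 & cmap_epochs$times <= -5)
    stopifnot(length(bi) > 0L)
    dat <- component_matrix(cmap_epochs)
    dat <- dat - rowMeans(dat[, bi, drop = FALSE])
    bc <- cmap_epochs
    bc$data[, 1L, ] <- dat
    neg <- peak_measure(bc, c(5, 11), 1, which.min)
    pos <- peak_measure(bc, c(10, 20), 1, which.max)
    for (i in seq_len(n_trials)) {
      cmap[i] <- max(dat[i, pos$idx]) - min(dat[i, neg$idx])
    }
  }
  data.frame(cnap_amp = cnap, cmap_amp = cmap)
}
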
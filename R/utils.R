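#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal of a real vector: the positive
#' frequencies are doubled, the negative frequencies zeroed, and DC/Nyquist
#' kept, so `Mod(hilbert_analytic(x))` is the amplitude envelope.
#'
#' @param x real numeric vector
#' @return complex vector of the same length
#' @keywords internal
hilbert_analytic <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1L)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Mirror-pad a vector symmetrically on both sides
#'
#' Pads with the reversed signal (symmetric reflection, no repeated edge
#' sample) by `pad` samples on each side; `pad` defaults to the full segment
#' length, the convention used for the pre-stimulus alpha pipeline.
#'
#' @param x numeric vector
#' @param pad samples to add on each side (<= length(x))
#' @keywords internal
mirror_pad <- function(x, pad = length(x) - 1L) {
  n <- length(x)
  stopifnot(pad >= 1L, pad <= n - 1L)
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

#' Periodic even (repeated mirror) extension
#'
#' Tiles the even periodic extension of `x` (period `2n - 2`) `reps` times
#' on each side of a central copy. Narrow-band zero-phase filtering started
#' from zero initial conditions needs this much context for its edge
#' transient to die out before the segment of interest.
#'
#' @param x numeric vector
#' @param reps number of full periods on each side
#' @return list with `padded` (the extended vector) and `offset` (samples
#'   before the central copy of `x`)
#' @keywords internal
mirror_pad_periodic <- function(x, reps = 3L) {
  n <- length(x)
  stopifnot(n >= 3L, reps >= 1L)
  period <- c(x, x[(n - 1L):2L])            # even extension, length 2n - 2
  full <- rep(period, 2L * reps + 1L)
  list(padded = full, offset = reps * (2L * n - 2L))
}

#' Deterministic per-stage child seeds
#'
#' Fans a single experiment seed out to independent stage seeds via a fixed
#' affine map modulo a Mersenne prime, so every stage (sequence, latents,
#' rendering, responses, analysis resampling) draws from its own stream and
#' the whole run is reproducible from one integer.
#'
#' @param seed integer master seed
#' @param stage stage name (any string) or integer offset
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  idx <- if (is.numeric(stage)) {
    as.double(stage)
  } else {
    # stable small hash of the stage name
    sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  }
  m <- 2147483647 # 2^31 - 1
  as.integer(((as.double(seed) %% m) * 48271 + 7919 * idx) %% (m - 1)) + 1L
}

#' Z-transform a numeric vector
#'
#' Centers and scales to unit variance (sample SD), the standardization
#' applied to all continuous single-trial predictors before model fitting.
#' Constant input returns all zeros rather than NaN.
#'
#' @param x numeric vector (NAs tolerated and preserved)
#' @return numeric vector, mean 0 and SD 1 over the non-NA entries
#' @export
ztrans <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    return(ifelse(is.na(x), NA_real_, 0))
  }
  (x - mu) / s
}

#' Per-subject z-transform of a column
#' @param x numeric vector
#' @param subject grouping vector, same length
#' @keywords internal
ztrans_by <- function(x, subject) {
  out <- x
  for (s in unique(subject)) {
    i <- subject == s
    out[i] <- ztrans(x[i])
  }
  out
}

ms_to_sample <- function(ms, srate) as.integer(round(ms / 1000 * srate))

#' @keywords internal
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# trials x samples matrix of a single-channel epochs object
#' @keywords internal
component_matrix <- function(ep) {
  m <- ep$data[, 1L, , drop = FALSE]
  dim(m) <- dim(m)[c(1L, 3L)]
  m
}
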
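#' Template-matching CCA for single-trial SEP extraction
#'
#' Learns spatial filters that maximize the correlation between the
#' horizontally concatenated single trials `X = [x_1, ..., x_N]` and the
#' grand-average template replicated N times, `Y = [xbar, ..., xbar]`.
#' Because averaging cancels the background noise, the leading canonical
#' component acts as a template match for the shared SEP morphology across
#' trials.
#'
#' The canonical problem is solved by whitening: with `Cxx`, `Cyy`, `Cxy`
#' the (shrinkage-regularized) covariance blocks, the SVD of
#' `Cxx^(-1/2) Cxy Cyy^(-1/2)` gives the canonical correlations (singular
#' values) and the filters after back-transformation. `Cyy` is rank-limited
#' (Y is a replicated average), so its inverse square root is a
#' pseudo-inverse over the retained eigenspace.
#'
#' @param epochs a `sep_epochs` (band-pass filtered, re-referenced)
#' @param window training window in ms post-stimulus, default `c(5, 80)`
#'   (the early SEP; the learned filter is later applied to full epochs)
#' @param channels channels entering the decomposition (default: all but the
#'   peripheral CNAP/CMAP channels)
#' @param shrinkage covariance shrinkage weight `gamma` in
#'   `(1-gamma) C + gamma tr(C)/p I` (default 1e-6; raise it for
#'   rank-deficient, e.g. average-referenced, data)
#' @return object of class `cca_result`: filters `Wx`, `Wy` (columns =
#'   components, descending canonical correlation `rho`), unit-norm
#'   activation patterns `A = Cxx Wx`, per-component mean waveforms over the
#'   training window, and placeholders for the selected component and sign
#' @export
fit_template_cca <- function(epochs, window = c(5, 80), channels = NULL,
                             shrinkage = 1e-6) {
  stopifnot(inherits(epochs, "sep_epochs"), length(window) == 2L,
            window[1L] < window[2L])
  if (is.null(channels)) {
    channels <- setdiff(epochs$ch_names, c("CNAP", "CMAP"))
  }
  chi <- match(channels, epochs$ch_names)
  stopifnot(!anyNA(chi))
  n_trials <- dim(epochs$data)[1L]
  if (n_trials < 2L) stop("template CCA needs >= 2 trials", call. = FALSE)
  ti <- which(epochs$times >= window[1L] & epochs$times <= window[2L])
  if (length(ti) < 2L) stop("training window outside the epoch range", call. = FALSE)
  p <- length(chi)
  tlen <- length(ti)

  # X: channels x (tlen * n_trials); Y: replicated grand average
  X <- matrix(0, p, tlen * n_trials)
  for (i in seq_len(n_trials)) {
    X[, ((i - 1L) * tlen + 1L):(i * tlen)] <- epochs$data[i, chi, ti]
  }
  xbar <- matrix(0, p, tlen)
  for (i in seq_len(n_trials)) {
    xbar <- xbar + X[, ((i - 1L) * tlen + 1L):(i * tlen)]
  }
  xbar <- xbar / n_trials
  Y <- matrix(xbar, p, tlen * n_trials)   # column-recycled replication

  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  m <- ncol(X) - 1L
  Cxx <- tcrossprod(Xc) / m
  Cyy <- tcrossprod(Yc) / m
  Cxy <- tcrossprod(Xc, Yc) / m
  reg <- function(C) (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / p) * diag(p)
  Cxx <- reg(Cxx)

  isqrt <- function(C, pseudo = FALSE) {
    e <- eigen(C, symmetric = TRUE)
    tol <- max(e$values) * p * .Machine$double.eps * 100
    keep <- e$values > tol
    if (!pseudo && any(!keep)) {
      stop(paste("rank-deficient covariance: increase the `shrinkage`",
                 "parameter (e.g. 1e-4) or drop redundant channels"),
           call. = FALSE)
    }
    v <- e$vectors[, keep, drop = FALSE]
    v %*% (t(v) / sqrt(e$values[keep]))
  }
  Wxx <- isqrt(Cxx)
  Wyy <- isqrt(reg(Cyy), pseudo = TRUE)   # Y is a replicated average: low rank
  sv <- svd(Wxx %*% Cxy %*% Wyy)
  rho <- pmin(pmax(sv$d, 0), 1)
  Wx <- Wxx %*% sv$u
  Wy <- Wyy %*% sv$v
  # fix an arbitrary overall sign per component for reproducibility
  for (k in seq_len(ncol(Wx))) {
    j <- which.max(abs(Wx[, k]))
    if (Wx[j, k] < 0) {
      Wx[, k] <- -Wx[, k]
      Wy[, k] <- -Wy[, k]
    }
  }
  A <- Cxx %*% Wx
  A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  mean_waveforms <- crossprod(Wx, xbar)   # components x time

  structure(
    list(Wx = Wx, Wy = Wy, rho = rho, patterns = A,
         mean_waveforms = mean_waveforms, times = epochs$times[ti],
         window = window, channels = channels, Cxx = Cxx,
         selected = NA_integer_, sign = 1),
    class = "cca_result"
  )
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d components over %d channels, window %g..%g ms\n",
              ncol(x$Wx), nrow(x$Wx), x$window[1L], x$window[2L]))
  cat("  rho:", paste(sprintf("%.3f", utils::head(x$rho, 5)), collapse = " "),
      if (length(x$rho) > 5) "...\n" else "\n")
  if (!is.na(x$selected)) {
    cat(sprintf("  selected component %d (sign %+d)\n", x$selected, x$sign))
  }
  invisible(x)
}

#' Activation patterns of CCA components
#'
#' The spatial filter `w` extracts a component; the corresponding pattern
#' `Cov(X) w` describes how that component projects back onto the channels
#' (taking the noise covariance into account). Patterns are column-scaled to
#' unit norm for reporting, making them invariant to the data's overall
#' scale.
#'
#' @param result a fitted `cca_result`
#' @param X optional channels x samples data matrix; defaults to the
#'   covariance stored at fit time
#' @return channels x components matrix of unit-norm patterns
#' @export
activation_patterns <- function(result, X = NULL) {
  stopifnot(inherits(result, "cca_result"))
  C <- if (is.null(X)) {
    result$Cxx
  } else {
    stopifnot(is.matrix(X), nrow(X) == nrow(result$Wx))
    Xc <- X - rowMeans(X)
    tcrossprod(Xc) / (ncol(X) - 1L)
  }
  A <- C %*% result$Wx
  sweep(A, 2L, sqrt(colSums(A^2)), "/")
}

#' Select the SEP component and standardize its sign
#'
#' Inspects the top `n_top` components (by canonical correlation). With a
#' template pattern, picks the component whose unit activation pattern has
#' the largest absolute cosine similarity to it (a proxy for the visual
#' identification of the tangential-dipole pattern); without one, picks the
#' largest canonical correlation (ties broken toward the lower index). The
#' sign factor is chosen so that the component's grand-average waveform is
#' negative at the N20 latency, making the N20 a negative peak by
#' convention.
#'
#' @param result a fitted `cca_result`
#' @param template_pattern optional channel vector to match patterns against
#' @param n20_latency latency (ms) at which the average must be negative
#' @param n_top number of leading components inspected (default 4)
#' @param min_similarity minimal absolute cosine similarity when matching a
#'   template (default 0.5)
#' @return the `cca_result` with `selected` and `sign` set
#' @export
select_and_standardize <- function(result, template_pattern = NULL,
                                   n20_latency = 20, n_top = 4,
                                   min_similarity = 0.5) {
  stopifnot(inherits(result, "cca_result"))
  k <- min(n_top, ncol(result$Wx))
  if (!is.null(template_pattern)) {
    stopifnot(length(template_pattern) == nrow(result$patterns))
    sims <- vapply(seq_len(k), function(j) {
      abs(cosine_similarity(result$patterns[, j], template_pattern))
    }, numeric(1))
    if (all(sims < min_similarity)) {
      stop(sprintf("no component matches the template pattern (max |cos| = %.3f < %.2f)",
                   max(sims), min_similarity), call. = FALSE)
    }
    sel <- which.max(sims)
  } else {
    sel <- which.max(result$rho[seq_len(k)])   # which.max: lowest index wins ties
  }
  at <- which.min(abs(result$times - n20_latency))
  val <- result$mean_waveforms[sel, at]
  result$selected <- as.integer(sel)
  result$sign <- if (val > 0) -1 else 1
  result
}

#' Project epochs through the selected CCA filter
#'
#' Applies `sign * w_x' x_i` to every trial over the full epoch length. The
#' same filter may be applied to differently filtered versions of the data
#' (e.g. the 0.5-45 Hz stream for the N140, or raw pre-stimulus segments for
#' alpha), as long as the channel set matches.
#'
#' @param epochs a `sep_epochs` containing at least the channels the filter
#'   was trained on
#' @param result a `cca_result` with a selected component
#' @param component optional component index overriding `result$selected`
#' @return a `sep_epochs` with a single channel `"CCA"`
#' @export
project_trials <- function(epochs, result, component = NULL) {
  stopifnot(inherits(epochs, "sep_epochs"), inherits(result, "cca_result"))
  sel <- if (is.null(component)) result$selected else as.integer(component)
  if (is.na(sel)) stop("no component selected: run select_and_standardize() first",
                       call. = FALSE)
  chi <- match(result$channels, epochs$ch_names)
  if (anyNA(chi)) stop("epochs lack channels the CCA filter was trained on",
                       call. = FALSE)
  w <- result$sign * result$Wx[, sel]
  n_trials <- dim(epochs$data)[1L]
  n_samp <- dim(epochs$data)[3L]
  out <- array(0, dim = c(n_trials, 1L, n_samp))
  for (i in seq_len(n_trials)) {
    out[i, 1L, ] <- crossprod(w, epochs$data[i, chi, ])
  }
  new_epochs(out, times = epochs$times, srate = epochs$srate,
             ch_names = "CCA", info = epochs$info)
}
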
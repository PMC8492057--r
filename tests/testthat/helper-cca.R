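# small toy epochs: one source with per-trial gain, fixed mixing, iid noise
toy_epochs <- function(n_trials = 40, n_ch = 2, noise = 0.3, seed = 1,
                       srate = 1000, gain_sd = 0.3) {
  set.seed(seed)
  tmpl <- sep_template(srate, length_ms = 100)
  times <- seq(0, 100, by = 1000 / srate)
  mix <- seq_len(n_ch)
  mix <- mix / sqrt(sum(mix^2))
  gains <- 1 + gain_sd * rnorm(n_trials)
  dat <- array(0, dim = c(n_trials, n_ch, length(times)))
  for (i in seq_len(n_trials)) {
    dat[i, , ] <- mix %o% (gains[i] * tmpl) +
      noise * matrix(rnorm(n_ch * length(times)), n_ch)
  }
  list(epochs = new_epochs(dat, times, srate, paste0("C", seq_len(n_ch))),
       mix = mix, gains = gains, tmpl = tmpl)
}

# brute-force oracle: scan w_x angles; for each, the best correlation with
# any filtered version of Y has the closed form of a regression R
brute_force_cca <- function(epochs, window = c(5, 80), step = 1e-3) {
  ti <- which(epochs$times >= window[1] & epochs$times <= window[2])
  n <- dim(epochs$data)[1L]
  X <- do.call(cbind, lapply(seq_len(n), function(i) epochs$data[i, , ti]))
  xbar <- Reduce(`+`, lapply(seq_len(n), function(i) epochs$data[i, , ti])) / n
  Y <- matrix(xbar, nrow(X), ncol(X))
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  P <- crossprod(Yc, solve(tcrossprod(Yc) + 1e-12 * diag(nrow(Yc)))) %*% Yc
  thetas <- seq(0, pi, by = step)
  best <- c(theta = NA, rho = -1)
  for (th in thetas) {
    u <- as.numeric(crossprod(c(cos(th), sin(th)), Xc))
    r2 <- sum(u * (P %*% u)) / sum(u * u)
    if (sqrt(r2) > best["rho"]) best <- c(theta = th, rho = sqrt(r2))
  }
  best
}

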
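#' Configuration of the synthetic SEP experiment generator
#'
#' Bundles every parameter of the generative model. The scalp voltage of the
#' evoked response follows the forward model `U = I * N_neurons * LF`: `I` is
#' the per-trial sum of local post-synaptic currents (modulated by a latent
#' excitability process), `N_neurons` the recruited population (modulated by
#' presented stimulus intensity), and `LF` a fixed lead-field gain that maps
#' the source to the scalp through a dipolar spatial pattern.
#'
#' The latent excitability is a stationary AR(1) process (unit marginal SD by
#' default). It couples negatively into the alpha-band amplitude envelope
#' (`alpha_coupling`, log scale: high alpha marks low excitability),
#' negatively into the post-synaptic current `I` (`epsc_coupling`: high
#' excitability yields a smaller evoked current here, so larger alpha goes
#' with a larger, i.e. more negative, N20 at fixed intensity), and negatively
#' into the observer's decision criterion (`criterion_coupling`: high
#' excitability lowers the threshold for reporting "strong", so high alpha
#' biases reports toward "weak").
#'
#' @param n_subjects subjects per simulated experiment
#' @param n_trials stimuli per subject (default 1000)
#' @param n_blocks stimulation blocks (default 5)
#' @param srate sampling rate in Hz (default 5000)
#' @param n_channels scalp EEG channels (default 32)
#' @param isi_low,isi_high inter-stimulus interval bounds in ms, drawn
#'   uniformly (defaults 1463 / 1563, mean 1513 ms)
#' @param intensity_levels named gains for the two intensities; the default
#'   strong/weak ratio of 1.2 mirrors a just-noticeable step above a clearly
#'   perceptible weak stimulus
#' @param pattern_sep unit-norm channel vector of the SEP source (default: a
#'   tangential-dipole-like pattern on an abstract spherical montage)
#' @param pattern_alpha channel vector of the alpha source (default equals
#'   `pattern_sep`: alpha and SEP share generators)
#' @param epsc_gain baseline post-synaptic current scale `I` in uV (default 3,
#'   a typical single-trial N20 magnitude)
#' @param n_neurons_gain population multiplier applied on top of
#'   `intensity_levels`
#' @param leadfield_gain scalar `LF`
#' @param excitability_ar_coef AR(1) coefficient of the excitability latent
#'   (|coef| < 1)
#' @param excitability_sd marginal SD of the excitability latent
#' @param alpha_coupling signed coefficient excitability -> log alpha envelope
#'   (default -0.5)
#' @param alpha_base baseline of the log alpha envelope (default log(2) uV)
#' @param alpha_noise_sd trial-level log-normal noise of the alpha envelope
#' @param alpha_freq alpha carrier frequency in Hz
#' @param epsc_coupling signed coefficient excitability -> `I`
#'   (default -0.15: higher excitability, smaller evoked current)
#' @param observer_dprime sensitivity of the SDT observer (default 1.14; the
#'   staircase calibration in the emulated design targets 1.5 but realized
#'   runs sit near 1.14)
#' @param criterion_base baseline decision criterion (default 0.01)
#' @param criterion_coupling signed coefficient excitability -> criterion
#'   (default -0.09, sized so the extreme alpha-quintile criterion contrast is
#'   reliably detectable in a 12-subject experiment; see the methods vignette)
#' @param noise_sd per-channel SD of the spatially mixed pink background
#'   noise, in uV (default 0.4)
#' @param cnap_gain peripheral nerve (CNAP) peak scale in uV
#' @param cmap_gain muscle (CMAP) response scale in mV
#' @param cmap_response_coupling optional thumb-twitch path: weight of the
#'   (z-scored) CMAP amplitude on the observer's evidence (default 0, off)
#' @param miss_rate probability of an omitted behavioral response
#' @param n140_scale depth in uV of an optional late negative component at
#'   150 ms (default 0, off; used to exercise the N140 window measure)
#' @param n20_meas_sd,alpha_meas_sd measurement noise used by the fast
#'   trial-level simulator [simulate_trial_table()] to emulate the extraction
#'   fidelity of the full EEG pipeline (N20 recovery r ~ 0.8, alpha rank
#'   correlation ~ 0.9)
#' @param seed default master seed carried with the config
#' @return object of class `generator_config`
#' @seealso [generate_experiment()], [simulate_trial_table()]
#' @export
generator_config <- function(n_subjects = 12L,
                             n_trials = 1000L,
                             n_blocks = 5L,
                             srate = 5000,
                             n_channels = 32L,
                             isi_low = 1463,
                             isi_high = 1563,
                             intensity_levels = c(weak = 1, strong = 1.2),
                             pattern_sep = NULL,
                             pattern_alpha = NULL,
                             epsc_gain = 3,
                             n_neurons_gain = 1,
                             leadfield_gain = 1,
                             excitability_ar_coef = 0.8,
                             excitability_sd = 1,
                             alpha_coupling = -0.5,
                             alpha_base = log(2),
                             alpha_noise_sd = 0.4,
                             alpha_freq = 10,
                             epsc_coupling = -0.15,
                             observer_dprime = 1.14,
                             criterion_base = 0.01,
                             criterion_coupling = -0.09,
                             noise_sd = 0.4,
                             cnap_gain = 5,
                             cmap_gain = 1,
                             cmap_response_coupling = 0,
                             miss_rate = 0.02,
                             n140_scale = 0,
                             n20_meas_sd = 0.34,
                             alpha_meas_sd = 0.31,
                             seed = 1L) {
  if (n_trials < 2) {
    stop("invalid config: n_trials must be >= 2", call. = FALSE)
  }
  if (!(isi_low < isi_high)) {
    stop("invalid config: isi_low must be < isi_high", call. = FALSE)
  }
  if (abs(excitability_ar_coef) >= 1) {
    stop("nonstationary excitability process: |excitability_ar_coef| must be < 1",
         call. = FALSE)
  }
  stopifnot(
    srate > 0, n_channels >= 2,
    all(is.finite(c(intensity_levels, epsc_gain, n_neurons_gain,
                    leadfield_gain, noise_sd))),
    all(c("weak", "strong") %in% names(intensity_levels))
  )
  if (is.null(pattern_sep)) {
    pattern_sep <- tangential_pattern(n_channels)
  }
  pattern_sep <- as.numeric(pattern_sep)
  if (length(pattern_sep) != n_channels || all(pattern_sep == 0)) {
    stop("pattern_sep must be a non-zero vector of length n_channels",
         call. = FALSE)
  }
  pattern_sep <- pattern_sep / sqrt(sum(pattern_sep^2))
  if (is.null(pattern_alpha)) pattern_alpha <- pattern_sep
  pattern_alpha <- as.numeric(pattern_alpha)
  if (length(pattern_alpha) != n_channels || all(pattern_alpha == 0)) {
    stop("pattern_alpha must be a non-zero vector of length n_channels",
         call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    n_blocks = as.integer(n_blocks), srate = srate,
    n_channels = as.integer(n_channels),
    isi_low = isi_low, isi_high = isi_high,
    intensity_levels = intensity_levels,
    pattern_sep = pattern_sep, pattern_alpha = pattern_alpha,
    epsc_gain = epsc_gain, n_neurons_gain = n_neurons_gain,
    leadfield_gain = leadfield_gain,
    excitability_ar_coef = excitability_ar_coef,
    excitability_sd = excitability_sd,
    alpha_coupling = alpha_coupling, alpha_base = alpha_base,
    alpha_noise_sd = alpha_noise_sd, alpha_freq = alpha_freq,
    epsc_coupling = epsc_coupling,
    observer_dprime = observer_dprime,
    criterion_base = criterion_base,
    criterion_coupling = criterion_coupling,
    noise_sd = noise_sd,
    cnap_gain = cnap_gain, cmap_gain = cmap_gain,
    cmap_response_coupling = cmap_response_coupling,
    miss_rate = miss_rate, n140_scale = n140_scale,
    n20_meas_sd = n20_meas_sd, alpha_meas_sd = alpha_meas_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d subjects x %d trials (%d blocks), %g Hz, %d EEG channels\n",
              x$n_subjects, x$n_trials, x$n_blocks, x$srate, x$n_channels))
  cat(sprintf("  ISI U[%g, %g] ms; intensity gains weak=%g strong=%g\n",
              x$isi_low, x$isi_high,
              x$intensity_levels[["weak"]], x$intensity_levels[["strong"]]))
  cat(sprintf("  observer d'=%g, c0=%g, criterion_coupling=%g\n",
              x$observer_dprime, x$criterion_base, x$criterion_coupling))
  invisible(x)
}

#' Abstract spherical montage and a tangential dipole pattern
#'
#' Channel positions are Fibonacci-spiral points on the upper unit
#' hemisphere (no real cap geometry is intended). The SEP pattern is the
#' quasi-static potential of a tangential dipole just below the surface,
#' yielding the characteristic frontal-positive / parietal-negative bipolar
#' topography of the N20-P35 complex.
#'
#' @param n_channels number of scalp channels
#' @return unit-norm numeric vector of length `n_channels`
#' @export
tangential_pattern <- function(n_channels) {
  pos <- montage_positions(n_channels)
  src <- c(0.35, -0.25, 0.75)
  src <- src / sqrt(sum(src^2)) * 0.85   # dipole slightly below the scalp
  mom <- c(1, 1, 0)
  mom <- mom / sqrt(sum(mom^2))          # tangential moment
  d <- sweep(pos, 2, src)                # channel - source vectors
  r <- sqrt(rowSums(d^2))
  v <- as.numeric(d %*% mom) / r^3
  v / sqrt(sum(v^2))
}

#' @rdname tangential_pattern
#' @export
montage_positions <- function(n_channels) {
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels                  # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Generate the pseudo-randomized stimulus sequence
#'
#' Intensity labels are balanced to an exact 50/50 split (up to one trial
#' when `n_trials` is odd), shuffled, and forced to start with a weak
#' stimulus as the perceptual anchor. Inter-stimulus intervals are drawn
#' uniformly from `[isi_low, isi_high]` ms and trials are assigned to
#' consecutive blocks.
#'
#' @param config a [generator_config()]
#' @param seed integer seed (default derived from `config$seed`)
#' @return data.frame with columns `trial`, `sample` (onset sample index),
#'   `time_ms`, `label` ("weak"/"strong"), `block`
#' @export
generate_stimulus_sequence <- function(config, seed = split_seed(config$seed, "sequence")) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_trials
  if (n < 2) stop("invalid config: n_trials must be >= 2", call. = FALSE)
  set.seed(seed)
  n_strong <- n %/% 2L
  labels <- sample(c(rep("strong", n_strong), rep("weak", n - n_strong)))
  # every sequence starts with a weak stimulus
  if (labels[1L] != "weak") {
    j <- which(labels == "weak")[1L]
    labels[c(1L, j)] <- labels[c(j, 1L)]
  }
  isi <- stats::runif(n - 1L, config$isi_low, config$isi_high)
  onset_ms <- 1000 + c(0, cumsum(isi))   # 1 s pre-roll before the first event
  block <- cut(seq_len(n), breaks = config$n_blocks, labels = FALSE)
  data.frame(
    trial = seq_len(n),
    sample = ms_to_sample(onset_ms, config$srate) + 1L,
    time_ms = onset_ms,
    label = labels,
    block = block,
    stringsAsFactors = FALSE
  )
}

#' Simulate the per-trial latent state
#'
#' Draws the excitability AR(1) trajectory, the log-normal alpha envelope
#' coupled to it, and the evoked-response gain through the voltage model
#' `gain = I * N_neurons * LF` with `I = epsc_gain * (1 + epsc_coupling *
#' excitability)` and `N_neurons = n_neurons_gain * intensity gain`.
#'
#' @param config a [generator_config()]
#' @param events sequence from [generate_stimulus_sequence()]
#' @param seed integer seed
#' @return data.frame with `trial`, `excitability`, `alpha_env`, `epsc`,
#'   `n_neurons`, `sep_gain`
#' @export
simulate_trial_latents <- function(config, events,
                                   seed = split_seed(config$seed, "latents")) {
  stopifnot(inherits(config, "generator_config"), is.data.frame(events))
  if (abs(config$excitability_ar_coef) >= 1) {
    stop("nonstationary excitability process: |excitability_ar_coef| must be < 1",
         call. = FALSE)
  }
  n <- nrow(events)
  set.seed(seed)
  phi <- config$excitability_ar_coef
  s <- config$excitability_sd
  if (s == 0) {
    exc <- rep(0, n)
  } else {
    innov <- stats::rnorm(n, 0, s * sqrt(1 - phi^2))
    innov[1L] <- stats::rnorm(1L, 0, s)   # start at the stationary law
    exc <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  alpha_env <- exp(config$alpha_base + config$alpha_coupling * exc +
                     stats::rnorm(n, 0, config$alpha_noise_sd))
  epsc <- config$epsc_gain * (1 + config$epsc_coupling * exc)
  n_neurons <- config$n_neurons_gain *
    unname(config$intensity_levels[events$label])
  data.frame(
    trial = events$trial,
    excitability = exc,
    alpha_env = alpha_env,
    epsc = epsc,
    n_neurons = n_neurons,
    sep_gain = epsc * n_neurons * config$leadfield_gain
  )
}

#' Unit SEP template waveform
#'
#' Stereotyped N20-P35 complex: support restricted to 5-80 ms post-stimulus,
#' negative extremum at 20 ms (normalized to -1), positive deflection at
#' 35 ms. Optionally adds a late negative component at 150 ms of depth
#' `n140_scale` (not gain-normalized).
#'
#' @param srate sampling rate in Hz
#' @param length_ms template duration from stimulus onset
#' @param n140_scale depth of the optional late negativity in uV
#' @return numeric vector of `length_ms/1000*srate + 1` samples starting at
#'   0 ms
#' @export
sep_template <- function(srate, length_ms = 250, n140_scale = 0) {
  t <- seq(0, length_ms, by = 1000 / srate)
  w <- -exp(-((t - 20)^2) / (2 * 3^2)) + 0.65 * exp(-((t - 35)^2) / (2 * 7^2))
  w[t < 5 | t > 80] <- 0
  w <- w / abs(min(w))                       # negative extremum exactly -1
  if (n140_scale != 0) {
    w <- w - n140_scale * exp(-((t - 150)^2) / (2 * 15^2))
  }
  w
}

cnap_template <- function(srate, length_ms = 30) {
  t <- seq(0, length_ms, by = 1000 / srate)
  w <- exp(-((t - 7)^2) / (2 * 0.8^2))       # afferent volley, peak at 7 ms
  w / max(w)
}

cmap_template <- function(srate, length_ms = 40) {
  t <- seq(0, length_ms, by = 1000 / srate)
  w <- -exp(-((t - 8)^2) / (2 * 1.2^2)) + 0.8 * exp(-((t - 14)^2) / (2 * 2^2))
  w / abs(min(w))                            # biphasic thumb-muscle response
}

#' Spatially mixed pink noise
#'
#' `n_channels` independent 1/f-amplitude noise series (FFT-shaped white
#' noise, unit variance) mixed through a random orthogonal matrix, giving a
#' spatially and temporally coloured EEG noise floor.
#' @keywords internal
pink_noise_matrix <- function(n_channels, n_samples, srate) {
  # synthesize at an even 2-3-5-smooth length (mixed-radix FFT cost), truncate
  nfft <- 2L * stats::nextn(ceiling(n_samples / 2), c(2L, 3L, 5L))
  f <- seq(0, srate / 2, length.out = nfft %/% 2L + 1L)
  shape <- 1 / sqrt(pmax(f, 1))              # 1 Hz flattening floor
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    spec <- stats::fft(stats::rnorm(nfft))
    idx <- seq_along(shape)
    spec[idx] <- spec[idx] * shape
    spec[(nfft %/% 2L + 2L):nfft] <- Conj(spec[rev(seq(2L, nfft %/% 2L))])
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n_samples)] / nfft
    out[ch, ] <- x / stats::sd(x)
  }
  mix <- qr.Q(qr(matrix(stats::rnorm(n_channels^2), n_channels)))
  mix %*% out
}

#' Render the continuous multichannel recording
#'
#' Projects the gain-scaled SEP template through the SEP spatial pattern,
#' adds an alpha carrier whose pre-stimulus amplitude envelope follows the
#' per-trial latent, adds spatially mixed pink background noise, and appends
#' the two peripheral channels: CNAP (nerve volley, peak near 7 ms, scales
#' with presented intensity only) and CMAP (biphasic muscle response,
#' 5-20 ms, in mV, scales with presented intensity only).
#'
#' @param config a [generator_config()]
#' @param events stimulus sequence
#' @param latents from [simulate_trial_latents()]
#' @param seed integer seed
#' @return object of class `sep_recording`
#' @export
render_recording <- function(config, events, latents,
                             seed = split_seed(config$seed, "recording")) {
  stopifnot(inherits(config, "generator_config"),
            nrow(events) == nrow(latents))
  srate <- config$srate
  tmpl <- sep_template(srate, n140_scale = config$n140_scale)
  if (length(tmpl) / srate * 1000 > min(diff(events$time_ms))) {
    warning("SEP template longer than the shortest ISI: adjacent responses overlap")
  }
  n_samples <- max(events$sample) + ms_to_sample(700, srate)
  set.seed(seed)

  # source-level time courses ------------------------------------------------
  sep_sig <- numeric(n_samples)
  ktmpl <- length(tmpl)
  for (i in seq_len(nrow(events))) {
    s0 <- events$sample[i]
    idx <- s0:min(s0 + ktmpl - 1L, n_samples)
    sep_sig[idx] <- sep_sig[idx] + latents$sep_gain[i] * tmpl[seq_along(idx)]
  }

  tt <- (seq_len(n_samples) - 1L) / srate
  carrier <- sin(2 * pi * config$alpha_freq * tt + stats::runif(1, 0, 2 * pi))
  # piecewise-constant envelope: each trial's latent governs the stretch up
  # to its own onset (boundaries at inter-onset midpoints), so the
  # pre-stimulus window of trial t carries alpha_env[t]
  bounds <- c(0L, ms_to_sample((events$time_ms[-1] + events$time_ms[-nrow(events)]) / 2,
                               srate), n_samples)
  env <- numeric(n_samples)
  for (i in seq_len(nrow(events))) {
    env[(bounds[i] + 1L):bounds[i + 1L]] <- latents$alpha_env[i]
  }
  if (bounds[nrow(events) + 1L] < n_samples) {
    env[(bounds[nrow(events) + 1L] + 1L):n_samples] <-
      latents$alpha_env[nrow(events)]
  }
  alpha_sig <- env * carrier

  # scalp channels -----------------------------------------------------------
  eeg <- config$pattern_sep %o% sep_sig + config$pattern_alpha %o% alpha_sig
  if (config$noise_sd > 0) {
    eeg <- eeg + config$noise_sd *
      pink_noise_matrix(config$n_channels, n_samples, srate)
  }

  # peripheral channels ------------------------------------------------------
  ct <- cnap_template(srate)
  mt <- cmap_template(srate)
  cnap <- numeric(n_samples)
  cmap <- numeric(n_samples)
  gint <- unname(config$intensity_levels[events$label])
  for (i in seq_len(nrow(events))) {
    s0 <- events$sample[i]
    ic <- s0:min(s0 + length(ct) - 1L, n_samples)
    cnap[ic] <- cnap[ic] + config$cnap_gain * gint[i] * ct[seq_along(ic)]
    im <- s0:min(s0 + length(mt) - 1L, n_samples)
    cmap[im] <- cmap[im] + config$cmap_gain * gint[i] * mt[seq_along(im)]
  }
  if (config$noise_sd > 0) {
    cnap <- cnap + stats::rnorm(n_samples, 0, 0.1 * config$cnap_gain * config$noise_sd)
    cmap <- cmap + stats::rnorm(n_samples, 0, 0.02 * config$cmap_gain)
  }

  ch_names <- c(sprintf("EEG%03d", seq_len(config$n_channels)), "CNAP", "CMAP")
  new_recording(
    data = rbind(eeg, cnap, cmap),
    srate = srate,
    ch_names = ch_names,
    eeg_channels = ch_names[seq_len(config$n_channels)],
    events = events
  )
}

#' Simulate the observer's intensity reports
#'
#' The internal evidence is `d' * [stimulus == strong]` plus standard normal
#' noise (plus, optionally, a thumb-twitch contribution proportional to the
#' trial's intensity gain); the report is "strong" whenever the evidence
#' exceeds the trial's criterion `criterion_base + criterion_coupling *
#' excitability`. A small fraction of trials (`miss_rate`) receives no
#' response (NA).
#'
#' @param latents from [simulate_trial_latents()]
#' @param events stimulus sequence
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return character vector of length `n_trials`: "strong", "weak" or NA
#' @export
simulate_responses <- function(latents, events, config,
                               seed = split_seed(config$seed, "responses")) {
  stopifnot(nrow(latents) == nrow(events))
  n <- nrow(events)
  set.seed(seed)
  evidence <- config$observer_dprime * (events$label == "strong") +
    stats::rnorm(n)
  if (config$cmap_response_coupling != 0) {
    gint <- unname(config$intensity_levels[events$label])
    evidence <- evidence + config$cmap_response_coupling * ztrans(gint)
  }
  criterion <- config$criterion_base +
    config$criterion_coupling * latents$excitability +
    config$observer_dprime / 2        # unbiased point between the two means
  resp <- ifelse(evidence > criterion, "strong", "weak")
  resp[stats::runif(n) < config$miss_rate] <- NA_character_
  resp
}

#' Generate one complete synthetic subject
#'
#' Composes [generate_stimulus_sequence()], [simulate_trial_latents()],
#' [render_recording()] and [simulate_responses()] under per-stage child
#' seeds derived from `seed`.
#'
#' @param config a [generator_config()]
#' @param seed master seed for this subject (default `config$seed`)
#' @return object of class `sep_dataset`: list with `recording`, `events`,
#'   `latents`, `responses` and the `config` snapshot
#' @export
generate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  events <- generate_stimulus_sequence(config, split_seed(seed, "sequence"))
  latents <- simulate_trial_latents(config, events, split_seed(seed, "latents"))
  recording <- render_recording(config, events, latents,
                                split_seed(seed, "recording"))
  responses <- simulate_responses(latents, events, config,
                                  split_seed(seed, "responses"))
  structure(
    list(recording = recording, events = events, latents = latents,
         responses = responses, config = config, seed = seed),
    class = "sep_dataset"
  )
}

#' @export
print.sep_dataset <- function(x, ...) {
  cat("<sep_dataset>\n")
  cat(sprintf("  %d trials, %d channels, %g Hz, %.1f s\n",
              nrow(x$events), nrow(x$recording$data), x$recording$srate,
              ncol(x$recording$data) / x$recording$srate))
  invisible(x)
}

#' Fast trial-level simulation of a multi-subject experiment
#'
#' Draws, for every subject, the stimulus sequence, the latent state and the
#' behavioral responses from the same generative model as
#' [generate_experiment()], but replaces the EEG rendering + extraction path
#' by direct measurements with calibrated noise: the measured N20 amplitude
#' is `-sep_gain` plus Gaussian noise (`n20_meas_sd`), and the measured log
#' alpha amplitude is `log(alpha_env)` plus Gaussian noise (`alpha_meas_sd`),
#' emulating the recovery fidelity of the full pipeline. Intended for
#' resampling studies (power, type-I error, sign recovery) where rendering
#' hours of multichannel EEG would dominate the cost without informing the
#' statistics under test.
#'
#' @param config a [generator_config()]
#' @param seed master experiment seed
#' @return a trial table: one row per trial with `subject`, `trial`,
#'   `intensity`, `response`, `n20_amp`, `alpha_log`, `cnap_amp`, `cmap_amp`
#'   and the ground-truth latents
#' @export
simulate_trial_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sseed <- split_seed(seed, s)
    events <- generate_stimulus_sequence(config, split_seed(sseed, "sequence"))
    latents <- simulate_trial_latents(config, events, split_seed(sseed, "latents"))
    responses <- simulate_responses(latents, events, config,
                                    split_seed(sseed, "responses"))
    set.seed(split_seed(sseed, "measurement"))
    n <- nrow(events)
    gint <- unname(config$intensity_levels[events$label])
    out[[s]] <- data.frame(
      subject = s,
      trial = events$trial,
      block = events$block,
      intensity = events$label,
      response = responses,
      n20_amp = -latents$sep_gain + stats::rnorm(n, 0, config$n20_meas_sd),
      alpha_log = log(latents$alpha_env) +
        stats::rnorm(n, 0, config$alpha_meas_sd),
      cnap_amp = config$cnap_gain * gint +
        stats::rnorm(n, 0, 0.05 * config$cnap_gain),
      cmap_amp = config$cmap_gain * gint +
        stats::rnorm(n, 0, 0.02 * config$cmap_gain),
      excitability = latents$excitability,
      alpha_env = latents$alpha_env,
      sep_gain = latents$sep_gain,
      valid = !is.na(responses),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
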
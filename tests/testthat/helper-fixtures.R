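# Shared fixtures: small, fast configurations and a cached rendered subject.
# Everything is generated in code at test time; the reduced sampling rate,
# channel count and trial numbers keep single tests in the seconds range
# while exercising the same code paths as full-size data.

small_config <- function(...) {
  args <- list(n_trials = 80L, srate = 1000, n_channels = 12L,
               n_blocks = 4L, seed = 42L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(generator_config, args)
}

# one rendered + analyzed subject, computed once per test run
cached_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(n_trials = 120L)
      ds <- generate_experiment(cfg)
      cache <<- list(config = cfg, dataset = ds,
                     analysis = analyze_subject(ds))
    }
    cache
  }
})

# noise-free single-source dataset for exact-recovery checks
noiseless_config <- function(...) {
  generator_config(n_trials = 20L, srate = 1000, n_channels = 8L,
                   n_blocks = 2L, noise_sd = 0, alpha_base = -Inf,
                   alpha_noise_sd = 0, miss_rate = 0, seed = 5L, ...)
}

# sinusoidal multichannel epochs with a known source vector
sinusoid_epochs <- function(n_trials, freq, amp, srate = 1000,
                            times = seq(-600, 100, by = 1000 / srate),
                            phases = seq_len(n_trials)) {
  dat <- array(0, dim = c(n_trials, 2L, length(times)))
  for (i in seq_len(n_trials)) {
    dat[i, 1L, ] <- amp * sin(2 * pi * freq * times / 1000 + phases[i])
  }
  new_epochs(dat, times, srate, c("SRC", "OFF"))
}
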
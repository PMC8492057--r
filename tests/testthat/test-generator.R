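test_that("stimulus sequences have the designed count, blocks, balance and anchor", {
  cfg <- generator_config(seed = 3L)   # full-size defaults: 1000 trials, 5 blocks
  ev <- generate_stimulus_sequence(cfg)
  expect_equal(nrow(ev), 1000L)
  expect_equal(as.integer(table(ev$block)), rep(200L, 5L))
  expect_equal(ev$label[1L], "weak")
  expect_lte(abs(sum(ev$label == "strong") - sum(ev$label == "weak")), 1L)
  # balance and anchor hold for every seed
  for (s in 1:20) {
    ev2 <- generate_stimulus_sequence(small_config(), seed = s)
    expect_equal(ev2$label[1L], "weak")
    expect_lte(abs(sum(ev2$label == "strong") - sum(ev2$label == "weak")), 1L)
  }
  expect_error(generator_config(n_trials = 1L), "n_trials")
})

test_that("inter-stimulus intervals are uniform with the designed mean", {
  cfg <- generator_config(seed = 8L)
  isi <- unlist(lapply(1:101, function(s) {
    diff(generate_stimulus_sequence(cfg, seed = s)$time_ms)
  }))                                   # > 1e5 draws
  expect_gt(length(isi), 1e5)
  expect_lt(abs(mean(isi) - 1513), 2)
  expect_gte(min(isi), 1463)
  expect_lte(max(isi), 1563)
})

test_that("latent state follows the voltage model exactly and degenerates correctly", {
  cfg <- small_config()
  ev <- generate_stimulus_sequence(cfg)
  lat <- simulate_trial_latents(cfg, ev)
  # conservation: stored gain == I * N_neurons * LF recomputed from latents
  expect_identical(lat$sep_gain, lat$epsc * lat$n_neurons * cfg$leadfield_gain)

  # excitability_sd = 0: gain depends on intensity only
  cfg0 <- small_config(excitability_sd = 0)
  lat0 <- simulate_trial_latents(cfg0, ev)
  expect_equal(as.numeric(tapply(lat0$sep_gain, ev$label, stats::sd)), c(0, 0))
  expect_setequal(round(unique(lat0$sep_gain), 10),
                  round(cfg0$epsc_gain * cfg0$intensity_levels, 10))

  expect_error(generator_config(excitability_ar_coef = 1), "nonstationar")
})

test_that("coupling signs propagate: alpha tracks excitability and gain as designed", {
  cfg <- generator_config(n_trials = 100000L, srate = 1000, n_channels = 8L,
                          seed = 21L)
  ev <- generate_stimulus_sequence(cfg)
  lat <- simulate_trial_latents(cfg, ev)
  # alpha_coupling < 0: alpha envelope anti-correlates with excitability
  expect_lt(cor(log(lat$alpha_env), lat$excitability), -0.5)
  # alpha_coupling < 0 and epsc_coupling < 0: at fixed intensity, high alpha
  # goes with a high (more negative N20) gain magnitude
  weak <- ev$label == "weak"
  expect_gt(cor(log(lat$alpha_env[weak]), lat$sep_gain[weak]), 0.3)

  # alpha_coupling = 0 decouples the envelope
  cfgz <- generator_config(n_trials = 100000L, srate = 1000, n_channels = 8L,
                           alpha_coupling = 0, seed = 22L)
  latz <- simulate_trial_latents(cfgz, ev)
  expect_lt(abs(cor(log(latz$alpha_env), latz$excitability)), 0.02)
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- small_config(n_trials = 30L)
  a <- generate_experiment(cfg, seed = 9L)
  b <- generate_experiment(cfg, seed = 9L)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$responses, b$responses)
  c <- generate_experiment(cfg, seed = 10L)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("SEP template has its negative extremum of -1 at 20 ms with 5-80 ms support", {
  for (fs in c(1000, 5000)) {
    tmpl <- sep_template(fs)
    t <- seq(0, by = 1000 / fs, length.out = length(tmpl))
    expect_equal(min(tmpl), -1)
    expect_lt(abs(t[which.min(tmpl)] - 20), 1)
    expect_true(all(tmpl[t < 5 | t > 80] == 0))
    expect_gt(max(tmpl[t > 25 & t < 45]), 0)   # positive deflection near 35 ms
  }
})

test_that("noiseless rendering inverts exactly through the pattern pseudo-inverse", {
  cfg <- noiseless_config()
  ev <- generate_stimulus_sequence(cfg)
  lat <- simulate_trial_latents(cfg, ev)
  rec <- render_recording(cfg, ev, lat)
  ep <- epoch_data(rec, c(0, 250))
  tmpl <- sep_template(cfg$srate)
  w <- cfg$pattern_sep / sum(cfg$pattern_sep^2)   # pseudo-inverse of the column
  chi <- match(rec$eeg_channels, rec$ch_names)
  for (i in c(1L, 7L, 20L)) {
    proj <- as.numeric(crossprod(w, ep$data[i, chi, ]))
    expect_equal(proj[seq_along(tmpl)], lat$sep_gain[i] * tmpl,
                 tolerance = 1e-10)
  }
})

test_that("peripheral channels scale monotonically with intensity and gain ratio", {
  cfg <- small_config()
  ds <- cached_subject()$dataset
  ep <- epoch_data(ds$recording, c(-25, 25))
  ch <- match("CNAP", ds$recording$ch_names)
  peak <- apply(ep$data[, ch, ep$times > 4 & ep$times < 10], 1L, max)
  m <- tapply(peak, ep$info$label, mean)
  expect_gt(m[["strong"]], m[["weak"]])

  # population d' of the CNAP intensity separation grows with the gain ratio
  dprime_cnap <- function(ratio) {
    cfgr <- small_config(intensity_levels = c(weak = 1, strong = ratio),
                         n_trials = 400L)
    tt <- simulate_trial_table(cfgr, seed = 77L)
    m <- tapply(tt$cnap_amp, tt$intensity, mean)
    s <- tapply(tt$cnap_amp, tt$intensity, stats::sd)
    (m[["strong"]] - m[["weak"]]) / sqrt(mean(s^2))
  }
  d <- vapply(c(1.1, 1.3, 1.6), dprime_cnap, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("the SDT observer is self-consistent and matches the closed-form accuracy", {
  cfg <- generator_config(n_trials = 100000L, srate = 1000, n_channels = 8L,
                          excitability_sd = 0, criterion_base = 0,
                          observer_dprime = 1.5, miss_rate = 0, seed = 31L)
  ev <- generate_stimulus_sequence(cfg)
  lat <- simulate_trial_latents(cfg, ev)
  resp <- simulate_responses(lat, ev, cfg)
  s <- sdt_from_trials(ev$label, resp)
  expect_equal(s$d_prime, 1.5, tolerance = 0.03 / 1.5)
  expect_lt(abs(s$criterion), 0.02)

  # d' = 1.14, c = 0: accuracy converges to Phi(d'/2) (numerical-integration
  # oracle: P(correct) = .5 P(N(d',1) > d'/2) + .5 P(N(0,1) < d'/2))
  cfg2 <- generator_config(n_trials = 100000L, srate = 1000, n_channels = 8L,
                           excitability_sd = 0, criterion_base = 0,
                           observer_dprime = 1.14, miss_rate = 0, seed = 32L)
  lat2 <- simulate_trial_latents(cfg2, ev)
  resp2 <- simulate_responses(lat2, ev, cfg2)
  acc <- mean(resp2 == ev$label)
  oracle <- stats::integrate(function(x) stats::dnorm(x), -Inf, 1.14 / 2)$value
  expect_equal(acc, oracle, tolerance = 0.01)

  # d' = 0: accuracy at chance
  cfg3 <- generator_config(n_trials = 100000L, srate = 1000, n_channels = 8L,
                           observer_dprime = 0, miss_rate = 0, seed = 33L)
  lat3 <- simulate_trial_latents(cfg3, ev)
  resp3 <- simulate_responses(lat3, ev, cfg3)
  expect_lt(abs(mean(resp3 == ev$label) - 0.5), 0.01)
})
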
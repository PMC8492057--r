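---
title: "Simulating and analyzing single-trial somatosensory evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing single-trial somatosensory evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurosep)
```

## The scientific problem

In a two-alternative intensity discrimination task on median-nerve
stimulation, the perceived intensity of a stimulus varies from trial to
trial even when the physical stimulus is identical. Two electrophysiological
signatures of instantaneous cortical excitability track this variability:
the amplitude of 8–13 Hz (alpha) oscillations just before the stimulus, and
the size of the first cortical response (the N20 component of the
somatosensory evoked potential, SEP). `neurosep` implements the complete
single-trial analysis chain for this question — evoked-response extraction
by template-matching canonical correlation analysis (CCA), pre-stimulus
alpha quantification, signal-detection-theoretic (SDT) behavioral analysis,
and group-level effect-path estimation — together with a forward-model
generator of synthetic experiments that embodies the generative assumptions
the analysis relies on. Every analysis stage is therefore testable against
known ground truth without any recorded data.

## The generative model

### Scalp voltages

The per-trial evoked scalp voltage follows the physiological decomposition

\[ U_t \;=\; I_t \cdot N_\mathrm{neurons}(\text{intensity}_t) \cdot LF , \]

where \(I_t\) is the summed local post-synaptic current on trial *t* (scaled
by `epsc_gain`, default 3 µV at the scalp), \(N_\mathrm{neurons}\) is the
recruited population (proportional to the presented intensity gain; the
strong/weak ratio defaults to 1.2, a just-noticeable step above a clearly
perceptible weak stimulus), and \(LF\) a fixed lead-field gain. The gain
\(U_t\) multiplies a stereotyped unit waveform with a negative extremum
(−1) at 20 ms and a positive deflection at 35 ms, supported on 5–80 ms —
the N20–P35 complex. The waveform projects to the 32-channel abstract
spherical montage through a tangential-dipole-like unit pattern. The
recording further contains an alpha-band carrier whose pre-stimulus
amplitude envelope is set per trial, spatially mixed 1/f background noise
(`noise_sd`, default 0.4 µV per channel), and two peripheral channels: a
nerve volley (CNAP, peak near 7 ms) and a biphasic muscle response (CMAP,
5–20 ms, mV range), both scaling with presented intensity only.

### Excitability, alpha, and the observer

A latent excitability state \(e_t\) follows a stationary AR(1) process
(coefficient 0.8, unit marginal SD) — the minimal serially correlated
choice for a slowly drifting cortical state. It couples three ways, all
sign-configurable:

* **alpha**: \(\log \alpha_t = \log 2 - 0.5\, e_t + \varepsilon_t\)
  (`alpha_coupling` < 0): high alpha marks *low* excitability;
* **evoked current**: \(I_t = 3\,(1 - 0.15\, e_t)\) (`epsc_coupling` < 0):
  low excitability (high alpha) yields a *larger*, i.e. more negative, N20
  at fixed intensity;
* **decision criterion**: the SDT observer reports "strong" when
  \(d'\,[\text{stim}=\text{strong}] + z_t\) exceeds
  \(d'/2 + c_0 + c_e e_t\) with \(c_e = -0.09\) (`criterion_coupling`):
  high alpha (low excitability) raises the criterion, biasing reports
  toward "weak". The \(d'/2\) offset makes `criterion_base` coincide with
  the estimated SDT criterion \(c\), so an observer with `criterion_base =
  0` is unbiased by construction.

The observer's sensitivity defaults to \(d' = 1.14\), the level a
staircase-calibrated discrimination task typically realizes (the
calibration itself targets 1.5); accuracy is then
\(\Phi(d'/2) \approx 71.6\%\).

### Calibration of the coupling sizes

Directions follow the studied phenomenon; magnitudes had to be fixed by
design. The criterion coupling was sized by an a-priori power analysis: in
a 12-subject experiment with 1000 trials each, the criterion estimated in a
200-trial extreme bin carries a sampling SE of ≈ 0.094, so a paired
quintile contrast needs a true difference of ≈ 0.18 to be detected reliably
(≈ 98% power at n = 12). With the alpha–excitability correlation of ≈ 0.72
implied by the alpha couplings, `criterion_coupling = -0.09` delivers that
difference. This makes the simulated bias effect larger than what human
recordings show (criterion differences there are nearer 0.07, which a
12-subject design would detect only ~37% of the time); the simulation is
calibrated for reliable detectability, not for effect-size realism, and the
package's claims about real data are directional only.

The fast trial-level simulator (`simulate_trial_table()`) adds Gaussian
measurement noise to the true N20 gain (`n20_meas_sd = 0.34`, giving
recovery r ≈ 0.8) and to the true log alpha envelope (`alpha_meas_sd =
0.31`, rank correlation ≈ 0.9) — the fidelity the full render → preprocess
→ CCA → features chain attains, as the test suite verifies on rendered
subjects. Resampling studies (power, type-I error, sign recovery) use this
path; rendering hundreds of multichannel 5 kHz recordings would multiply
cost without informing the statistics under test.

## The analysis chain

### Preprocessing

Stimulation artifacts are excised between −2 and +4 ms around each stimulus
and bridged by piecewise cubic Hermite interpolation (PCHIP), anchored on
the two samples flanking each window edge (the anchor count is a package
convention; PCHIP reproduces constants and linear trends exactly, which the
tests assert). The SEP stream is band-pass filtered 30–200 Hz with a
4th-order Butterworth applied forward and backward (zero phase, squared
magnitude response); this doubles as a baseline correction and attenuates
14 Hz by well over 30 dB, so alpha cannot leak into the evoked measures.
Epochs span −100…600 ms; scalp channels are average-referenced (peripheral
channels excluded).

### Template-matching CCA

With \(X = [x_1 \dots x_N]\) the concatenated single trials (5–80 ms) and
\(Y = [\bar{x} \dots \bar{x}]\) the replicated grand average, CCA maximizes
\(\mathrm{corr}(w_x^\top X,\, w_y^\top Y)\). Because averaging cancels
noise, \(w_x\) acts as a spatial template matcher for the shared SEP
morphology. The problem is solved by whitening: the SVD of
\(C_{xx}^{-1/2} C_{xy} C_{yy}^{-1/2}\) yields the canonical correlations
and, after back-transformation, the filters. Two numerical points:
\(C_{yy}\) is rank-limited (its columns repeat an average), so its inverse
square root is a pseudo-inverse over the retained eigenspace; and
\(C_{xx}\) receives shrinkage \((1-\gamma)C + \gamma\,\mathrm{tr}(C)/p\,I\)
with \(\gamma = 10^{-6}\), enough to handle the rank deficiency an average
reference induces. Components are reported in descending correlation;
among the leading four, the SEP component is selected by absolute cosine
similarity between its activation pattern \(A = C_{xx} w_x\) and a template
pattern (on synthetic data, the generating pattern — an automated stand-in
for the visual identification of the tangential dipole, validated only on
synthetic ground truth), and its sign is fixed so the grand average is
negative at 20 ms. Equal correlations tie-break toward the lower index.
One caveat the tests make explicit: a perfect canonical correlation of 1
requires identical trials; physiological gain variability alone caps
\(\rho_1\) below 1 even without sensor noise.

### Per-trial features

* **N20**: the subject latency is the minimum of the component's average
  within 15–30 ms (a physiologically bracketed window; the average's
  position is warned about if it touches the boundary), and each trial's
  amplitude is the minimum within ±2 ms of that latency.
* **P15 / N140**: plain window means (±1 ms around the average P15 latency;
  140–160 ms on a 0.5–45 Hz-filtered copy of the data projected through the
  *same* spatial filter).
* **Pre-stimulus alpha**: segments are cut at −500…−5 ms *before* any
  filtering (no post-stimulus leakage — asserted by mutation testing),
  projected through the CCA filter, symmetrically padded, band-passed 8–13
  Hz, and the modulus of the analytic signal (FFT-based Hilbert transform)
  is averaged over −200…−10 ms and natural-log-transformed (envelope first,
  log second).
* **CNAP/CMAP**: the nerve channel is 70 Hz high-passed; its peak is the
  maximum within ±1 ms of the subject latency found in 5–9 ms. The muscle
  channel is baseline-corrected (−20…−5 ms) and measured peak-to-peak
  between the negative (5–11 ms) and positive (10–20 ms) deflections, each
  within ±1 ms of the subject latencies.

### Numerical choices in the alpha pipeline

Three choices deserve explanation because naïve implementations fail:

1. **Narrow-band filter stability.** An 8th-order transfer-function
   band-pass with edges at 8–13 Hz is numerically unstable at a 5 kHz
   sampling rate (outputs grow by tens of orders of magnitude; the same
   happens in other scientific stacks). The segment is therefore decimated
   first — a zero-phase anti-alias low-pass followed by subsampling to
   ≈ 16× the upper band edge (≈ 250 Hz) — and the band-pass is
   designed at the decimated rate, where it is well conditioned. For the
   same reason `zero_phase_filter()` realizes wide bands with a tiny
   relative low edge (e.g. 0.5–45 Hz at 5 kHz) as a high-pass + low-pass
   cascade.
2. **Padding.** Zero-initial-condition forward-backward filtering has an
   edge transient of several hundred ms at a 5 Hz bandwidth. A single
   mirror reflection is not enough context; the implementation tiles a
   periodic even extension (three reflections per side) so the transient
   dies out before the segment of interest.
3. **Intrinsic edge bias.** Even with ideal filtering, band-limiting a
   495 ms segment whose averaging window reaches within ~15 ms of the
   segment edge biases the envelope by ~10% in a phase-dependent way (the
   reference implementations in other ecosystems behave identically).
   The bias is common-mode across trials, so rank-based and contrast
   analyses are unaffected; the tests assert absolute amplitude recovery
   (within 3%) only in the segment interior, exact log-ratio scaling for
   amplitude doublings, and rank recovery > 0.9 end-to-end.

### SDT and the quintile machinery

Hit and false-alarm rates are empirical conditional proportions (trials
without a response excluded); rates of exactly 0 or 1 are replaced by
\(1/(2N)\) and \(1 - 1/(2N)\) — the standard correction, flagged whenever
applied. Then \(d' = \Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{fa})\) and
\(c = -\tfrac12(\Phi^{-1}(\mathrm{hit}) + \Phi^{-1}(\mathrm{fa}))\); the
implementation is tested to \(10^{-6}\) against an independent
`erfinv`-based quantile oracle and to \(10^{-3}\) against a brute-force 2×2
likelihood grid. The quintile contrast stable-sorts each subject's trials
by an electrophysiological variable, takes the first and last
\(\lfloor 0.2 n \rfloor\) trials, estimates the SDT measure in each bin
(if a tiny bin lacks a stimulus category entirely, a log-linear
\((k+0.5)/(n+1)\) correction keeps the estimate defined — a documented
assumption), and compares highest minus lowest across subjects with a
paired t-test and paired Cohen's d (mean difference / SD of differences).

The above-chance permutation test remaps responses to stimuli 100,000
times. A uniform remapping only changes accuracy through the number of
"strong" responses landing on strong stimuli, which is hypergeometric; the
implementation samples that sufficient statistic directly (O(n_perm)
regardless of trial count) and is tested against explicit brute-force
permutations. The p-value counts surrogates *strictly* greater than the
observed accuracy (an add-one estimator is available); Bonferroni
correction across subjects is applied when a family size is given. Because
the accuracy support is a lattice, the permutation p is discrete; its null
calibration is verified at conventional thresholds rather than with a
continuous-uniform KS test.

### Group-level inference

Mixed-effects models delegate to `lme4`/`lmerTest`: continuous outcomes use
restricted maximum likelihood with Satterthwaite denominator df; binary
outcomes use a logit link (Wald z). Confidence intervals are normal
approximations on the fixed effect. Continuous predictors are z-transformed
per subject beforehand. A registry carries the model contracts used in the
analyses (e.g. `alpha_n20`: `n20 ~ 1 + alpha + (1 + alpha | subject)`).

Full multi-level structural equation modeling is out of scope; the
`two_stage_paths()` estimator is the package's explicit desk-scale stand-in:
each within-subject regression of the path set (N20 on intensity + alpha;
CNAP and CMAP on intensity; the binary report on intensity + N20 + alpha +
CMAP, logistic) is fitted per subject, and the per-subject coefficients are
tested against zero. It is validated for *sign* recovery and type-I
calibration only — its coefficients are not comparable in magnitude to
latent-variable path estimates. Subjects with separated logistic fits
(|coefficient| > 15 or non-finite) are excluded with a log entry. A single
subject degrades to within-subject estimates with a warning.

One convention worth stating: N20 amplitudes are kept *signed* (negative
peaks). A deeper N20 is a *smaller* number, so "high alpha goes with a
larger N20" appears as a negative alpha → N20 regression sign, and "a
smaller (less negative) N20 goes with more 'strong' reports" appears as a
positive N20 → report sign. The acceptance tests check recovered signs
against the generator's ground-truth coupling directions under exactly this
convention.

Within-subject standard errors for condition figures remove each subject's
mean, add back the grand mean, and scale the per-condition SD/√n by
\(\sqrt{k/(k-1)}\) for k conditions.

## Problem sizes

The package's own study conditions are the generator defaults: 12 subjects
× 1000 trials in 5 blocks, ISIs uniform on 1463–1563 ms (mean 1513 ms),
sequences starting with a weak stimulus, 5 kHz sampling, 32 scalp channels.
Rendered-EEG checks run on single subjects (160 trials at 5 kHz in the
acceptance script; 120 trials at 1 kHz with 12 channels in the unit tests
— the chain is rate-agnostic and the tests also pin the 5 kHz stability
corners). Resampling studies use 100 simulated experiments for power and
sign recovery and 200 null experiments for type-I calibration, all via the
trial-level simulator.

## What passing tests do and do not show

The generator reproduces the statistical *structure* the analyses assume —
a dipolar evoked complex with excitability-coupled gain, anti-coupled
alpha, an SDT observer with a state-dependent criterion — not real
recordings: no real cap geometry or head model (source reconstruction is
out of scope), a sinusoidal alpha carrier rather than broadband bursts, no
eye or muscle artifacts (the threshold-rejection hook stands in for manual
screening and is off by default), stationary noise, and a no-response rate
of 2% rather than task-dependent lapses. Passing tests certify the
machinery — extraction fidelity at the stated SNR, estimator correctness
against oracles, calibration under the null, determinism — and the
*directions* of the modeled effects; they do not certify effect sizes in
human data.
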
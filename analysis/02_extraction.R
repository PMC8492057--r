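#!/usr/bin/env Rscript

# Renders one synthetic subject as continuous multichannel EEG and runs the
# full single-trial extraction chain: stimulation-artifact interpolation,
# 30-200 Hz zero-phase band-pass, average reference, epoching, template-
# matching CCA (5-80 ms), N20 peak extraction, pre-stimulus alpha envelope,
# and CNAP/CMAP peripheral measures. Reports how well the extracted
# single-trial measures recover the generator's ground truth.
#
# A 160-trial subject at the full 5 kHz sampling rate is used; recovery
# statistics stabilize well below 1000 trials while the rendering stays in
# the minutes range.
#
# Output: results/extraction_recovery.tsv, results/cca_waveform.tsv

library(neurosep)

seed <- 20260924L
cfg <- generator_config(n_trials = 160L, seed = seed)
cat(sprintf("Rendering one subject: %d trials, %d channels, %g Hz ...\n",
            cfg$n_trials, cfg$n_channels, cfg$srate))
ds <- generate_experiment(cfg, seed = seed)
res <- analyze_subject(ds)

cat("\nTemplate-matching CCA:\n")
print(res$cca)
cat(sprintf("\nRecovery against generator ground truth:\n"))
cat(sprintf("  N20 amplitude vs true gain:      r = %.3f\n", res$n20_truth_cor))
cat(sprintf("  alpha log-envelope (rank):     rho = %.3f\n", res$alpha_truth_cor))
cat(sprintf("  activation pattern vs source:  cos = %.3f\n", res$pattern_cosine))

dir.create("results", showWarnings = FALSE)
write.table(
  data.frame(n20_truth_cor = res$n20_truth_cor,
             alpha_truth_cor = res$alpha_truth_cor,
             pattern_cosine = res$pattern_cosine,
             rho1 = res$cca$rho[1], n_trials = cfg$n_trials,
             srate = cfg$srate),
  "results/extraction_recovery.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

# grand-average waveform of the selected component over its training window
wf <- data.frame(time_ms = res$cca$times,
                 amplitude = res$cca$sign *
                   res$cca$mean_waveforms[res$cca$selected, ])
write.table(wf, "results/cca_waveform.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("\nComponent waveform minimum at %.1f ms (N20 by construction at 20 ms).\n",
            wf$time_ms[which.min(wf$amplitude)]))
cat("Wrote results/extraction_recovery.tsv and results/cca_waveform.tsv\n")
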
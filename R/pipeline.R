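#' Full single-subject analysis: recording to trial table
#'
#' Runs the complete extraction chain on one synthetic subject:
#' stimulus-artifact interpolation, 30-200 Hz zero-phase band-pass on the
#' scalp channels, average re-reference, epoching (-100..600 ms),
#' template-matching CCA on 5-80 ms with sign standardization against the
#' known generating pattern, projection of full-length epochs, N20 peak
#' extraction, N140 window mean on a 0.5-45 Hz stream, pre-stimulus alpha
#' log-envelope on the raw stream, and CNAP/CMAP peripheral amplitudes.
#'
#' @param dataset a `sep_dataset` from [generate_experiment()]
#' @param subject_id label written into the trial table
#' @param band scalp band-pass in Hz (default `c(30, 200)`)
#' @param epoch_window epoch bounds in ms (default `c(-100, 600)`)
#' @param cca_window CCA training window in ms (default `c(5, 80)`)
#' @param reject_threshold optional amplitude rejection threshold in uV
#'   (default NULL, off)
#' @return list with the per-trial `trial_table` (tombstoned rows flagged by
#'   `valid`), the fitted `cca` result, and recovery diagnostics
#'   (`n20_truth_cor`, `alpha_truth_cor`, `pattern_cosine`)
#' @export
analyze_subject <- function(dataset, subject_id = 1L, band = c(30, 200),
                            epoch_window = c(-100, 600),
                            cca_window = c(5, 80),
                            reject_threshold = NULL) {
  stopifnot(inherits(dataset, "sep_dataset"))
  cfg <- dataset$config
  rec <- dataset$recording
  meta <- data.frame(intensity = dataset$events$label,
                     response = dataset$responses,
                     stringsAsFactors = FALSE)
  meta <- cbind(meta, dataset$latents[, c("excitability", "alpha_env", "sep_gain")])

  rec <- interpolate_stimulus_artifact(rec)

  # peripheral channels: single-vector filtering, tiny epochs
  single_channel <- function(v, ch) {
    new_recording(matrix(v, nrow = 1L), rec$srate, ch_names = ch,
                  eeg_channels = character(0), events = rec$events)
  }
  cnap_hp <- zero_phase_filter(rec$data["CNAP", ], rec$srate, low = 70)
  ep_cnap <- epoch_data(single_channel(cnap_hp, "CNAP"), c(-30, 30))
  ep_cmap <- epoch_data(single_channel(rec$data["CMAP", ], "CMAP"), c(-30, 30))
  rm(cnap_hp)

  # the raw (unfiltered) pre-stimulus stream for the alpha pipeline
  ep_raw <- epoch_data(rec, c(-600, 100))

  # streams are filtered on the continuous data (no epoch edge artifacts)
  # one at a time to bound peak memory
  rec_sep <- rereference_average(
    filter_recording(rec, low = band[1L], high = band[2L]))
  ep_sep <- epoch_data(rec_sep, epoch_window, metadata = meta)
  rm(rec_sep)
  kept <- ep_sep$info$trial
  valid <- !is.na(ep_sep$info$response)
  if (!is.null(reject_threshold)) {
    valid <- valid & amplitude_reject(ep_sep, reject_threshold,
                                      channels = rec$eeg_channels)
  }
  rec_low <- rereference_average(filter_recording(rec, low = 0.5, high = 45))
  ep_low <- epoch_data(rec_low, epoch_window)
  rm(rec_low)
  invisible(gc(verbose = FALSE))

  pick <- function(ep, ch) {
    i <- match(ch, ep$ch_names)
    new_epochs(ep$data[, i, , drop = FALSE], ep$times, ep$srate, ch, ep$info)
  }

  cca <- fit_template_cca(ep_sep, window = cca_window)
  cca <- select_and_standardize(cca, template_pattern = cfg$pattern_sep)
  comp <- project_trials(ep_sep, cca)
  comp_low <- project_trials(ep_low, cca)

  n20 <- n20_peak_amplitude(comp)
  n140 <- window_mean_amplitude(comp_low, c(140, 160))
  alpha_log <- prestimulus_alpha(ep_raw, cca)
  periph <- peripheral_amplitudes(pick(ep_cnap, "CNAP"), pick(ep_cmap, "CMAP"))

  tab <- data.frame(
    subject = subject_id,
    trial = kept,
    block = ep_sep$info$block,
    intensity = ep_sep$info$intensity,
    response = ep_sep$info$response,
    n20_amp = n20$amplitude,
    n20_latency = n20$latency,
    n140_amp = n140,
    alpha_log = alpha_log,
    cnap_amp = periph$cnap_amp,
    cmap_amp = periph$cmap_amp,
    excitability = ep_sep$info$excitability,
    alpha_env = ep_sep$info$alpha_env,
    sep_gain = ep_sep$info$sep_gain,
    valid = valid,
    stringsAsFactors = FALSE
  )
  list(
    trial_table = tab,
    cca = cca,
    n20_truth_cor = stats::cor(-tab$n20_amp, tab$sep_gain),
    alpha_truth_cor = stats::cor(tab$alpha_log, log(tab$alpha_env),
                                 method = "spearman"),
    pattern_cosine = abs(cosine_similarity(cca$patterns[, cca$selected],
                                           cfg$pattern_sep))
  )
}

#' Run the simulate-to-statistics pipeline
#'
#' Generates (or reuses) a multi-subject trial table and runs the enabled
#' analyses: per-subject accuracy/SDT with permutation tests, extreme
#' alpha- and N20-quintile criterion contrasts, and the two-stage path
#' analysis. Outputs are written under `out_dir` as TSV/JSON together with
#' a manifest (config, seed, package version, config file MD5) sufficient
#' to reproduce the run bit-identically.
#'
#' @param config a [generator_config()]
#' @param out_dir output directory (created if needed)
#' @param seed master run seed (default `config$seed`)
#' @param stages character subset of `c("simulate", "sdt", "paths")`; when
#'   `"simulate"` is omitted and `trials.tsv` exists in `out_dir`, the
#'   cached trial table is reused
#' @param render if TRUE, every subject is rendered as continuous EEG and
#'   analyzed with [analyze_subject()]; if FALSE (default), the fast
#'   trial-level simulator [simulate_trial_table()] is used
#' @param n_perm permutations for the accuracy test
#' @return (invisibly) a list with `trial_table`, `sdt`, `bins`, `paths`,
#'   `manifest`
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         stages = c("simulate", "sdt", "paths"),
                         render = FALSE, n_perm = 10000L) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials_path <- file.path(out_dir, "trials.tsv")
  log_path <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)

  if ("simulate" %in% stages || !file.exists(trials_path)) {
    logline("simulate: %d subjects x %d trials (render = %s, seed = %d)",
            config$n_subjects, config$n_trials, render, seed)
    if (render) {
      tabs <- vector("list", config$n_subjects)
      for (s in seq_len(config$n_subjects)) {
        ds <- generate_experiment(config, seed = split_seed(seed, s))
        tabs[[s]] <- analyze_subject(ds, subject_id = s)$trial_table
      }
      trial_table <- do.call(rbind, tabs)
    } else {
      trial_table <- simulate_trial_table(config, seed = seed)
    }
    utils::write.table(trial_table, trials_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    logline("simulate: reusing cached %s", trials_path)
    trial_table <- utils::read.delim(trials_path, stringsAsFactors = FALSE)
  }

  out <- list(trial_table = trial_table)
  subjects <- unique(trial_table$subject)

  if ("sdt" %in% stages) {
    logline("sdt: per-subject accuracy, d', c (+ %d permutations)", n_perm)
    rows <- lapply(seq_along(subjects), function(j) {
      df <- trial_table[trial_table$subject == subjects[j] &
                          !is.na(trial_table$response), ]
      s <- sdt_from_trials(df$intensity, df$response)
      pt <- permutation_accuracy_test(df$intensity, df$response,
                                      n_perm = n_perm,
                                      seed = split_seed(seed, 10000 + j),
                                      family_size = length(subjects))
      data.frame(subject = subjects[j], n = nrow(df), accuracy = pt$accuracy,
                 hit = s$hit, fa = s$fa, d_prime = s$d_prime,
                 criterion = s$criterion, p_perm = pt$p,
                 p_perm_bonf = pt$p_bonferroni)
    })
    out$sdt <- do.call(rbind, rows)
    utils::write.table(out$sdt, file.path(out_dir, "sdt.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$bins <- list(
      alpha_criterion = extreme_bin_contrast(trial_table, "alpha_log", "criterion"),
      alpha_d_prime = extreme_bin_contrast(trial_table, "alpha_log", "d_prime"),
      n20_criterion = extreme_bin_contrast(trial_table, "n20_amp", "criterion")
    )
    bin_summary <- do.call(rbind, lapply(names(out$bins), function(nm) {
      b <- out$bins[[nm]]
      data.frame(contrast = nm, sort_var = b$sort_var, measure = b$measure,
                 mean_low = b$mean_low, mean_high = b$mean_high, t = b$t,
                 df = b$df, p = b$p, cohen_d = b$cohen_d)
    }))
    utils::write.table(bin_summary, file.path(out_dir, "bins.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  if ("paths" %in% stages) {
    logline("paths: two-stage path analysis")
    out$paths <- two_stage_paths(trial_table)
    jsonlite::write_json(out$paths, file.path(out_dir, "paths.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_list <- unclass(config)
  cfg_list$intensity_levels <- as.list(cfg_list$intensity_levels)
  yaml::write_yaml(cfg_list, cfg_path)
  manifest <- list(
    seed = seed,
    stages = stages,
    render = render,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("neurosep"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}

#' Human-readable summary of a pipeline run
#'
#' Reads the artifacts in a run directory and formats per-subject accuracy
#' and SDT estimates, the quintile bin contrasts, and the path signs. The
#' numbers are taken verbatim from the TSV/JSON artifacts.
#'
#' @param run_dir directory written by [run_pipeline()]
#' @return character vector of report lines (also written to `report.txt`)
#' @export
make_report <- function(run_dir) {
  sdt_path <- file.path(run_dir, "sdt.tsv")
  if (!dir.exists(run_dir) || length(list.files(run_dir)) == 0L) {
    stop("empty or missing run directory", call. = FALSE)
  }
  lines <- c("neurosep pipeline report", strrep("=", 24))
  if (file.exists(sdt_path)) {
    s <- utils::read.delim(sdt_path)
    lines <- c(lines, "",
               sprintf("Subjects: %d; mean accuracy %.2f%%, mean d' = %.3f, mean c = %.3f",
                       nrow(s), 100 * mean(s$accuracy), mean(s$d_prime),
                       mean(s$criterion)),
               sprintf("Above-chance permutation test: %d/%d subjects with Bonferroni p < 0.05",
                       sum(s$p_perm_bonf < 0.05), nrow(s)))
  }
  bins_path <- file.path(run_dir, "bins.tsv")
  if (file.exists(bins_path)) {
    b <- utils::read.delim(bins_path)
    lines <- c(lines, "", "Extreme-quintile contrasts (highest - lowest bin):",
               sprintf("  %s: %s %.3f -> %.3f, t(%g) = %.2f, p = %.4f, d = %.2f",
                       b$contrast, b$measure, b$mean_low, b$mean_high, b$df,
                       b$t, b$p, b$cohen_d))
  }
  paths_path <- file.path(run_dir, "paths.json")
  if (file.exists(paths_path)) {
    p <- jsonlite::read_json(paths_path, simplifyVector = TRUE)
    lines <- c(lines, "", "Two-stage path estimates:",
               sprintf("  %s ~ %s: beta = %+.3f (p = %.2g)",
                       p$outcome, p$predictor, p$beta, p$p))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  lines
}
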
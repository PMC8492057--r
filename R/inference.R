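#' Prepare a trial table for model fitting
#'
#' Adds the model-ready columns: `intensity01` (strong = 1), `response01`
#' (reported strong = 1), and per-subject z-transformed copies (`*_z`) of
#' every continuous single-trial measure present. Rows without a response
#' keep `response01 = NA` and are excluded by the fitting routines.
#'
#' @param trial_table data.frame with at least `subject`, `intensity`,
#'   `response`
#' @return the table with added columns
#' @export
prepare_model_frame <- function(trial_table) {
  stopifnot(all(c("subject", "intensity", "response") %in% names(trial_table)))
  tt <- trial_table
  tt$intensity01 <- as.numeric(tt$intensity == "strong")
  tt$response01 <- ifelse(is.na(tt$response), NA_real_,
                          as.numeric(tt$response == "strong"))
  for (v in intersect(c("n20_amp", "alpha_log", "p15_amp", "n140_amp",
                        "cnap_amp", "cmap_amp"), names(tt))) {
    tt[[paste0(v, "_z")]] <- ztrans_by(tt[[v]], tt$subject)
  }
  tt
}

model_registry <- function() {
  list(
    alpha_n20 = list(
      formula = n20_amp_z ~ 1 + alpha_log_z + (1 + alpha_log_z | subject),
      family = "gaussian", predictor = "alpha_log_z", outcome = "n20_amp_z"),
    n20_perception = list(
      formula = response01 ~ 1 + n20_amp_z + intensity01 + (1 | subject),
      family = "binomial", predictor = "n20_amp_z", outcome = "response01"),
    p15_perception = list(
      formula = response01 ~ 1 + p15_amp_z + intensity01 + (1 | subject),
      family = "binomial", predictor = "p15_amp_z", outcome = "response01"),
    n140_perception = list(
      formula = response01 ~ 1 + n140_amp_z + intensity01 +
        (1 + n140_amp_z + intensity01 | subject),
      family = "binomial", predictor = "n140_amp_z", outcome = "response01"),
    n140_alpha_intensity = list(
      formula = n140_amp_z ~ 1 + intensity01 + alpha_log_z +
        (1 + intensity01 + alpha_log_z | subject),
      family = "gaussian", predictor = "alpha_log_z", outcome = "n140_amp_z")
  )
}

#' Fit a linear or logistic mixed-effects model for a named contract
#'
#' Delegates to `lmerTest::lmer` (continuous outcomes, Satterthwaite
#' denominator df) or `lme4::glmer` with a logit link (binary outcomes).
#' Either a registered `formula_id` (e.g. `"alpha_n20"`:
#' `n20_amp_z ~ 1 + alpha_log_z + (1 + alpha_log_z | subject)`) or an
#' explicit `formula` + `family` may be given. Continuous predictors are
#' expected z-transformed; use [prepare_model_frame()]. On non-convergence
#' the fit falls back to the two-stage estimator with a message.
#'
#' @param trial_table data.frame (will be passed through
#'   [prepare_model_frame()] if the model columns are absent)
#' @param formula_id one of `names(neurosep:::model_registry())`
#' @param formula,family,predictor explicit alternative to `formula_id`
#' @return one-row data.frame (an effect estimate): `predictor`, `outcome`,
#'   `beta`, `stat`, `df`, `p`, `ci_lo`, `ci_hi`, `method`
#' @export
fit_mixed_model <- function(trial_table, formula_id = NULL, formula = NULL,
                            family = c("gaussian", "binomial"),
                            predictor = NULL) {
  if (!is.null(formula_id)) {
    reg <- model_registry()
    if (!formula_id %in% names(reg)) {
      stop(sprintf("unknown formula_id '%s'; available: %s", formula_id,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    spec <- reg[[formula_id]]
    formula <- spec$formula
    family <- spec$family
    predictor <- spec$predictor
  } else {
    stopifnot(!is.null(formula))
    family <- match.arg(family)
  }
  if (!"response01" %in% names(trial_table)) {
    trial_table <- prepare_model_frame(trial_table)
  }
  if (length(unique(trial_table$subject)) < 5L) {
    warning("fewer than 5 subjects: mixed-model variance components are poorly identified")
  }
  dat <- trial_table[stats::complete.cases(trial_table[all.vars(formula)]), ]
  fit <- tryCatch({
    if (family == "binomial") {
      lme4::glmer(formula, data = dat, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))
    } else {
      lmerTest::lmer(formula, data = dat)
    }
  }, error = function(e) e)
  conv_ok <- !inherits(fit, "error")
  if (conv_ok) {
    cs <- stats::coef(summary(fit))
    target <- if (is.null(predictor)) "(Intercept)" else predictor
    if (!target %in% rownames(cs)) {
      stop(sprintf("predictor '%s' not among the fixed effects", target),
           call. = FALSE)
    }
    beta <- cs[target, "Estimate"]
    se <- cs[target, "Std. Error"]
    if (family == "binomial") {
      stat <- cs[target, "z value"]
      df <- NA_real_
      p <- cs[target, "Pr(>|z|)"]
    } else {
      stat <- cs[target, "t value"]
      df <- cs[target, "df"]
      p <- cs[target, "Pr(>|t|)"]
    }
    data.frame(predictor = target,
               outcome = deparse(formula[[2L]]),
               beta = beta, stat = stat, df = df, p = p,
               ci_lo = beta - stats::qnorm(0.975) * se,
               ci_hi = beta + stats::qnorm(0.975) * se,
               method = "mixed_model", stringsAsFactors = FALSE)
  } else {
    message("mixed model did not converge (", conditionMessage(fit),
            "); falling back to the two-stage estimator")
    fixed <- stats::formula(lme4::nobars(formula))
    est <- two_stage_single(dat, fixed, family,
                            if (is.null(predictor)) "(Intercept)" else predictor)
    est$method <- "two_stage"
    est
  }
}

# per-subject fits + group-level one-sample t-test on the coefficients
two_stage_single <- function(dat, fixed_formula, family, predictor,
                             clip = 15, warn_single = TRUE) {
  subjects <- unique(dat$subject)
  coefs <- rep(NA_real_, length(subjects))
  for (j in seq_along(subjects)) {
    dj <- dat[dat$subject == subjects[j], , drop = FALSE]
    fit <- tryCatch({
      if (family == "binomial") {
        stats::glm(fixed_formula, data = dj, family = stats::binomial())
      } else {
        stats::lm(fixed_formula, data = dj)
      }
    }, error = function(e) NULL, warning = function(w) {
      # glm warns on fitted 0/1 probabilities under separation; refit quietly
      suppressWarnings(
        if (family == "binomial") {
          stats::glm(fixed_formula, data = dj, family = stats::binomial())
        } else {
          stats::lm(fixed_formula, data = dj)
        })
    })
    if (is.null(fit)) next
    b <- stats::coef(fit)[predictor]
    if (is.finite(b) && abs(b) <= clip) coefs[j] <- b
  }
  dropped <- sum(is.na(coefs))
  if (dropped > 0L) {
    message(sprintf("%d subject-level fit(s) excluded (separation or failure)",
                    dropped))
  }
  coefs <- coefs[!is.na(coefs)]
  outcome <- deparse(fixed_formula[[2L]])
  if (length(coefs) < 2L) {
    if (warn_single) {
      warning("single subject: within-subject estimate only, no group test")
    }
    return(data.frame(predictor = predictor, outcome = outcome,
                      beta = mean(coefs), stat = NA_real_, df = NA_real_,
                      p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      method = "two_stage", stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(coefs)
  data.frame(predictor = predictor, outcome = outcome,
             beta = mean(coefs), stat = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             ci_lo = tt$conf.int[1L], ci_hi = tt$conf.int[2L],
             method = "two_stage", stringsAsFactors = FALSE)
}

#' Two-stage path analysis over the trial table
#'
#' Desk-scale stand-in for a multi-level structural path model: each
#' within-subject regression of the path set is fitted per subject
#' (logistic for the binary perceived intensity), and the per-subject
#' coefficients are tested against zero with one-sample t-tests. The path
#' set is
#' \itemize{
#'   \item `n20_amp_z ~ intensity01 + alpha_log_z`
#'   \item `cnap_amp_z ~ intensity01`
#'   \item `cmap_amp_z ~ intensity01`
#'   \item `response01 ~ intensity01 + n20_amp_z + alpha_log_z + cmap_amp_z`
#'     (logit link)
#' }
#' Estimated only for sign and coverage; it does not reproduce latent-level
#' path coefficients of a full SEM.
#'
#' @param trial_table data.frame with the per-trial measures
#' @return data.frame of effect estimates, one row per (outcome, predictor)
#'   path
#' @export
two_stage_paths <- function(trial_table) {
  tt <- prepare_model_frame(trial_table)
  tt <- tt[!is.na(tt$response01), , drop = FALSE]
  paths <- list(
    list(f = n20_amp_z ~ intensity01 + alpha_log_z, fam = "gaussian",
         preds = c("intensity01", "alpha_log_z")),
    list(f = cnap_amp_z ~ intensity01, fam = "gaussian",
         preds = "intensity01"),
    list(f = cmap_amp_z ~ intensity01, fam = "gaussian",
         preds = "intensity01"),
    list(f = response01 ~ intensity01 + n20_amp_z + alpha_log_z + cmap_amp_z,
         fam = "binomial",
         preds = c("intensity01", "n20_amp_z", "alpha_log_z", "cmap_amp_z"))
  )
  single <- length(unique(tt$subject)) < 2L
  if (single) {
    warning("single subject: within-subject estimates only, no group test")
  }
  out <- list()
  for (p in paths) {
    for (pred in p$preds) {
      out[[length(out) + 1L]] <- two_stage_single(tt, p$f, p$fam, pred,
                                                  warn_single = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Within-subject standard errors of condition means
#'
#' Removes between-subject offsets (subtract each subject's mean, add back
#' the grand mean), computes each condition's SD across subjects divided by
#' sqrt(n), and applies the `sqrt(k/(k-1))` bias correction for k
#' conditions — the standard error appropriate for within-subject condition
#' comparisons in figures.
#'
#' @param values numeric matrix, subjects x conditions, no missing cells
#' @return numeric vector of per-condition standard errors
#' @export
within_subject_sem <- function(values) {
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("missing cells are not allowed (no imputation)", call. = FALSE)
  n <- nrow(values)
  k <- ncol(values)
  stopifnot(n >= 2L, k >= 2L)
  centered <- values - rowMeans(values) + mean(values)
  apply(centered, 2L, stats::sd) / sqrt(n) * sqrt(k / (k - 1))
}
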
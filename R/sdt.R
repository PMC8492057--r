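#' Hit and false-alarm rates from trial labels
#'
#' Empirical conditional response proportions: `hit = p("strong" | strong
#' stimulus)`, `fa = p("strong" | weak stimulus)`. Trials without a response
#' (NA) are excluded. Extreme rates of exactly 0 or 1 are replaced by
#' `1/(2N)` and `1 - 1/(2N)` (N = trials in that category) so the normal
#' quantiles stay finite; the `corrected` flag records when this happened.
#'
#' @param stimulus character vector in {"weak","strong"}
#' @param response character vector in {"weak","strong"} or NA
#' @return list with `hit`, `fa`, `n_strong`, `n_weak`, `corrected`
#' @export
rates_from_trials <- function(stimulus, response) {
  stopifnot(length(stimulus) == length(response))
  ok <- !is.na(response)
  stimulus <- stimulus[ok]
  response <- response[ok]
  for (lab in c("weak", "strong")) {
    if (!any(stimulus == lab)) {
      stop(sprintf("no responded trials in stimulus category '%s'", lab),
           call. = FALSE)
    }
  }
  n_strong <- sum(stimulus == "strong")
  n_weak <- sum(stimulus == "weak")
  hit <- sum(stimulus == "strong" & response == "strong") / n_strong
  fa <- sum(stimulus == "weak" & response == "strong") / n_weak
  corrected <- FALSE
  clip <- function(p, n) {
    if (p <= 0) {
      corrected <<- TRUE
      1 / (2 * n)
    } else if (p >= 1) {
      corrected <<- TRUE
      1 - 1 / (2 * n)
    } else {
      p
    }
  }
  hit <- clip(hit, n_strong)
  fa <- clip(fa, n_weak)
  list(hit = hit, fa = fa, n_strong = n_strong, n_weak = n_weak,
       corrected = corrected)
}

#' Sensitivity d' and criterion c
#'
#' `d' = qnorm(hit) - qnorm(fa)` measures the discriminability of the two
#' stimulus intensities; `c = -0.5 * (qnorm(hit) + qnorm(fa))` the response
#' bias (positive c: tendency to report "weak").
#'
#' @param hit,fa rates strictly inside (0, 1)
#' @return named numeric vector `c(d_prime, criterion)`
#' @export
d_prime_and_criterion <- function(hit, fa) {
  if (any(c(hit, fa) <= 0) || any(c(hit, fa) >= 1)) {
    stop("rates must lie strictly in (0, 1); apply the extreme-rate correction in rates_from_trials()",
         call. = FALSE)
  }
  zh <- stats::qnorm(hit)
  zf <- stats::qnorm(fa)
  c(d_prime = zh - zf, criterion = -0.5 * (zh + zf))
}

#' Full SDT estimate for a set of trials
#'
#' @param stimulus,response as in [rates_from_trials()]
#' @return object of class `sdt_result`: rates, counts, d', c, correction
#'   flag
#' @export
sdt_from_trials <- function(stimulus, response) {
  r <- rates_from_trials(stimulus, response)
  dc <- d_prime_and_criterion(r$hit, r$fa)
  structure(c(r, as.list(dc)), class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("<sdt_result> hit = %.3f, fa = %.3f (n = %d/%d)%s\n",
              x$hit, x$fa, x$n_strong, x$n_weak,
              if (x$corrected) " [rates corrected]" else ""))
  cat(sprintf("  d' = %.3f, c = %.3f\n", x$d_prime, x$criterion))
  invisible(x)
}

#' Cohen's d for paired samples
#'
#' Mean of the paired differences divided by the sample SD (n-1 denominator)
#' of the differences.
#'
#' @param differences numeric vector of paired differences (>= 2 values)
#' @return scalar effect size
#' @export
cohens_d_paired <- function(differences) {
  stopifnot(length(differences) >= 2L)
  s <- stats::sd(differences)
  if (!is.finite(s) || s == 0) {
    stop("zero variance of the paired differences: effect size undefined",
         call. = FALSE)
  }
  mean(differences) / s
}

# SDT estimate inside a (possibly tiny) trial bin: when a stimulus category
# is entirely absent, fall back to the log-linear correction
# (count + 0.5)/(n + 1) on both rates so the estimate stays defined
sdt_bin <- function(stimulus, response) {
  out <- tryCatch(sdt_from_trials(stimulus, response), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ok <- !is.na(response)
  stimulus <- stimulus[ok]
  response <- response[ok]
  ns <- sum(stimulus == "strong")
  nw <- sum(stimulus == "weak")
  hit <- (sum(stimulus == "strong" & response == "strong") + 0.5) / (ns + 1)
  fa <- (sum(stimulus == "weak" & response == "strong") + 0.5) / (nw + 1)
  dc <- d_prime_and_criterion(hit, fa)
  structure(list(hit = hit, fa = fa, n_strong = ns, n_weak = nw,
                 corrected = TRUE, d_prime = unname(dc["d_prime"]),
                 criterion = unname(dc["criterion"])),
            class = "sdt_result")
}

#' Extreme-quintile SDT contrast across subjects
#'
#' Per subject: stable-sort the responded trials by `sort_var`, take the
#' first and last `floor(n * bin_fraction)` trials (lowest and highest
#' quintile for the default fraction 0.2), estimate the SDT `measure` in
#' each bin, then compare the per-subject highest-vs-lowest values with a
#' paired t-test and a paired Cohen's d at the group level. The reported
#' difference is highest bin minus lowest bin.
#'
#' @param trial_table data.frame with columns `subject`, `intensity`,
#'   `response` and the sort variable
#' @param sort_var name of the column to sort trials by (e.g. `"alpha_log"`,
#'   `"n20_amp"`)
#' @param measure `"criterion"` or `"d_prime"`
#' @param bin_fraction fraction of trials per extreme bin (default 0.2)
#' @param min_trials minimal responded trials per subject (default 50)
#' @return object of class `bin_contrast`: per-subject bin values, t
#'   statistic, df, p, Cohen's d, 95% CI of the difference
#' @export
extreme_bin_contrast <- function(trial_table, sort_var,
                                 measure = c("criterion", "d_prime"),
                                 bin_fraction = 0.2, min_trials = 50L) {
  measure <- match.arg(measure)
  stopifnot(all(c("subject", "intensity", "response", sort_var) %in%
                  names(trial_table)))
  subjects <- unique(trial_table$subject)
  low <- numeric(length(subjects))
  high <- numeric(length(subjects))
  corrected <- logical(length(subjects))
  for (j in seq_along(subjects)) {
    df <- trial_table[trial_table$subject == subjects[j] &
                        !is.na(trial_table$response), , drop = FALSE]
    n <- nrow(df)
    if (n < min_trials) {
      stop(sprintf("subject %s has %d responded trials (< %d)",
                   subjects[j], n, min_trials), call. = FALSE)
    }
    ord <- order(df[[sort_var]])           # stable: original order breaks ties
    k <- floor(n * bin_fraction)
    lo <- df[ord[seq_len(k)], ]
    hi <- df[ord[seq(n - k + 1L, n)], ]
    slo <- sdt_bin(lo$intensity, lo$response)
    shi <- sdt_bin(hi$intensity, hi$response)
    if (slo$corrected || shi$corrected) {
      corrected[j] <- TRUE
      message(sprintf("subject %s: extreme-rate correction applied in a bin",
                      subjects[j]))
    }
    low[j] <- slo[[measure]]
    high[j] <- shi[[measure]]
  }
  diffs <- high - low
  tt <- stats::t.test(diffs)
  structure(
    list(sort_var = sort_var, measure = measure, bin_fraction = bin_fraction,
         per_subject = data.frame(subject = subjects, low = low, high = high),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohen_d = cohens_d_paired(diffs),
         ci = unname(tt$conf.int), mean_low = mean(low), mean_high = mean(high),
         corrected_any = any(corrected)),
    class = "bin_contrast"
  )
}

#' @export
print.bin_contrast <- function(x, ...) {
  cat(sprintf("<bin_contrast> %s by %s quintiles (fraction %.2f)\n",
              x$measure, x$sort_var, x$bin_fraction))
  cat(sprintf("  mean lowest = %.3f, highest = %.3f; t(%g) = %.3f, p = %.4f, Cohen's d = %.3f\n",
              x$mean_low, x$mean_high, x$df, x$t, x$cohen_d))
  invisible(x)
}

#' Permutation test for above-chance discrimination accuracy
#'
#' Randomly remaps responses to stimuli `n_perm` times and reports the
#' proportion of surrogate accuracies strictly greater than the observed one
#' (optionally the add-one estimator `(b + 1)/(n_perm + 1)`). The remapping
#' is sampled through its sufficient statistic — the number of "strong"
#' responses falling on strong stimuli, which under a uniform permutation is
#' hypergeometric — making the test O(n_perm) regardless of trial count.
#'
#' @param stimuli,responses equal-length label vectors in {"weak","strong"}
#'   (NA responses dropped)
#' @param n_perm number of permutations (default 100000)
#' @param seed integer seed
#' @param family_size optional number of tests for a Bonferroni-adjusted p
#' @param estimator `"strict"` (proportion strictly greater) or `"add_one"`
#' @return list with `accuracy`, `p`, `p_bonferroni` (NA without
#'   `family_size`), `n`, `n_perm`
#' @export
permutation_accuracy_test <- function(stimuli, responses, n_perm = 100000L,
                                      seed = NULL, family_size = NULL,
                                      estimator = c("strict", "add_one")) {
  estimator <- match.arg(estimator)
  stopifnot(length(stimuli) == length(responses))
  if (n_perm < 100L) warning("n_perm < 100: permutation p-value is unstable")
  ok <- !is.na(responses)
  stimuli <- stimuli[ok]
  responses <- responses[ok]
  n <- length(stimuli)
  acc <- mean(stimuli == responses)
  ns <- sum(stimuli == "strong")
  m <- sum(responses == "strong")
  if (!is.null(seed)) set.seed(seed)
  k <- stats::rhyper(n_perm, m, n - m, ns)
  surr <- (n - ns - m + 2 * k) / n
  b <- sum(surr > acc)
  p <- if (estimator == "strict") b / n_perm else (b + 1) / (n_perm + 1)
  list(accuracy = acc, p = p,
       p_bonferroni = if (is.null(family_size)) NA_real_ else min(1, p * family_size),
       n = n, n_perm = n_perm)
}
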
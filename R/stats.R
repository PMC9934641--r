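#' One-sided t-test of decoding accuracy against theoretical chance
#'
#' One-sample t-test of per-subject mean accuracies against chance
#' (1/3 for three balanced classes), one-sided "greater" since
#' below-chance values carry no meaning here, with optional Bonferroni
#' correction over the number of simultaneous tests (windows or time
#' bins). A zero-variance accuracy vector is decided exactly by the
#' sign of `mean - chance` and flagged.
#'
#' @param accuracies Per-subject mean accuracies.
#' @param chance Chance level (default 1/3).
#' @param n_tests Number of simultaneous tests for Bonferroni (1 = no
#'   correction).
#' @param test_name Label stored in the output row.
#' @return A one-row `data.frame` (`GroupStats`): estimate (mean -
#'   chance), statistic, df, `p_raw`, `p_adjusted`, n, correction,
#'   direction, `zero_variance` flag.
#' @export
ttest_vs_chance <- function(accuracies, chance = 1 / 3, n_tests = 1,
                            test_name = "accuracy vs chance") {
  if (length(accuracies) < 2)
    stop("need at least 2 subjects")
  est <- mean(accuracies) - chance
  if (stats::sd(accuracies) == 0) {
    p <- if (est > 0) 0 else 1
    out <- data.frame(test_name = test_name, estimate = est,
                      statistic = NA_real_, df = NA_real_, p_raw = p,
                      p_adjusted = min(1, p * n_tests),
                      n_subjects = length(accuracies),
                      correction = if (n_tests > 1) "bonferroni" else "none",
                      direction = "greater", zero_variance = TRUE,
                      stringsAsFactors = FALSE)
    return(out)
  }
  tt <- t.test(accuracies, mu = chance, alternative = "greater")
  data.frame(test_name = test_name, estimate = est,
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * n_tests),
             n_subjects = length(accuracies),
             correction = if (n_tests > 1) "bonferroni" else "none",
             direction = "greater", zero_variance = FALSE,
             stringsAsFactors = FALSE)
}

#' Subject-wise permutation test of group decoding accuracy
#'
#' Builds an empirical null by shuffling each subject's trial labels
#' independently and re-running that subject's decoding, recording the
#' cross-subject mean accuracy per permutation. The p-value uses the
#' add-one rule `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it
#' can never be exactly zero. Inside permutations the CV iteration
#' count may be reduced for tractability (the `cv` default here is 10
#' iterations); the reduction is recorded in the result.
#'
#' @param epochs List of [epoch_set()]s (one per subject).
#' @param window Window name (looked up in each epoch set's windows) or
#'   a length-2 ms pair.
#' @param n_perm Number of permutations (study setting: 1000; fewer
#'   than 100 triggers a warning about unstable p-values).
#' @param cv A [cv_scheme()] used inside the test (reduced iterations
#'   by default).
#' @param seed Integer seed controlling both label shuffles and CV.
#' @return A `permutation_null`: observed group statistic, null
#'   distribution, `p_perm`, per-subject observed accuracies.
#' @export
permutation_test <- function(epochs, window = "Sensory", n_perm = 1000,
                             cv = cv_scheme(n_iterations = 10),
                             seed = 1) {
  if (n_perm < 100)
    warning("fewer than 100 permutations gives an unstable p-value")
  feats <- lapply(epochs, function(ep) {
    wms <- if (is.character(window)) ep$windows[[window]] else window
    if (is.null(wms))
      stop(sprintf("window '%s' not found in epoch set", window))
    list(X = window_average(ep, wms), y = ep$labels)
  })
  n_sub <- length(feats)
  cv0 <- cv
  cv0$seed <- NULL                 # decode draws from the ambient stream
  # every (subject, permutation) unit runs under one sequential RNG
  # stream: drawing the shuffle and the CV splits from fixed-offset
  # derived seeds risks correlated streams that bias the null
  subject_acc <- vapply(seq_len(n_sub), function(i) {
    with_seed(derive_seed(seed, i),
              decode_features(feats[[i]]$X, feats[[i]]$y,
                              cv0)$mean_accuracy)
  }, 0)
  observed <- mean(subject_acc)
  null_dist <- vapply(seq_len(n_perm), function(j) {
    mean(vapply(seq_len(n_sub), function(i) {
      with_seed(derive_seed(seed, j * 1000L + i), {
        yp <- sample(feats[[i]]$y)
        decode_features(feats[[i]]$X, yp, cv0)$mean_accuracy
      })
    }, 0))
  }, 0)
  structure(
    list(window = if (is.character(window)) window else "custom",
         n_permutations = n_perm,
         observed_group_stat = observed,
         subject_accuracies = subject_acc,
         null_distribution = null_dist,
         p_perm = (1 + sum(null_dist >= observed)) / (1 + n_perm),
         cv_iterations = cv$n_iterations),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> [%s] observed %.3f, %d permutations, p = %.4g\n",
    x$window, x$observed_group_stat, x$n_permutations, x$p_perm))
  invisible(x)
}

#' Paired right-tailed comparison of Sensory vs Delay accuracy
#'
#' Paired-sample t-test with alternative Sensory > Delay; encoding of a
#' visible stimulus should be decoded at least as well as its
#' maintained trace.
#'
#' @param sensory Per-subject Sensory-period mean accuracies.
#' @param delay Per-subject Delay-period mean accuracies (same order).
#' @return A one-row `data.frame` with the mean difference, t, df, p.
#' @export
paired_sensory_delay <- function(sensory, delay) {
  if (length(sensory) != length(delay))
    stop("paired vectors differ in length")
  if (length(sensory) < 2) stop("need at least 2 subjects")
  d <- sensory - delay
  if (stats::sd(d) < 1e-10 * (abs(mean(d)) + 1)) {
    # constant difference: decide exactly by its sign and flag
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    return(data.frame(test_name = "Sensory > Delay (paired)",
                      estimate = mean(d), statistic = if (mean(d) == 0) 0
                        else NA_real_,
                      df = length(d) - 1, p_raw = p, p_adjusted = p,
                      n_subjects = length(sensory), correction = "none",
                      direction = "greater", zero_variance = TRUE,
                      stringsAsFactors = FALSE))
  }
  tt <- t.test(sensory, delay, paired = TRUE, alternative = "greater")
  data.frame(test_name = "Sensory > Delay (paired)",
             estimate = mean(sensory - delay),
             statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             p_adjusted = tt$p.value, n_subjects = length(sensory),
             correction = "none", direction = "greater",
             zero_variance = FALSE, stringsAsFactors = FALSE)
}

#' Pearson correlation between Sensory and Delay accuracy
#'
#' Quantifies whether subjects who are decoded well during encoding are
#' also decoded well during maintenance.
#'
#' @param sensory Per-subject Sensory accuracies.
#' @param delay Per-subject Delay accuracies.
#' @return List with `r`, `p` (two-sided), `df`.
#' @export
sensory_delay_correlation <- function(sensory, delay) {
  if (length(sensory) != length(delay))
    stop("paired vectors differ in length")
  if (length(sensory) < 3) stop("need at least 3 subjects")
  if (stats::sd(sensory) == 0 || stats::sd(delay) == 0)
    stop("zero variance in accuracy vector; correlation undefined")
  ct <- cor.test(sensory, delay, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Linear regression of decoding accuracy on age
#'
#' Ordinary least squares of per-subject accuracy on age, reporting the
#' slope, R-squared and the F-test p-value, used to check that group
#' decoding is not driven by the older children.
#'
#' @param age_months Per-subject ages in months.
#' @param accuracies Per-subject mean accuracies.
#' @param window Optional label stored in the output.
#' @return A one-row `data.frame` with `r_squared`, `slope`,
#'   `p_value`, `n_subjects`.
#' @export
age_regression <- function(age_months, accuracies, window = NA) {
  if (length(age_months) != length(accuracies))
    stop("age and accuracy vectors differ in length")
  if (length(age_months) < 3) stop("need at least 3 subjects")
  if (stats::sd(age_months) == 0)
    stop("constant age; regression undefined")
  fit <- lm(accuracies ~ age_months)
  an <- anova(fit)
  data.frame(window = window,
             r_squared = summary(fit)$r.squared,
             slope = unname(coef(fit)[2]),
             p_value = an[["Pr(>F)"]][1],
             n_subjects = length(accuracies),
             stringsAsFactors = FALSE)
}

#' Group significance mask for a temporal generalization matrix
#'
#' Cell-wise one-sided t-tests of per-subject generalization accuracy
#' against chance, Bonferroni-corrected over all cells, yielding the
#' boolean mask overlaid on group generalization maps.
#'
#' @param mats List of `gen_matrix` objects (one per subject) on the
#'   same bin grid.
#' @param chance Chance level (1/3).
#' @param alpha Family-wise alpha (0.05).
#' @return List with `mean_accuracy` matrix, `p_adjusted` matrix and
#'   logical `significant` mask.
#' @export
tempgen_group_stats <- function(mats, chance = 1 / 3, alpha = 0.05) {
  stopifnot(length(mats) >= 2)
  arr <- simplify2array(lapply(mats, `[[`, "accuracy"))
  nb <- dim(arr)[1:2]
  n_cells <- prod(nb)
  pmat <- matrix(NA_real_, nb[1], nb[2])
  for (i in seq_len(nb[1])) {
    for (j in seq_len(nb[2])) {
      v <- arr[i, j, ]
      pmat[i, j] <- if (stats::sd(v) == 0) {
        if (mean(v) > chance) 0 else 1
      } else {
        t.test(v, mu = chance, alternative = "greater")$p.value
      }
    }
  }
  p_adj <- pmin(1, pmat * n_cells)
  list(mean_accuracy = apply(arr, 1:2, mean), p_adjusted = p_adj,
       significant = p_adj < alpha,
       times_ms = mats[[1]]$times_ms)
}
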
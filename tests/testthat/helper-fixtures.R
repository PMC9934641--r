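# Shared test helpers: small session/model builders and independent
# oracles. All fixtures are generated in code at test time.

quick_cfg <- function(n = 30, ch = 16, fs = 200, ...) {
  session_config(n_trials_per_category = n, n_channels = ch,
                 fs_raw_hz = fs, ...)
}

null_model <- function(...) {
  signal_model(amp_sensory = 0, artifact_rate = 0, subject_snr_sd = 0, ...)
}

# 3-class Gaussian samples with shared identity covariance and class
# means on the vertices of a scaled simplex
gauss3 <- function(n_per, p, sep, seed) {
  with_seed(seed, {
    mus <- rbind(c(sep, 0), c(-sep / 2, sep * sqrt(3) / 2),
                 c(-sep / 2, -sep * sqrt(3) / 2))
    if (p > 2) mus <- cbind(mus, matrix(0, 3, p - 2))
    X <- do.call(rbind, lapply(1:3, function(ci)
      matrix(rnorm(n_per * p), n_per, p) +
        rep(mus[ci, ], each = n_per)))
    list(X = X, y = factor(rep(c("a", "b", "c"), each = n_per)),
         mus = mus)
  })
}

# Independent Gaussian-discriminant oracle: evaluates the quadratic
# discriminant -(x - mu_k)' Sigma^-1 (x - mu_k)/2 + log pi_k per test
# point, with the same shrinkage-target definition as the classifier
# but through direct quadratic forms rather than precomputed affine
# weights.
oracle_gauss_scores <- function(Xtr, ytr, Xte, lambda) {
  y <- factor(ytr)
  k <- nlevels(y)
  p <- ncol(Xtr)
  priors <- as.numeric(table(y)) / length(y)
  mus <- lapply(levels(y), function(cl)
    colMeans(Xtr[y == cl, , drop = FALSE]))
  Xc <- Xtr
  for (i in seq_len(nrow(Xtr))) Xc[i, ] <- Xtr[i, ] - mus[[as.integer(y)[i]]]
  S <- crossprod(Xc) / nrow(Xtr)
  nu <- mean(diag(S))
  Sig <- (1 - lambda) * S + lambda * nu * diag(p)
  sc <- vapply(seq_len(k), function(ci) {
    apply(Xte, 1, function(x) {
      d <- x - mus[[ci]]
      -0.5 * drop(crossprod(d, solve(Sig, d))) + log(priors[ci])
    })
  }, numeric(nrow(Xte)))
  matrix(sc, nrow(Xte), k, dimnames = list(NULL, levels(y)))
}

oracle_gauss_predict <- function(Xtr, ytr, Xte, lambda) {
  sc <- oracle_gauss_scores(Xtr, ytr, Xte, lambda)
  factor(colnames(sc)[max.col(sc, ties.method = "first")],
         levels = colnames(sc))
}
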
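#' Average epochs over a time window
#'
#' Per trial and channel, the mean voltage over all samples in the
#' half-open window `[start, end)`.
#'
#' @param ep An [epoch_set()].
#' @param window_ms Length-2 numeric window in ms.
#' @return Trials x channels matrix (uV).
#' @export
window_average <- function(ep, window_ms) {
  idx <- which(ep$times_ms >= window_ms[1] & ep$times_ms < window_ms[2])
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g) contains no samples", window_ms[1],
                 window_ms[2]))
  rowSums(ep$data[, , idx, drop = FALSE], dims = 2) / length(idx)
}

#' Average single trials into class-balanced pseudo-trials
#'
#' Within each class, trials are randomly permuted and partitioned into
#' consecutive groups of exactly `group_size`; remainder trials are
#' dropped, and each group is averaged into one pseudo-trial. Averaging
#' same-class trials raises the signal-to-noise ratio of the features
#' handed to the classifier.
#'
#' @param X Trials x features matrix.
#' @param y Per-trial class labels.
#' @param group_size Trials per average (default 5).
#' @param seed Optional seed; `NULL` uses the ambient RNG.
#' @return List with `features` (pseudo-trials x features), `labels`,
#'   `group_size`, and `provenance` (constituent trial indices per
#'   pseudo-trial).
#' @export
make_pseudotrials <- function(X, y, group_size = 5, seed = NULL) {
  y <- factor(y)
  with_seed(seed, {
    feats <- list(); labs <- list(); prov <- list()
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < group_size)
        stop(sprintf(
          "class '%s' has %d trials, fewer than group_size = %d",
          cl, length(idx), group_size))
      perm <- sample(idx)
      ng <- length(idx) %/% group_size
      keep <- perm[seq_len(ng * group_size)]
      g <- rep(seq_len(ng), each = group_size)
      feats[[cl]] <- rowsum(X[keep, , drop = FALSE], g,
                            reorder = TRUE) / group_size
      labs[[cl]] <- rep(cl, ng)
      prov[[cl]] <- split(keep, g)
    }
    list(features = do.call(rbind, feats),
         labels = factor(unlist(labs), levels = levels(y)),
         group_size = group_size,
         provenance = unlist(prov, recursive = FALSE))
  })
}

#' Equalize class counts by stratified up-sampling
#'
#' Minority classes receive duplicates drawn uniformly with replacement
#' from their own rows until every class matches the majority count.
#' Applied independently within a training or test partition, never
#' across them.
#'
#' @param X Rows x features matrix.
#' @param y Class labels.
#' @param seed Optional seed; `NULL` uses the ambient RNG.
#' @return List with balanced `X` and `y`.
#' @export
stratify_upsample <- function(X, y, seed = NULL) {
  y <- factor(y)
  with_seed(seed, {
    counts <- table(y)
    target <- max(counts)
    extra <- integer(0)
    for (cl in levels(y)) {
      need <- target - counts[[cl]]
      if (need > 0) {
        idx <- which(y == cl)
        extra <- c(extra, sample(idx, need, replace = TRUE))
      }
    }
    if (length(extra)) {
      X <- rbind(X, X[extra, , drop = FALSE])
      y <- factor(c(as.character(y), as.character(y[extra])),
                  levels = levels(y))
    }
    list(X = X, y = y)
  })
}

#' Demean features using training-partition column means
#'
#' Column means are computed on the training rows only and subtracted
#' from both partitions, so no information leaks from the test set.
#'
#' @param train_X Training rows x features matrix.
#' @param test_X Optional test rows x features matrix.
#' @return List with `train_X`, `test_X` and the subtracted
#'   `column_means`.
#' @export
demean_features <- function(train_X, test_X = NULL) {
  if (nrow(train_X) == 0) stop("training partition is empty")
  mu <- colMeans(train_X)
  train_X <- sweep(train_X, 2, mu)
  if (!is.null(test_X)) test_X <- sweep(test_X, 2, mu)
  list(train_X = train_X, test_X = test_X, column_means = mu)
}
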
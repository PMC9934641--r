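#' Cross-validation scheme for repeated decoding
#'
#' Each iteration assigns a stratified random 2/3 of the single trials
#' to the training set and 1/3 to a held-out test set, builds
#' pseudo-trials independently within each partition, up-samples to
#' equal class counts, demeans with training-derived column means, then
#' fits and evaluates the classifier. Accuracy is averaged over
#' iterations.
#'
#' @param n_iterations Number of iterations (default 100).
#' @param train_fraction Fraction of trials in the training set (2/3).
#' @param group_size Trials per pseudo-trial average (5).
#' @param seed Integer seed making the whole scheme reproducible.
#' @param lambda Shrinkage for [lda_fit()]: `"auto"` or fixed in
#'   `[0, 1]`.
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(n_iterations = 100, train_fraction = 2 / 3,
                      group_size = 5, seed = 1, lambda = "auto") {
  if (!is_count(n_iterations))
    config_error("n_iterations must be a positive integer")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    config_error("train_fraction must lie strictly between 0 and 1")
  if (!is_count(group_size))
    config_error("group_size must be a positive integer")
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 group_size = as.integer(group_size),
                 seed = seed, lambda = lambda),
            class = "cv_scheme")
}

# check that every class leaves at least one pseudo-trial in both
# partitions; `where` names the analysis in the error message
check_class_counts <- function(counts, cv, where = "analysis") {
  for (cl in names(counts)) {
    n_tr <- round(cv$train_fraction * counts[[cl]])
    n_te <- counts[[cl]] - n_tr
    if (n_tr < cv$group_size || n_te < cv$group_size)
      stop(sprintf(
        "%s: class '%s' has %d trials, too few for group_size %d after a %d/%d split",
        where, cl, counts[[cl]], cv$group_size,
        round(100 * cv$train_fraction),
        round(100 * (1 - cv$train_fraction))), call. = FALSE)
  }
}

# One stratified trial split followed by pseudo-trial construction in
# each partition, using the ambient RNG. Returns integer-coded labels.
.split_pseudo <- function(X, idx_by_class, cv) {
  k <- length(idx_by_class)
  gs <- cv$group_size
  tr_rows <- list(); te_rows <- list()
  tr_g <- list(); te_g <- list()
  tr_y <- integer(0); te_y <- integer(0)
  off_tr <- 0L; off_te <- 0L
  for (ci in seq_len(k)) {
    idx <- idx_by_class[[ci]]
    n <- length(idx)
    n_tr <- round(cv$train_fraction * n)
    perm <- idx[sample.int(n)]
    tr <- perm[seq_len(n_tr)]
    te <- perm[(n_tr + 1):n]
    ng_tr <- length(tr) %/% gs
    ng_te <- length(te) %/% gs
    tr_rows[[ci]] <- tr[seq_len(ng_tr * gs)]
    te_rows[[ci]] <- te[seq_len(ng_te * gs)]
    tr_g[[ci]] <- rep(off_tr + seq_len(ng_tr), each = gs)
    te_g[[ci]] <- rep(off_te + seq_len(ng_te), each = gs)
    tr_y <- c(tr_y, rep(ci, ng_tr))
    te_y <- c(te_y, rep(ci, ng_te))
    off_tr <- off_tr + ng_tr
    off_te <- off_te + ng_te
  }
  PTtr <- rowsum(X[unlist(tr_rows), , drop = FALSE], unlist(tr_g),
                 reorder = TRUE) / gs
  PTte <- rowsum(X[unlist(te_rows), , drop = FALSE], unlist(te_g),
                 reorder = TRUE) / gs
  list(PTtr = PTtr, ytr = tr_y, PTte = PTte, yte = te_y)
}

# Up-sample integer-coded rows to equal class counts (ambient RNG).
.upsample_rows <- function(n_rows_y, k) {
  counts <- tabulate(n_rows_y, k)
  target <- max(counts)
  extra <- integer(0)
  for (ci in seq_len(k)) {
    need <- target - counts[ci]
    if (need > 0)
      extra <- c(extra, sample(which(n_rows_y == ci), need,
                               replace = TRUE))
  }
  extra
}

#' Decode class labels from a feature matrix with repeated CV
#'
#' The core per-subject decoding routine: repeated stratified
#' train/test splits at the single-trial level, pseudo-trial averaging
#' and up-sampling within each partition, train-derived demeaning, then
#' shrinkage LDA. Identical seeds give bit-identical results.
#'
#' @param X Trials x features matrix.
#' @param y Per-trial class labels.
#' @param cv A [cv_scheme()].
#' @param where Analysis name used in error messages.
#' @return A `decoding_result`: `per_iteration_accuracy`,
#'   `mean_accuracy`, mean row-stochastic `confusion`,
#'   `n_trials_per_class_used`, `mean_lambda`.
#' @export
decode_features <- function(X, y, cv = cv_scheme(), where = "decoding") {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  classes <- levels(y)
  k <- length(classes)
  if (k < 2) stop(sprintf("%s: need at least 2 classes", where))
  idx_by_class <- lapply(seq_len(k), function(ci) which(as.integer(y) == ci))
  counts <- setNames(lengths(idx_by_class), classes)
  check_class_counts(counts, cv, where)
  n_it <- cv$n_iterations
  acc <- numeric(n_it)
  lam <- numeric(n_it)
  conf_counts <- matrix(0, k, k)
  with_seed(cv$seed, {
    for (it in seq_len(n_it)) {
      sp <- .split_pseudo(X, idx_by_class, cv)
      ex_tr <- .upsample_rows(sp$ytr, k)
      ex_te <- .upsample_rows(sp$yte, k)
      Xtr <- rbind(sp$PTtr, sp$PTtr[ex_tr, , drop = FALSE])
      ytr <- c(sp$ytr, sp$ytr[ex_tr])
      Xte <- rbind(sp$PTte, sp$PTte[ex_te, , drop = FALSE])
      yte <- c(sp$yte, sp$yte[ex_te])
      mu <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2, mu)
      Xte <- sweep(Xte, 2, mu)
      pri <- tabulate(ytr, k) / length(ytr)
      fit <- .lda_core(Xtr, ytr, k, cv$lambda, pri)
      sc <- Xte %*% t(fit$W)
      sc <- sweep(sc, 2, fit$b, "+")
      pred <- max.col(sc, ties.method = "first")
      acc[it] <- mean(pred == yte)
      lam[it] <- fit$lambda
      conf_counts <- conf_counts + tabulate(yte + k * (pred - 1), k * k)
    }
  })
  conf <- conf_counts / rowSums(conf_counts)
  dimnames(conf) <- list(true = classes, predicted = classes)
  structure(
    list(window = attr(X, "window_name"),
         per_iteration_accuracy = acc,
         mean_accuracy = mean(acc),
         confusion = conf,
         n_trials_per_class_used = counts,
         mean_lambda = mean(lam),
         cv = cv),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result>%s mean accuracy %.3f over %d iterations (lambda %.3f)\n",
              if (is.null(x$window)) "" else paste0(" [", x$window, "]"),
              x$mean_accuracy, length(x$per_iteration_accuracy),
              x$mean_lambda))
  invisible(x)
}

#' Decode one time-averaged analysis window
#'
#' @param ep An [epoch_set()].
#' @param window_ms Length-2 window in ms (half-open).
#' @param cv A [cv_scheme()].
#' @param window_name Label stored in the result.
#' @return A `decoding_result`.
#' @export
decode_window <- function(ep, window_ms, cv = cv_scheme(),
                          window_name = NULL) {
  X <- window_average(ep, window_ms)
  if (is.null(window_name))
    window_name <- sprintf("[%g, %g) ms", window_ms[1], window_ms[2])
  attr(X, "window_name") <- window_name
  res <- decode_features(X, ep$labels, cv,
                         where = sprintf("window %s", window_name))
  res$window_ms <- window_ms
  res
}

#' Decode the Baseline, Sensory and Delay windows
#'
#' Runs [decode_window()] on each analysis window carried by the epoch
#' set (by default Baseline -300--0 ms, Sensory 0--1000 ms, Delay
#' 1000--3000 ms).
#'
#' @param ep An [epoch_set()].
#' @param cv A [cv_scheme()].
#' @param windows Optional named list of ms-pair windows; defaults to
#'   `ep$windows`.
#' @return Named list of `decoding_result`s.
#' @export
decode_timeavg_all <- function(ep, cv = cv_scheme(), windows = NULL) {
  if (is.null(windows)) windows <- ep$windows
  if (is.null(windows))
    stop("epoch set carries no analysis windows; pass `windows`")
  out <- lapply(names(windows), function(nm)
    decode_window(ep, windows[[nm]], cv, window_name = nm))
  setNames(out, names(windows))
}

# bin the epoch samples into consecutive bins of bin_width_ms;
# returns trials x (channels*bins) matrix plus bin metadata
bin_features <- function(ep, bin_width_ms) {
  spb <- bin_width_ms * ep$fs_hz / 1000
  if (abs(spb - round(spb)) > 1e-9 || spb < 1)
    stop("bin_width_ms must correspond to a whole number of samples")
  spb <- round(spb)
  d <- dim(ep$data)
  n_bins <- d[3] %/% spb
  if (n_bins < 2)
    stop("bin width divides the epoch into fewer than 2 bins")
  feats <- array(0, c(d[1], d[2], n_bins))
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1) * spb + 1):(b * spb)
    feats[, , b] <- rowSums(ep$data[, , idx, drop = FALSE], dims = 2) / spb
  }
  centers <- ep$times_ms[1] + (seq_len(n_bins) - 0.5) * bin_width_ms
  list(flat = matrix(feats, d[1], d[2] * n_bins), n_bins = n_bins,
       n_channels = d[2], centers = centers)
}

#' Temporal generalization: train on one time bin, test on all bins
#'
#' Divides each epoch into consecutive `bin_width_ms` bins of
#' channel-mean voltages, then, per CV iteration, performs one
#' trial-level split shared across bins, builds one set of pseudo-trial
#' groups per partition (reused across bins so no trial crosses
#' partitions at any bin), demeans each bin with its training-partition
#' means, fits the classifier per training bin and evaluates it on every
#' test bin. The averaged train-time x test-time accuracy matrix shows
#' how long a neural code persists: its diagonal is time-resolved
#' decoding, off-diagonal cells measure cross-temporal generalization.
#'
#' @param ep An [epoch_set()].
#' @param bin_width_ms Bin width in ms (50 by default; 20 for the
#'   finer-grained variant).
#' @param cv A [cv_scheme()].
#' @return A `gen_matrix`: `accuracy` (train x test), `times_ms` bin
#'   centers, `bin_width_ms`, `n_iterations`.
#' @export
temporal_generalization <- function(ep, bin_width_ms = 50,
                                    cv = cv_scheme()) {
  bf <- bin_features(ep, bin_width_ms)
  y <- droplevels(factor(ep$labels))
  classes <- levels(y)
  k <- length(classes)
  idx_by_class <- lapply(seq_len(k), function(ci) which(as.integer(y) == ci))
  counts <- setNames(lengths(idx_by_class), classes)
  check_class_counts(counts, cv, "temporal generalization")
  nb <- bf$n_bins
  nc <- bf$n_channels
  acc_sum <- matrix(0, nb, nb)
  with_seed(cv$seed, {
    for (it in seq_len(cv$n_iterations)) {
      sp <- .split_pseudo(bf$flat, idx_by_class, cv)
      ex_tr <- .upsample_rows(sp$ytr, k)
      ex_te <- .upsample_rows(sp$yte, k)
      Xtr <- rbind(sp$PTtr, sp$PTtr[ex_tr, , drop = FALSE])
      ytr <- c(sp$ytr, sp$ytr[ex_tr])
      Xte <- rbind(sp$PTte, sp$PTte[ex_te, , drop = FALSE])
      yte <- c(sp$yte, sp$yte[ex_te])
      mu <- colMeans(Xtr)              # per (channel, bin) train means
      Xtr <- sweep(Xtr, 2, mu)
      Xte <- sweep(Xte, 2, mu)
      n_tr <- nrow(Xtr); n_te <- nrow(Xte)
      dim(Xtr) <- c(n_tr, nc, nb)
      dim(Xte) <- c(n_te, nc, nb)
      te_mat <- aperm(Xte, c(1, 3, 2))  # (test row, bin) x channel
      dim(te_mat) <- c(n_te * nb, nc)
      yte_rep <- rep(yte, times = nb)
      pri <- tabulate(ytr, k) / length(ytr)
      for (b in seq_len(nb)) {
        fit <- .lda_core(Xtr[, , b], ytr, k, cv$lambda, pri)
        sc <- te_mat %*% t(fit$W)
        sc <- sweep(sc, 2, fit$b, "+")
        pred <- max.col(sc, ties.method = "first")
        correct <- matrix(pred == yte_rep, n_te, nb)
        acc_sum[b, ] <- acc_sum[b, ] + colMeans(correct)
      }
    }
  })
  structure(
    list(accuracy = acc_sum / cv$n_iterations,
         times_ms = bf$centers,
         bin_width_ms = bin_width_ms,
         n_iterations = cv$n_iterations,
         classes = classes),
    class = "gen_matrix")
}

#' @export
print.gen_matrix <- function(x, ...) {
  cat(sprintf("<gen_matrix> %d x %d bins of %g ms (%g..%g ms), %d iterations\n",
              nrow(x$accuracy), ncol(x$accuracy), x$bin_width_ms,
              min(x$times_ms), max(x$times_ms), x$n_iterations))
  invisible(x)
}

#' Split a session into early and late halves and decode each
#'
#' Partitions the trials by experimental block (blocks 1--4 vs 5--8)
#' and runs the requested analysis independently on each half.
#'
#' @param ep An [epoch_set()] whose `trial_meta` has a `block` column.
#' @param cv A [cv_scheme()].
#' @param analysis `"windows"` for time-averaged decoding or
#'   `"tempgen"` for temporal generalization.
#' @param bin_width_ms Bin width for `"tempgen"`.
#' @return List with `early` and `late` results.
#' @export
split_half_decode <- function(ep, cv = cv_scheme(),
                              analysis = c("windows", "tempgen"),
                              bin_width_ms = 50) {
  analysis <- match.arg(analysis)
  if (is.null(ep$trial_meta$block))
    stop("trial metadata carries no block information")
  halves <- list(early = subset_epochs(ep, ep$trial_meta$block <= 4),
                 late = subset_epochs(ep, ep$trial_meta$block >= 5))
  lapply(halves, function(h) {
    if (analysis == "windows") decode_timeavg_all(h, cv)
    else temporal_generalization(h, bin_width_ms, cv)
  })
}

#' Cross-decode: train on one dataset, test on another
#'
#' Fits the classifier on pseudo-trials built from the whole training
#' epoch set and evaluates on pseudo-trials from the whole test set
#' (e.g. early session half to late half). Because the two sets are
#' disjoint by construction there is no trial-level CV; instead the
#' pseudo-trial grouping is re-drawn `cv$n_iterations` times to yield a
#' comparable accuracy distribution.
#'
#' @param train_ep Training [epoch_set()].
#' @param test_ep Test [epoch_set()] with the same montage and time
#'   grid.
#' @param cv A [cv_scheme()].
#' @param windows Named window list; defaults to `train_ep$windows`.
#' @return Named list of `decoding_result`s.
#' @export
cross_decode <- function(train_ep, test_ep, cv = cv_scheme(),
                         windows = NULL) {
  if (dim(train_ep$data)[2] != dim(test_ep$data)[2])
    stop("channel montages differ between training and test sets")
  if (length(train_ep$times_ms) != length(test_ep$times_ms) ||
      max(abs(train_ep$times_ms - test_ep$times_ms)) > 1e-9)
    stop("epoch time grids differ between training and test sets")
  if (is.null(windows)) windows <- train_ep$windows
  k_lv <- levels(droplevels(factor(train_ep$labels)))
  out <- lapply(names(windows), function(nm) {
    Xtr_all <- window_average(train_ep, windows[[nm]])
    Xte_all <- window_average(test_ep, windows[[nm]])
    ytr_all <- factor(train_ep$labels, levels = k_lv)
    yte_all <- factor(test_ep$labels, levels = k_lv)
    k <- length(k_lv)
    acc <- numeric(cv$n_iterations)
    lam <- numeric(cv$n_iterations)
    conf_counts <- matrix(0, k, k)
    with_seed(cv$seed, {
      for (it in seq_len(cv$n_iterations)) {
        ptr <- make_pseudotrials(Xtr_all, ytr_all, cv$group_size)
        pte <- make_pseudotrials(Xte_all, yte_all, cv$group_size)
        btr <- stratify_upsample(ptr$features, ptr$labels)
        bte <- stratify_upsample(pte$features, pte$labels)
        dm <- demean_features(btr$X, bte$X)
        fit <- .lda_core(dm$train_X, as.integer(btr$y), k, cv$lambda,
                         tabulate(as.integer(btr$y), k) / length(btr$y))
        sc <- dm$test_X %*% t(fit$W)
        sc <- sweep(sc, 2, fit$b, "+")
        pred <- max.col(sc, ties.method = "first")
        yi <- as.integer(bte$y)
        acc[it] <- mean(pred == yi)
        lam[it] <- fit$lambda
        conf_counts <- conf_counts + tabulate(yi + k * (pred - 1), k * k)
      }
    })
    conf <- conf_counts / rowSums(conf_counts)
    dimnames(conf) <- list(true = k_lv, predicted = k_lv)
    structure(
      list(window = nm, window_ms = windows[[nm]],
           per_iteration_accuracy = acc, mean_accuracy = mean(acc),
           confusion = conf,
           n_trials_per_class_used = table(ytr_all),
           mean_lambda = mean(lam), cv = cv),
      class = "decoding_result")
  })
  setNames(out, names(windows))
}
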
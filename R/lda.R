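#' Fit a multiclass LDA classifier with shrinkage-regularised covariance
#'
#' Linear discriminant analysis assuming class-conditional Gaussians
#' with a shared covariance. The pooled within-class covariance `S`
#' (maximum-likelihood, computed from class-centered samples) is shrunk
#' toward a scaled identity target:
#' \deqn{\hat\Sigma = (1-\lambda) S + \lambda \frac{tr(S)}{p} I}
#' With `lambda = "auto"` the Ledoit-Wolf analytic estimator is used:
#' \eqn{\lambda = \min(1, \bar b^2 / d^2)} where
#' \eqn{d^2 = \|S - \nu I\|_F^2} (\eqn{\nu = tr(S)/p}) and
#' \eqn{\bar b^2 = (\sum_k \|x_k\|^4 - n \|S\|_F^2)/n^2} over the
#' centered samples \eqn{x_k}. This keeps the fit well-conditioned when
#' channels outnumber pseudo-trials in small folds.
#'
#' The discriminant for class k is affine:
#' \eqn{w_k = \hat\Sigma^{-1}\mu_k},
#' \eqn{b_k = -\tfrac12 \mu_k^\top \hat\Sigma^{-1}\mu_k + \log\pi_k}
#' with empirical priors \eqn{\pi_k}.
#'
#' @param X Samples x features matrix.
#' @param y Class labels (>= 2 classes, >= 2 samples each).
#' @param lambda `"auto"` or a fixed value in `[0, 1]`.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return An `lda_model`: class means, shrunk pooled covariance,
#'   `shrinkage_lambda`, discriminant `weights` (classes x features),
#'   `biases`, `class_labels`, `priors`.
#' @export
lda_fit <- function(X, y, lambda = "auto", priors = "empirical") {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  counts <- table(y)
  if (nlevels(y) < 2)
    stop("LDA needs at least 2 classes")
  if (any(counts < 2))
    stop("LDA needs at least 2 samples per class")
  if (is.numeric(lambda) && (lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1]")
  pri <- if (identical(priors, "uniform")) {
    rep(1 / nlevels(y), nlevels(y))
  } else {
    as.numeric(counts) / nrow(X)
  }
  fit <- .lda_core(X, as.integer(y), nlevels(y), lambda, pri)
  structure(
    list(class_means = fit$means, pooled_cov = fit$sigma,
         shrinkage_lambda = fit$lambda, weights = fit$W,
         biases = fit$b, class_labels = levels(y), priors = pri),
    class = "lda_model")
}

# Fast core shared with the decoding loops: X numeric matrix, yi integer
# class codes 1..k, pri numeric priors. Returns means, shrunk sigma,
# lambda, weights, biases.
.lda_core <- function(X, yi, k, lambda, pri) {
  n <- nrow(X); p <- ncol(X)
  means <- rowsum(X, yi, reorder = TRUE) / as.numeric(tabulate(yi, k))
  Xc <- X - means[yi, , drop = FALSE]
  S <- crossprod(Xc) / n
  nu <- sum(diag(S)) / p
  if (identical(lambda, "auto")) {
    d2 <- sum(S^2) - 2 * nu * sum(diag(S)) + p * nu^2
    if (d2 < 1e-30) {
      lambda <- 1
    } else {
      b2bar <- (sum(rowSums(Xc^2)^2) - n * sum(S^2)) / n^2
      lambda <- min(1, max(0, b2bar / d2))
    }
  }
  Sig <- (1 - lambda) * S
  diag(Sig) <- diag(Sig) + lambda * nu
  Wt <- tryCatch(solve(Sig, t(means)),
                 error = function(e)
                   stop("pooled covariance is singular; use nonzero shrinkage (lambda > 0)",
                        call. = FALSE))
  W <- t(Wt)                       # k x p
  b <- -0.5 * rowSums(W * means) + log(pri)
  list(means = means, sigma = Sig, lambda = lambda, W = W, b = b)
}

#' Predict class labels from a fitted LDA model
#'
#' Labels are the argmax of the affine discriminant scores
#' \eqn{w_k^\top x + b_k}. Exact score ties break deterministically to
#' the smallest class index; tied rows are recorded in
#' `attr(, "ties")`.
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param X Samples x features matrix.
#' @return List with `labels` (factor) and `scores` (samples x classes);
#'   tie row indices in `attr(, "ties")`.
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$weights))
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 ncol(model$weights), ncol(X)))
  scores <- X %*% t(model$weights)
  scores <- sweep(scores, 2, model$biases, "+")
  colnames(scores) <- model$class_labels
  ix <- max.col(scores, ties.method = "first")
  is_tie <- rowSums(scores == scores[cbind(seq_len(nrow(scores)), ix)]) > 1
  out <- list(labels = factor(model$class_labels[ix],
                              levels = model$class_labels),
              scores = scores)
  attr(out, "ties") <- which(is_tie)
  out
}

#' Accuracy and row-normalised confusion matrix
#'
#' Confusion row r, column c holds the fraction of true-class-r samples
#' predicted as class c, so rows sum to one. Accuracy is the overall
#' proportion of correct predictions (the diagonal weighted by
#' true-class counts). A class absent from `true_y` yields an `NA` row
#' and is flagged in `attr(, "missing_classes")` rather than silently
#' propagating NaN.
#'
#' @param true_y True labels.
#' @param pred_y Predicted labels.
#' @param classes Optional class-level vector; defaults to the union of
#'   factor levels.
#' @return List with `accuracy` and `confusion`.
#' @export
accuracy_and_confusion <- function(true_y, pred_y, classes = NULL) {
  if (length(true_y) != length(pred_y))
    stop("true and predicted label vectors differ in length")
  if (is.null(classes))
    classes <- union(levels(factor(true_y)), levels(factor(pred_y)))
  tf <- factor(true_y, levels = classes)
  pf <- factor(pred_y, levels = classes)
  tab <- table(tf, pf)
  n_true <- rowSums(tab)
  conf <- tab / ifelse(n_true > 0, n_true, NA)
  conf <- matrix(as.numeric(conf), nrow = length(classes),
                 dimnames = list(true = classes, predicted = classes))
  out <- list(accuracy = mean(tf == pf), confusion = conf)
  attr(out, "missing_classes") <- classes[n_true == 0]
  out
}
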
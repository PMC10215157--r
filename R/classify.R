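# Two-class Fisher linear discriminant with pooled within-class covariance
# and a small ridge term guaranteeing solvability on tiny samples.

#' Fit a two-class linear discriminant
#'
#' Pooled within-class covariance `S = ((n1-1)S1 + (n2-1)S2)/(n1+n2-2)`,
#' ridge-regularized as `S + lambda * (trace(S)/p) * I` (with an absolute
#' fallback when the trace is zero) so the fit is defined even for singular
#' covariances. Class priors are empirical. A point is assigned to the class
#' with the larger discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log prior_k`; exact ties go to the
#' class listed first.
#'
#' @param X Numeric matrix (rows = cases, columns = predictors).
#' @param y Class labels (two distinct values); the first level is the class
#'   listed first (tie winner).
#' @param lambda Ridge factor relative to the mean covariance eigenvalue.
#' @return A `vq_linear_model`: list with `classes`, `means` (2 x p),
#'   `cov_inv`, `priors`, `weights`, `intercept`. The decision boundary is
#'   `weights %*% x + intercept = 0` (positive = first class).
#' @export
fit_linear <- function(X, y, lambda = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) {
    stop("fit_linear needs exactly two classes, got ",
         length(classes), call. = FALSE)
  }
  n1 <- sum(y == classes[1]); n2 <- sum(y == classes[2])
  if (n1 == 0L || n2 == 0L) stop("a class has no rows", call. = FALSE)
  p <- ncol(X)
  X1 <- X[y == classes[1], , drop = FALSE]
  X2 <- X[y == classes[2], , drop = FALSE]
  mu <- rbind(colMeans(X1), colMeans(X2))
  S <- matrix(0, p, p)
  if (n1 > 1) S <- S + (n1 - 1) * stats::cov(X1)
  if (n2 > 1) S <- S + (n2 - 1) * stats::cov(X2)
  df <- max(n1 + n2 - 2, 1)
  S <- S / df
  tr <- sum(diag(S))
  ridge <- if (tr > 0) lambda * tr / p else lambda
  Sreg <- S + diag(ridge, p)
  Sinv <- solve(Sreg)
  priors <- c(n1, n2) / (n1 + n2)
  # score difference (class1 - class2) is linear: w'x + b
  w <- Sinv %*% (mu[1, ] - mu[2, ])
  b <- -0.5 * (mu[1, ] %*% Sinv %*% mu[1, ] -
                 mu[2, ] %*% Sinv %*% mu[2, ]) +
    log(priors[1] / priors[2])
  structure(list(classes = classes, means = mu, cov_inv = Sinv,
                 priors = priors, weights = drop(w),
                 intercept = drop(b), n = c(n1, n2)),
            class = "vq_linear_model")
}

#' Predict classes from a fitted linear discriminant
#'
#' @param object A `vq_linear_model`.
#' @param newdata Matrix with the same columns the model was fitted on.
#' @param ... Unused.
#' @return Character vector of class labels; ties go to the first class.
#' @export
predict.vq_linear_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$weights), call. = FALSE)
  }
  score <- drop(newdata %*% object$weights) + object$intercept
  ifelse(score >= 0, object$classes[1], object$classes[2])
}

#' Classification accuracy of a linear discriminant
#'
#' @param model A `vq_linear_model`.
#' @param X,y Evaluation data (for resubstitution accuracy, the training
#'   data).
#' @return Fraction of correctly classified rows.
#' @export
model_accuracy <- function(model, X, y) {
  mean(predict(model, X) == as.character(y))
}

# Resubstitution or leave-one-out accuracy for one subset of columns.
#' @keywords internal
#' @noRd
vq_subset_accuracy <- function(X, y, eval = c("resub", "loocv"),
                               lambda = 1e-6) {
  eval <- match.arg(eval)
  if (eval == "resub") {
    m <- fit_linear(X, y, lambda)
    return(model_accuracy(m, X, y))
  }
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) { correct[i] <- FALSE; next }
    m <- fit_linear(X[-i, , drop = FALSE], yi, lambda)
    correct[i] <- predict(m, X[i, , drop = FALSE]) == as.character(y[i])
  }
  mean(correct)
}
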
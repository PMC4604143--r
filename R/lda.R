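## Linear discriminant analysis for the SVB/VB task: pooled covariance,
## prior-probability threshold, standardized coefficients and apparent
## error rate (APER) on the training rows.

#' Fit the linear discriminant classifier
#'
#' Estimates the class mean vectors and the pooled covariance
#' `S = ((n1-1) S1 + (n2-1) S2) / (n1+n2-2)`, the discriminant coefficient
#' vector `a = S^-1 (mu1 - mu2)`, the standardized coefficients (a scaled
#' by the pooled per-variable standard deviations) and the apparent error
#' rate `APER = (N - n11 - n22)/N` by resubstitution. A pooled covariance
#' with reciprocal condition estimate below `1e-12` (e.g. collinear
#' features) raises a conditioning error of class
#' `"hbclass_conditioning_error"`.
#'
#' @param X numeric feature matrix (rows = beats).
#' @param y SVB/VB labels (class 1 = SVB, class 2 = VB).
#' @param priors class priors `(SVB, VB)`, both positive, summing to 1
#'   (default `c(0.3, 0.7)`).
#' @return An `lda_model`.
#' @export
fit_lda <- function(X, y, priors = c(0.3, 0.7)) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  stopifnot(length(priors) == 2L, all(priors > 0),
            abs(sum(priors) - 1) < 1e-8)
  n1 <- sum(y == "SVB"); n2 <- sum(y == "VB")
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 rows")
  X1 <- X[y == "SVB", , drop = FALSE]
  X2 <- X[y == "VB", , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  rc <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12)
    stop(errorCondition(
      sprintf("pooled covariance is singular or badly scaled (rcond = %g)", rc),
      class = "hbclass_conditioning_error"))
  a <- drop(solve(S, mu1 - mu2))
  model <- structure(list(
    mu1 = mu1, mu2 = mu2, sigma_pooled = S, a_hat = a,
    priors = priors, threshold = log(priors[2] / priors[1]),
    std_coeffs = a * sqrt(diag(S)),
    feature_names = colnames(X), aper = NA_real_
  ), class = "lda_model")
  pred <- predict(model, X)
  model$aper <- mean(pred != y)
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d coefficient(s), priors=(%.2f,%.2f), threshold=%.4f, APER=%.4f\n",
              length(x$a_hat), x$priors[1], x$priors[2], x$threshold, x$aper))
  invisible(x)
}

#' Discriminant scores
#'
#' `lambda(y) = (y - (mu1 + mu2)/2)' a`.
#'
#' @param model an `lda_model`.
#' @param newdata numeric matrix.
#' @return Numeric vector of scores.
#' @export
lda_score <- function(model, newdata) {
  X <- as.matrix(newdata)
  drop((X - matrix((model$mu1 + model$mu2) / 2, nrow(X),
                   ncol(X), byrow = TRUE)) %*% model$a_hat)
}

#' Classify beats with the discriminant rule
#'
#' Class 1 (SVB) iff `lambda(y) > ln(pi2/pi1)`, otherwise (including
#' equality) class 2 (VB).
#'
#' @param object an `lda_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return Factor of SVB/VB decisions.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  svb_vb_factor(ifelse(lda_score(object, newdata) > object$threshold,
                       "SVB", "VB"))
}
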
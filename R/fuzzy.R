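## Percentile fuzzy classifier: per feature and class, the empirical
## distribution of the training values defines a membership via the
## percentile ranking; the class with the larger mean confidence over the
## selected features wins.

#' Fit the fuzzy percentile classifier
#'
#' Stores, per feature and per class, the sorted training values whose
#' empirical CDF (midpoint convention at ties) drives the confidence
#' `1 - |2 F_c(x) - 1|`: maximal at the class median, zero outside the
#' class range.
#'
#' @param X numeric feature matrix (rows = beats).
#' @param y SVB/VB labels.
#' @return A `fuzzy_model`.
#' @export
fit_fuzzy <- function(X, y) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  if (!all(table(y) > 0)) stop("both classes must be present")
  dist <- lapply(.classes, function(cl)
    lapply(seq_len(ncol(X)), function(j) sort(X[y == cl, j])))
  names(dist) <- .classes
  structure(list(dist = dist, p = ncol(X), feature_names = colnames(X)),
            class = "fuzzy_model")
}

#' @export
print.fuzzy_model <- function(x, ...) {
  cat(sprintf("<fuzzy_model> %d feature(s); class sizes SVB=%d VB=%d\n",
              x$p, length(x$dist$SVB[[1]]), length(x$dist$VB[[1]])))
  invisible(x)
}

# empirical CDF with midpoint convention at ties, vectorised over x
ecdf_mid <- function(sorted_values, x) {
  n <- length(sorted_values)
  nle <- findInterval(x, sorted_values)                 # count <= x
  nlt <- findInterval(x, sorted_values, left.open = TRUE) # count < x
  (nlt + nle) / (2 * n)
}

#' Fuzzy class confidence of a feature value
#'
#' `1 - |2 F_c(x) - 1|` where `F_c` is the class-conditional empirical CDF
#' of the feature (midpoint convention at ties).
#'
#' @param model a `fuzzy_model`.
#' @param feature feature index within the model.
#' @param x value(s) to evaluate.
#' @param class `"SVB"` or `"VB"`.
#' @return Confidence(s) in \[0, 1\].
#' @export
fuzzy_confidence <- function(model, feature, x, class) {
  stopifnot(inherits(model, "fuzzy_model"), class %in% .classes)
  sv <- model$dist[[class]][[feature]]
  if (!length(sv)) stop("empty class distribution")
  1 - abs(2 * ecdf_mid(sv, x) - 1)
}

#' Classify beats by mean fuzzy confidence
#'
#' The mean confidence over the model's features is computed per class; the
#' class with the larger mean wins, exact ties resolve to VB.
#'
#' @param object a `fuzzy_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return Factor of SVB/VB decisions.
#' @export
predict.fuzzy_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  conf <- function(cl) {
    m <- vapply(seq_len(object$p), function(j)
      fuzzy_confidence(object, j, X[, j], cl), numeric(nrow(X)))
    rowMeans(matrix(m, nrow = nrow(X)))
  }
  svb <- conf("SVB"); vb <- conf("VB")
  svb_vb_factor(ifelse(svb > vb, "SVB", "VB"))
}
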
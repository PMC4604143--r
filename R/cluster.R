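## k-means cluster classifier: Lloyd iterations from random distinct rows,
## best of `replicates` restarts kept by the training criterion
## Mean(Se,PPV) (then Se), each cluster labelled by its majority beat class
## (tie -> VB), prediction by the nearest centroid.

#' Fit the k-means cluster classifier
#'
#' Each replicate starts Lloyd iterations (Euclidean distance) from `k`
#' randomly chosen distinct training rows and runs until assignments stop
#' changing or 100 iterations; an emptied cluster is re-seeded to the row
#' farthest from its assigned centroid. Clusters are labelled by their
#' majority class (tie to VB) and the replicate maximising the training
#' Mean(Se,PPV) — ties broken by higher Se, then by replicate order — is
#' kept.
#'
#' @param X numeric feature matrix (rows = beats).
#' @param y SVB/VB labels.
#' @param k number of clusters; must not exceed the number of distinct rows.
#' @param replicates random restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 100).
#' @return A `cluster_model`: centroids, per-centroid labels, kept
#'   replicate's criterion.
#' @export
fit_cluster <- function(X, y, k, replicates = 10, max_iter = 100) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  # row identity via a concatenated key (much faster than unique() on a
  # numeric matrix, which the stepwise trainer calls thousands of times)
  key <- do.call(paste, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                          sep = "\r"))
  if (k > length(unique(key))) stop("k exceeds the number of distinct rows")
  best <- NULL
  for (r in seq_len(replicates)) {
    perm <- sample.int(nrow(X))
    sel <- perm[!duplicated(key[perm])][seq_len(k)]
    init <- X[sel, , drop = FALSE]
    fit <- .lloyd_cpp(X, init, as.integer(max_iter))
    labels <- vapply(seq_len(k), function(j) {
      member <- y[fit$assignment == j]
      if (sum(member == "VB") >= sum(member == "SVB")) "VB" else "SVB"
    }, "")
    pred <- labels[fit$assignment]
    m <- beat_metrics(confusion_counts(y, pred))
    crit <- mean_se_ppv(m)
    se <- if (is.na(m$Se)) -Inf else m$Se
    if (is.null(best) || crit > best$crit + 1e-12 ||
        (abs(crit - best$crit) <= 1e-12 && se > best$se + 1e-12)) {
      best <- list(centroids = fit$centroids, labels = labels,
                   crit = crit, se = se)
    }
  }
  structure(list(k = k, centroids = best$centroids, labels = best$labels,
                 replicate_score = best$crit,
                 feature_names = colnames(X)),
            class = "cluster_model")
}

# criterion value usable for replicate comparison (NA metrics -> -Inf)
mean_se_ppv <- function(m) {
  if (is.na(m$Se) || is.na(m$PPV)) -Inf else (m$Se + m$PPV) / 2
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d over %d feature(s); labels: %s; training Mean(Se,PPV)=%.2f%%\n",
              x$k, ncol(x$centroids), paste(x$labels, collapse = ","),
              x$replicate_score))
  invisible(x)
}

#' Classify beats by the nearest cluster centroid
#'
#' @param object a `cluster_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return Factor of SVB/VB decisions (distance ties resolve to the
#'   lowest centroid index).
#' @export
predict.cluster_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  cen <- object$centroids
  # squared Euclidean distances n x k
  d2 <- outer(rowSums(X^2), rep(1, nrow(cen))) -
    2 * X %*% t(cen) + outer(rep(1, nrow(X)), rowSums(cen^2))
  nearest <- apply(d2, 1, which.min) # ties -> lowest index
  svb_vb_factor(object$labels[nearest])
}
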
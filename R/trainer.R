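## Iterative forward feature-selection training protocol: at each step every
## not-yet-selected feature is tentatively added, the classifier refit and
## the training Se/PPV computed; the feature maximising Mean(Se,PPV) is kept
## (ties: higher Se, then lower feature index). Selection stops when no
## candidate raises the criterion nor Se. Plus the hyperparameter sweeps:
## cluster count 2-10, class priors, tree pruning levels.

#' Training criterion Mean(Se,PPV)
#'
#' Arithmetic mean of sensitivity and positive predictivity in percent —
#' the optimisation criterion weighting SVB false positives and VB false
#' negatives equally.
#'
#' @param counts a [confusion_counts()] object.
#' @return Percent.
#' @export
train_criterion <- function(counts) {
  m <- beat_metrics(counts)
  if (is.na(m$Se) || is.na(m$PPV))
    stop("criterion undefined: Se or PPV has a zero denominator")
  (m$Se + m$PPV) / 2
}

#' Classifier adapters for the stepwise trainer
#'
#' Each adapter wraps one Stage-2 classifier as a `fit(X, y)` closure
#' returning a model with a `predict` method over the same columns.
#'
#' @param k,replicates cluster count and restarts for the cluster adapter.
#' @param priors class priors for the LDA adapter.
#' @return A list with elements `fit` and `name`.
#' @name adapters
NULL

#' @rdname adapters
#' @export
adapter_cluster <- function(k, replicates = 10) {
  list(fit = function(X, y) fit_cluster(X, y, k = k, replicates = replicates),
       name = sprintf("cluster(k=%d)", k))
}

#' @rdname adapters
#' @export
adapter_fuzzy <- function() {
  list(fit = function(X, y) fit_fuzzy(X, y), name = "fuzzy")
}

#' @rdname adapters
#' @export
adapter_lda <- function(priors = c(0.3, 0.7)) {
  list(fit = function(X, y) fit_lda(X, y, priors = priors),
       name = sprintf("lda(%.0f/%.0f)", 100 * priors[1], 100 * priors[2]))
}

#' Stepwise forward feature selection
#'
#' At each step every remaining candidate feature is temporarily appended to
#' the selected set, the classifier refit on the training rows and the
#' resubstitution Se/PPV computed. The candidate maximising Mean(Se,PPV)
#' (ties: higher Se, then lower column index) is kept; selection stops when
#' the best candidate raises neither the criterion nor (at an equal
#' criterion) Se, or at `max_steps`. Features that raise a conditioning
#' error (LDA: collinear additions producing a badly scaled pooled
#' covariance) are excluded from the current and all later steps.
#'
#' @param adapter an adapter from [adapter_cluster()], [adapter_fuzzy()] or
#'   [adapter_lda()].
#' @param X numeric training feature matrix (e.g. the 210-column expansion).
#' @param y SVB/VB labels containing both classes.
#' @param max_steps step cap (default 150).
#' @param verbose print one line per step.
#' @return A `stepwise_trace`: data frame `trace` (step, feature, Se, PPV,
#'   criterion), `selected` column indices, `stop_step`, `excluded`, and the
#'   final `model`.
#' @export
stepwise_select <- function(adapter, X, y, max_steps = 150, verbose = FALSE) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  p <- ncol(X)
  selected <- integer(0)
  excluded <- integer(0)
  cur_crit <- -Inf; cur_se <- -Inf
  trace <- NULL
  model <- NULL
  eps <- 1e-9
  for (step in seq_len(max_steps)) {
    candidates <- setdiff(seq_len(p), c(selected, excluded))
    if (!length(candidates)) break
    best <- NULL
    for (j in candidates) {
      cols <- c(selected, j)
      fit <- tryCatch(adapter$fit(X[, cols, drop = FALSE], y),
                      hbclass_conditioning_error = function(e) e,
                      error = function(e) NULL)
      if (inherits(fit, "hbclass_conditioning_error")) {
        excluded <- c(excluded, j) # never re-tried
        next
      }
      if (is.null(fit)) next # infeasible with this candidate; retry later steps
      pred <- predict(fit, X[, cols, drop = FALSE])
      m <- beat_metrics(confusion_counts(y, pred))
      crit <- mean_se_ppv(m)
      se <- if (is.na(m$Se)) -Inf else m$Se
      if (is.null(best) || crit > best$crit + eps ||
          (abs(crit - best$crit) <= eps && se > best$se + eps)) {
        best <- list(j = j, crit = crit, se = se,
                     ppv = if (is.na(m$PPV)) NA_real_ else m$PPV,
                     model = fit)
      }
    }
    if (is.null(best)) break
    improves <- best$crit > cur_crit + eps ||
      (abs(best$crit - cur_crit) <= eps && best$se > cur_se + eps)
    if (!improves) break
    selected <- c(selected, best$j)
    cur_crit <- best$crit; cur_se <- best$se
    model <- best$model
    trace <- rbind(trace, data.frame(step = step, feature = best$j,
                                     Se = best$se, PPV = best$ppv,
                                     criterion = best$crit))
    if (verbose)
      message(sprintf("[%s] step %d: +%s Se=%.2f PPV=%.2f Mean=%.2f",
                      adapter$name, step,
                      colnames(X)[best$j] %||% best$j,
                      best$se, best$ppv, best$crit))
  }
  structure(list(trace = trace, selected = selected,
                 stop_step = length(selected), excluded = sort(excluded),
                 model = model, criterion = cur_crit, se = cur_se,
                 adapter_name = adapter$name),
            class = "stepwise_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("<stepwise_trace> %s: %d step(s), Mean(Se,PPV)=%.2f%% Se=%.2f%%\n",
              x$adapter_name, x$stop_step, x$criterion, x$se))
  if (!is.null(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Sweep the cluster count
#'
#' Runs [stepwise_select()] with the cluster adapter for each `k` and keeps
#' the count with the best stopped criterion (tie: higher Se, then lower
#' `k`). The upper bound follows the rule of thumb
#' `floor(sqrt(n_features / 2))`, i.e. 10 for the 210-column expansion.
#'
#' @param X,y training matrix and labels.
#' @param k_range cluster counts to try (default `2:10`).
#' @param k_max upper bound on the cluster count; defaults to the rule of
#'   thumb applied to the full 210-feature input space.
#' @param replicates,max_steps,verbose passed through.
#' @return List `k` (best count), `trace` (its `stepwise_trace`), `all`
#'   (per-k summary data frame).
#' @export
sweep_clusters <- function(X, y, k_range = 2:10, k_max = max_cluster_count(),
                           replicates = 10, max_steps = 150,
                           verbose = FALSE) {
  kmax <- k_max
  if (any(k_range < 2 | k_range > kmax))
    stop("k_range must lie within [2, ", kmax, "]")
  results <- lapply(k_range, function(k)
    stepwise_select(adapter_cluster(k, replicates), X, y,
                    max_steps = max_steps, verbose = verbose))
  crit <- vapply(results, `[[`, 0, "criterion")
  se <- vapply(results, `[[`, 0, "se")
  best <- order(-crit, -se, k_range)[1]
  list(k = k_range[best], trace = results[[best]],
       all = data.frame(k = k_range, criterion = crit, Se = se,
                        steps = vapply(results, `[[`, 0L, "stop_step")))
}

#' Rule-of-thumb maximal cluster count
#' @param n_features size of the input feature space (default 210).
#' @return `floor(sqrt(n_features / 2))`.
#' @export
max_cluster_count <- function(n_features = 210) {
  as.integer(floor(sqrt(n_features / 2)))
}

#' Sweep class prior probabilities
#'
#' Evaluates `eval_fn` for each prior pair and applies the selection rule:
#' among pairs whose criterion is within `tol` (0.5 percentage points) of
#' the grid maximum, the first (in grid order) with `Se > PPV` is chosen;
#' if no pair satisfies `Se > PPV`, the criterion-maximising pair is
#' returned.
#'
#' @param eval_fn function of a prior pair returning a list with at least
#'   `Se`, `PPV`, `criterion` (and optionally a model/trace, carried along).
#' @param prior_grid list of `c(SVB, VB)` prior pairs summing to 1.
#' @param tol criterion tolerance in percentage points (default 0.5).
#' @return List `priors` (chosen pair), `result` (its evaluation), `all`
#'   (summary data frame).
#' @export
sweep_priors <- function(eval_fn, prior_grid, tol = 0.5) {
  stopifnot(length(prior_grid) >= 1L)
  res <- lapply(prior_grid, eval_fn)
  crit <- vapply(res, `[[`, 0, "criterion")
  se <- vapply(res, `[[`, 0, "Se")
  ppv <- vapply(res, `[[`, 0, "PPV")
  top <- max(crit)
  ok <- se > ppv & crit >= top - tol
  pick <- if (any(ok)) which(ok)[1] else which.max(crit)
  list(priors = prior_grid[[pick]], result = res[[pick]],
       all = data.frame(prior_svb = vapply(prior_grid, `[`, 0, 1),
                        prior_vb = vapply(prior_grid, `[`, 0, 2),
                        Se = se, PPV = ppv, criterion = crit))
}

#' Scan all pruning levels of a classification tree
#'
#' Prunes the tree stepwise from its full size down to one decision node
#' and reports, at every reachable decision-node count along the prune
#' sequence, the evaluation metrics on `(X, y)` together with the
#' complexity measures: misclassified fraction (error cost), number of
#' distinct features used and total reachable nodes. A single collapse can
#' remove several decision nodes at once, so the scan reports the counts
#' the sequence actually visits.
#'
#' @param tree a `beat_tree`.
#' @param X,y evaluation rows and labels.
#' @return Data frame with one row per visited decision-node count.
#' @export
prune_scan <- function(tree, X, y) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  out <- NULL
  cur <- tree
  repeat {
    pred <- predict(cur, X)
    m <- beat_metrics(confusion_counts(y, pred))
    internal <- reachable_internal(cur)
    out <- rbind(out, data.frame(
      decision_nodes = decision_nodes(cur),
      Se = m$Se, PPV = m$PPV,
      criterion = if (is.na(m$Se) || is.na(m$PPV)) NA_real_
                  else (m$Se + m$PPV) / 2,
      error_cost = mean(pred != y),
      n_features = length(unique(cur$nodes$var[internal])),
      total_nodes = length(reachable_ids(cur))))
    dn <- decision_nodes(cur)
    if (dn <= 1L) break
    cur <- tree_prune(cur, dn - 1L)
  }
  out
}
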
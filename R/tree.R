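## Classification tree for the SVB/VB task: exhaustive univariate splitting
## under deviance (maximum deviance reduction), Gini or twoing criteria,
## per-node prior reweighting, and backward pruning guided by the
## resubstitution misclassification rate (MCE).

#' Node impurity
#'
#' Deviance: `i_D = 2 n (-sum p_j log p_j)` (natural log, `0 log 0 = 0`),
#' i.e. `2n` times the entropy. Gini: `1 - sum p_j^2`, which for two classes
#' equals `2 p1 (1 - p1)`. The twoing rule is defined on splits, not nodes,
#' and is evaluated inside the split search.
#'
#' @param p class-proportion vector summing to 1.
#' @param criterion `"deviance"` or `"gini"`.
#' @param n node size (used by the deviance).
#' @return Nonnegative impurity.
#' @export
impurity <- function(p, criterion = c("deviance", "gini"), n = 1) {
  criterion <- match.arg(criterion)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a proportion vector summing to 1")
  if (n < 1) stop("node size must be >= 1")
  if (criterion == "gini") return(1 - sum(p^2))
  terms <- ifelse(p > 0, p * log(p), 0)
  2 * n * (-sum(terms))
}

.criterion_code <- function(criterion) {
  match(match.arg(criterion, c("deviance", "gini", "twoing")),
        c("deviance", "gini", "twoing")) - 1L
}

#' Best univariate split of a node
#'
#' Exhaustive search over all features and all midpoints between adjacent
#' distinct sorted values. Class counts are reweighted to the prior ratio at
#' the node (the node's effective proportions equal the priors). Deviance
#' and Gini maximise the impurity decrease (parent minus mass-weighted
#' children); twoing maximises
#' `(pL * pR / 4) * (sum_j |p_jL - p_jR|)^2`. Ties resolve to the lowest
#' feature index, then the lowest threshold. Rows descend left iff
#' `x < threshold`.
#'
#' @param X numeric feature matrix (rows = beats).
#' @param y SVB/VB labels.
#' @param criterion `"deviance"`, `"gini"` or `"twoing"`.
#' @param priors class priors `(SVB, VB)` summing to 1.
#' @return List `feature` (column index), `threshold`, `goodness`; or
#'   `feature = NA` when no candidate threshold exists (all rows identical
#'   in every feature). Zero-gain splits are legal and resolve by the
#'   tie-break, so locally uninformative partitions (e.g. the first cut of
#'   an XOR pattern) can still be made.
#' @export
best_split <- function(X, y, criterion = "deviance", priors = c(0.5, 0.5)) {
  X <- as.matrix(X)
  yy <- as.integer(svb_vb_factor(y)) - 1L # 0 = SVB, 1 = VB
  res <- .best_split_cpp(X, yy, .criterion_code(criterion), priors)
  if (res$feature < 0)
    return(list(feature = NA_integer_, threshold = NA_real_,
                goodness = NA_real_))
  res
}

#' Grow a classification tree
#'
#' Recursive splitting by [best_split()]. A node is terminal when it is
#' pure, when it is impure but holds fewer than `min_impure` rows, or when
#' no candidate split exists. Each node predicts the majority class under
#' prior-reweighted proportions (`argmax_j priors_j * n_jm / n_j(root)`);
#' an exact tie falls back to the raw-count majority, then to VB.
#'
#' @param X numeric feature matrix.
#' @param y SVB/VB labels.
#' @param criterion splitting criterion: `"deviance"` (default), `"gini"`,
#'   `"twoing"`.
#' @param priors class priors `(SVB, VB)`.
#' @param min_impure minimum size of an impure node to be split (default 10).
#' @return A `beat_tree` object.
#' @export
fit_tree <- function(X, y, criterion = "deviance", priors = c(0.5, 0.5),
                     min_impure = 10) {
  X <- as.matrix(X)
  y <- svb_vb_factor(y)
  stopifnot(nrow(X) >= 1L, length(y) == nrow(X),
            length(priors) == 2L, abs(sum(priors) - 1) < 1e-8)
  root_n <- c(sum(y == "SVB"), sum(y == "VB"))
  pred_of <- function(n1, n2) {
    w <- c(if (root_n[1] > 0) priors[1] / root_n[1] else 0,
           if (root_n[2] > 0) priors[2] / root_n[2] else 0)
    a1 <- w[1] * n1; a2 <- w[2] * n2
    if (abs(a1 - a2) > 1e-12) return(if (a2 > a1) 2L else 1L)
    if (n1 != n2) return(if (n2 > n1) 2L else 1L) # tie -> raw majority
    2L # full tie -> VB
  }
  nodes <- list()
  # stack of (row indices, parent id, side, depth)
  grow <- function(rows, depth) {
    yy <- y[rows]
    n1 <- sum(yy == "SVB"); n2 <- sum(yy == "VB")
    id <- length(nodes) + 1L
    node <- list(id = id, var = NA_integer_, thr = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 n = length(rows), n1 = n1, n2 = n2,
                 pred = pred_of(n1, n2), depth = depth)
    nodes[[id]] <<- node
    pure <- n1 == 0L || n2 == 0L
    if (pure || length(rows) < min_impure) return(id)
    sp <- best_split(X[rows, , drop = FALSE], yy, criterion, priors)
    if (is.na(sp$feature)) return(id)
    go_left <- X[rows, sp$feature] < sp$threshold
    nodes[[id]]$var <<- as.integer(sp$feature)
    nodes[[id]]$thr <<- sp$threshold
    nodes[[id]]$left <<- grow(rows[go_left], depth + 1L)
    nodes[[id]]$right <<- grow(rows[!go_left], depth + 1L)
    id
  }
  old <- options(expressions = 500000); on.exit(options(old))
  grow(seq_len(nrow(X)), 0L)
  df <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(id = nd$id, var = nd$var, thr = nd$thr, left = nd$left,
               right = nd$right, n = nd$n, n1 = nd$n1, n2 = nd$n2,
               pred = nd$pred, depth = nd$depth)))
  df$pruned_leaf <- FALSE
  structure(list(nodes = df, criterion = criterion, priors = priors,
                 min_impure = min_impure, n = nrow(X),
                 feature_names = colnames(X), prune_sequence = NULL),
            class = "beat_tree")
}

is_leaf_vec <- function(tree) {
  is.na(tree$nodes$var) | tree$nodes$pruned_leaf
}

#' Number of decision (internal split) nodes of a tree
#' @param tree a `beat_tree`.
#' @return Count of reachable internal nodes.
#' @export
decision_nodes <- function(tree) {
  length(reachable_internal(tree))
}

# ids of reachable nodes from the root given pruning flags
reachable_ids <- function(tree) {
  leaf <- is_leaf_vec(tree)
  out <- integer(0)
  stack <- 1L
  while (length(stack)) {
    id <- stack[1L]; stack <- stack[-1L]
    out <- c(out, id)
    if (!leaf[id])
      stack <- c(stack, tree$nodes$left[id], tree$nodes$right[id])
  }
  out
}

reachable_internal <- function(tree) {
  ids <- reachable_ids(tree)
  ids[!is_leaf_vec(tree)[ids]]
}

#' @export
print.beat_tree <- function(x, ...) {
  cat(sprintf("<beat_tree> criterion=%s priors=(%.2f,%.2f) n=%d: %d decision node(s), %d node(s) total\n",
              x$criterion, x$priors[1], x$priors[2], x$n,
              decision_nodes(x), length(reachable_ids(x))))
  invisible(x)
}

#' Classify beats with a tree
#'
#' Root-to-leaf descent: a row goes left iff `x[feature] < threshold`; the
#' leaf's majority class is returned.
#'
#' @param object a `beat_tree`.
#' @param newdata numeric matrix of rows to classify.
#' @param ... unused.
#' @return Factor of SVB/VB decisions.
#' @export
predict.beat_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  leaf <- is_leaf_vec(object)
  nd <- object$nodes
  out <- integer(nrow(X))
  route <- function(id, rows) {
    if (!length(rows)) return()
    if (leaf[id]) {
      out[rows] <<- nd$pred[id]
      return()
    }
    go_left <- X[rows, nd$var[id]] < nd$thr[id]
    route(nd$left[id], rows[go_left])
    route(nd$right[id], rows[!go_left])
  }
  route(1L, seq_len(nrow(X)))
  svb_vb_factor(.classes[out])
}

# resubstitution misclassification count of node id if treated as a leaf
node_leaf_errors <- function(tree, id) {
  nd <- tree$nodes
  nd$n[id] - if (nd$pred[id] == 1L) nd$n1[id] else nd$n2[id]
}

# total leaf errors of the (possibly pruned) subtree rooted at id
subtree_errors <- function(tree, id) {
  leaf <- is_leaf_vec(tree)
  total <- 0
  stack <- id
  while (length(stack)) {
    i <- stack[1L]; stack <- stack[-1L]
    if (leaf[i]) total <- total + node_leaf_errors(tree, i)
    else stack <- c(stack, tree$nodes$left[i], tree$nodes$right[i])
  }
  total
}

#' Resubstitution misclassification rate of a (pruned) tree
#' @param tree a `beat_tree`.
#' @return Fraction of training rows misclassified by the current leaves.
#' @export
resub_mce <- function(tree) {
  subtree_errors(tree, 1L) / tree$n
}

#' Prune a tree to a target number of decision nodes
#'
#' Iteratively collapses the reachable internal node whose conversion to a
#' leaf minimally increases the resubstitution misclassification cost (ties
#' to the lowest node id) until at most `target_decision_nodes` internal
#' nodes remain. Priors affect growth only; pruning costs use the raw
#' training proportions.
#'
#' @param tree a `beat_tree`.
#' @param target_decision_nodes target internal-node count (0 = root stump).
#' @return The pruned `beat_tree`; `$prune_sequence` records each collapse
#'   (node id, error increase, decision nodes and resubstitution MCE after).
#' @export
tree_prune <- function(tree, target_decision_nodes) {
  stopifnot(inherits(tree, "beat_tree"), target_decision_nodes >= 0)
  seqrec <- tree$prune_sequence
  while (decision_nodes(tree) > target_decision_nodes) {
    internal <- reachable_internal(tree)
    inc <- vapply(internal, function(id)
      node_leaf_errors(tree, id) - subtree_errors(tree, id), 0)
    pick <- internal[which.min(inc)] # which.min ties -> first = lowest id
    tree$nodes$pruned_leaf[pick] <- TRUE
    seqrec <- rbind(seqrec, data.frame(
      node = pick, error_increase = min(inc) / tree$n,
      decision_nodes = decision_nodes(tree), resub_mce = resub_mce(tree)))
  }
  tree$prune_sequence <- seqrec
  tree
}
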
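# --- classification tree ----------------------------------------------------

test_that("impurity follows the deviance and Gini closed forms", {
  expect_equal(impurity(c(1, 0), "deviance", n = 7), 0)
  expect_equal(impurity(c(1, 0), "gini"), 0)
  expect_equal(impurity(c(0.5, 0.5), "gini"), 0.5)
  expect_equal(impurity(c(0.3, 0.7), "gini"), 0.42)
  expect_equal(impurity(c(0.5, 0.5), "deviance", n = 10), 2 * 10 * log(2))
  expect_equal(round(impurity(c(0.5, 0.5), "deviance", n = 10), 4), 13.8629)
  expect_error(impurity(c(0.5, 0.6), "gini"), "summing to 1")

  # two-class identities: gini = 2 p1 (1-p1); deviance = 2 n * entropy
  for (p1 in seq(0, 1, by = 0.05)) {
    expect_equal(impurity(c(p1, 1 - p1), "gini"), 2 * p1 * (1 - p1))
    for (n in c(1, 4, 33))
      expect_equal(impurity(c(p1, 1 - p1), "deviance", n),
                   2 * n * impurity(c(p1, 1 - p1), "deviance", 1) / 2)
  }
})

test_that("best_split equals the exhaustive oracle on random fixtures", {
  # worked 1-D example: SVB at {1,2}, VB at {5,6} -> threshold 3.5
  X <- matrix(c(1, 2, 5, 6), ncol = 1)
  y <- c("SVB", "SVB", "VB", "VB")
  for (crit in c("deviance", "gini", "twoing")) {
    sp <- best_split(X, y, crit)
    expect_equal(sp$feature, 1)
    expect_equal(sp$threshold, 3.5)
  }
  # twoing goodness of the fully separated even split: (0.25/4) * 2^2
  expect_equal(best_split(X, y, "twoing")$goodness, 0.25)

  # identical rows, mixed labels -> no split
  none <- best_split(matrix(1, 4, 2), y, "gini")
  expect_true(is.na(none$feature))

  # randomized equivalence with the plain-R exhaustive search
  set.seed(33)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    Xr <- matrix(round(rnorm(n * 3), 1), n, 3)
    yr <- sample(c("SVB", "VB"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(yr)) < 2) next
    pri <- sample(list(c(0.5, 0.5), c(0.3, 0.7)), 1)[[1]]
    for (crit in c("deviance", "gini", "twoing")) {
      got <- best_split(Xr, yr, crit, pri)
      want <- oracle_best_split(Xr, yr, crit, pri)
      expect_equal(got$feature, want$feature, info = paste(rep, crit))
      if (!is.na(want$feature)) {
        expect_equal(got$threshold, want$threshold)
        expect_equal(got$goodness, want$goodness, tolerance = 1e-10)
      }
    }
  }
})

test_that("tree growth yields pure-leaf trees on separable fixtures", {
  # pure training set -> single leaf
  pure <- fit_tree(matrix(rnorm(12), 12, 1), rep("SVB", 12))
  expect_equal(decision_nodes(pure), 0)
  expect_equal(as.character(predict(pure, matrix(0))), "SVB")

  # separable 1-D set -> depth-1 tree, zero training error
  X <- matrix(c(rnorm(12, 1, 0.3), rnorm(12, 6, 0.3)), ncol = 1)
  y <- rep(c("SVB", "VB"), each = 12)
  t1 <- fit_tree(X, y)
  expect_equal(decision_nodes(t1), 1)
  expect_equal(resub_mce(t1), 0)
  expect_equal(as.character(predict(t1, matrix(c(1.5, 5.5)))),
               c("SVB", "VB"))

  # XOR pattern needs at least 3 internal nodes but is fully separable
  set.seed(8)
  centers <- rbind(c(0.25, 0.25), c(0.75, 0.75), c(0.25, 0.75), c(0.75, 0.25))
  Xx <- do.call(rbind, lapply(1:4, function(q)
    cbind(runif(12, centers[q, 1] - 0.2, centers[q, 1] + 0.2),
          runif(12, centers[q, 2] - 0.2, centers[q, 2] + 0.2))))
  yx <- rep(c("SVB", "SVB", "VB", "VB"), each = 12)
  tx <- fit_tree(Xx, yx, min_impure = 2)
  expect_gte(decision_nodes(tx), 3)
  expect_equal(resub_mce(tx), 0)
  expect_equal(as.character(predict(tx, Xx)), yx)

  # growth-vs-oracle: every split of a grown tree matches the oracle root
  sp <- best_split(Xx, yx)
  want <- oracle_best_split(Xx, yx)
  expect_equal(sp$feature, want$feature)
  expect_equal(sp$threshold, want$threshold)
})

test_that("pruning collapses minimal-cost nodes and is monotone", {
  set.seed(14)
  X <- matrix(rnorm(400), 200, 2)
  y <- ifelse(X[, 1] + 0.5 * rnorm(200) > 0, "VB", "SVB")
  tr <- fit_tree(X, y, min_impure = 10)
  full_dn <- decision_nodes(tr)
  expect_gt(full_dn, 4)

  # the first collapse is the argmin over all internal candidates
  internal <- hbclass:::reachable_internal(tr)
  inc <- vapply(internal, function(id)
    hbclass:::node_leaf_errors(tr, id) - hbclass:::subtree_errors(tr, id), 0)
  pr1 <- tree_prune(tr, full_dn - 1)
  expect_equal(pr1$prune_sequence$node[1], internal[which.min(inc)])

  # full prune sequence: target reached exactly, error non-decreasing
  seq_tree <- tree_prune(tr, 0)
  expect_equal(decision_nodes(seq_tree), 0)
  mce <- seq_tree$prune_sequence$resub_mce
  expect_true(all(diff(mce) >= -1e-12))

  # a single-split prune behaves like one split; a stump predicts majority
  one <- tree_prune(tr, 1)
  expect_equal(decision_nodes(one), 1)
  stump <- tree_prune(tr, 0)
  maj <- names(which.max(table(y)))
  expect_true(all(predict(stump, X) == maj))
})

test_that("tree predictions agree with rpart on a separable fixture", {
  skip_if_not_installed("rpart")
  set.seed(4)
  X <- matrix(rnorm(300), 150, 2)
  y <- ifelse(X[, 1] > 0.2, "VB", "SVB")
  tr <- fit_tree(X, y, criterion = "gini")
  df <- data.frame(y = factor(y), x1 = X[, 1], x2 = X[, 2])
  rp <- rpart::rpart(y ~ x1 + x2, df, method = "class",
                     control = rpart::rpart.control(minsplit = 10, cp = 0))
  agree <- mean(predict(tr, X) == predict(rp, df, type = "class"))
  expect_gte(agree, 0.95)
})

# --- k-means cluster classifier --------------------------------------------

test_that("k-means matches the all-partitions oracle on tiny sets", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  y <- c("SVB", "SVB", "VB", "VB")
  set.seed(2)
  m <- fit_cluster(X, y, k = 2)
  expect_equal(sort(as.numeric(m$centroids)), c(0.5, 10.5))
  want <- oracle_kmeans_partition(X, 2)
  expect_equal(sort(as.numeric(m$centroids)), sort(want$centroids[, 1]))

  # two distinct points, k = 2: each its own centroid
  m2 <- fit_cluster(matrix(c(0, 5), ncol = 1), c("SVB", "VB"), k = 2)
  expect_equal(sort(as.numeric(m2$centroids)), c(0, 5))

  # 6-point 2-D fixture vs brute force
  set.seed(6)
  X6 <- matrix(c(0, 0, 0.3, 0.2, 5, 5, 5.4, 5.1, 10, 0, 10.2, 0.4),
               ncol = 2, byrow = TRUE)
  y6 <- c("SVB", "SVB", "VB", "VB", "VB", "VB")
  m6 <- fit_cluster(X6, y6, k = 3, replicates = 20)
  want6 <- oracle_kmeans_partition(X6, 3)
  expect_equal(m6$centroids[order(m6$centroids[, 1]), ],
               want6$centroids[order(want6$centroids[, 1]), ],
               ignore_attr = TRUE)

  expect_error(fit_cluster(matrix(1, 5, 1), rep("SVB", 5), k = 2), "distinct")
})

test_that("cluster labelling and nearest-centroid prediction follow the rules", {
  # majority labelling: 3 SVB + 1 VB -> SVB; 2/2 tie -> VB
  X <- matrix(c(0, 0.1, 0.2, 0.3, 10, 10.1, 10.2, 10.3), ncol = 1)
  y <- c("SVB", "SVB", "SVB", "VB", "SVB", "SVB", "VB", "VB")
  set.seed(3)
  m <- fit_cluster(X, y, k = 2, replicates = 20)
  lab <- m$labels[order(m$centroids[, 1])]
  expect_equal(lab, c("SVB", "VB"))

  # prediction = label of nearest centroid; equidistant -> lowest index
  p <- predict(m, matrix(c(0, 10, 5.15), ncol = 1))
  d <- abs(5.15 - sort(m$centroids[, 1]))
  expect_equal(as.character(p[1:2]), c("SVB", "VB"))
  mm <- structure(list(k = 2, centroids = matrix(c(0, 10), ncol = 1),
                       labels = c("SVB", "VB"), replicate_score = 100,
                       feature_names = NULL), class = "cluster_model")
  expect_equal(as.character(predict(mm, matrix(5))), "SVB") # tie -> index 1
  # brute-force distance table on a 5-point fixture
  X5 <- matrix(rnorm(10), 5, 2)
  m5 <- structure(list(k = 3, centroids = matrix(rnorm(6), 3, 2),
                       labels = c("SVB", "VB", "SVB"), replicate_score = 0,
                       feature_names = NULL), class = "cluster_model")
  pd <- predict(m5, X5)
  for (i in 1:5) {
    dd <- apply(m5$centroids, 1, function(cc) sum((X5[i, ] - cc)^2))
    expect_equal(as.character(pd[i]), m5$labels[which.min(dd)])
  }
})

test_that("replicate selection never keeps a worse replicate than the first", {
  set.seed(19)
  X <- matrix(rnorm(200), 100, 2)
  y <- ifelse(X[, 1] > 0, "VB", "SVB")
  for (s in 1:4) {
    set.seed(s)
    one <- fit_cluster(X, y, k = 3, replicates = 1)
    set.seed(s)
    ten <- fit_cluster(X, y, k = 3, replicates = 10)
    expect_gte(ten$replicate_score, one$replicate_score)
  }
})

# --- fuzzy percentile classifier -------------------------------------------

test_that("fuzzy confidence is the folded empirical percentile", {
  X <- matrix(c(1:8, 101:108), ncol = 1)
  y <- rep(c("SVB", "VB"), each = 8)
  m <- fit_fuzzy(X, y)
  expect_equal(fuzzy_confidence(m, 1, 4.5, "SVB"), 1)   # class median
  expect_equal(fuzzy_confidence(m, 1, 0.5, "SVB"), 0)   # below the range
  expect_equal(fuzzy_confidence(m, 1, 6.5, "SVB"), 0.5) # 75th percentile
  expect_equal(fuzzy_confidence(m, 1, 200, "VB"), 0)    # above the range
  # midpoint convention at a tied value
  mt <- fit_fuzzy(matrix(c(1, 2, 2, 3, 9, 9, 9, 9), ncol = 1),
                  rep(c("SVB", "VB"), each = 4))
  expect_equal(fuzzy_confidence(mt, 1, 2, "SVB"), 1) # F = (1 + 3)/(2*4) = 0.5
})

test_that("fuzzy prediction averages confidences and breaks ties to VB", {
  set.seed(10)
  Xs <- cbind(rnorm(40, 0, 0.5), rnorm(40, 10, 0.5))
  Xv <- cbind(rnorm(40, 100, 0.5), rnorm(40, -50, 0.5))
  X <- rbind(Xs, Xv)
  y <- rep(c("SVB", "VB"), each = 40)
  m <- fit_fuzzy(X, y)
  # SVB medians are far outside the VB ranges and vice versa
  expect_equal(as.character(predict(m, rbind(c(0, 10)))), "SVB")
  expect_equal(as.character(predict(m, rbind(c(100, -50)))), "VB")

  # two-feature fixture with hand-computed CDF values
  m2 <- fit_fuzzy(matrix(c(1, 2, 3, 4, 3, 4, 5, 6), ncol = 2),
                  c("SVB", "SVB", "VB", "VB"))
  x <- c(1.5, 3.5)
  # SVB: x sits at both class medians (F = 0.5 -> confidence 1)
  cs <- mean(c(1, 1))
  cv <- mean(c(0, 0)) # 1.5 below VB range of feature 1; 3.5 below for f2
  pred <- predict(m2, rbind(x))
  expect_equal(as.character(pred), if (cs > cv) "SVB" else "VB")
  expect_equal(as.character(pred), "SVB")
})

# --- linear discriminant ----------------------------------------------------

test_that("LDA reproduces the 1-D worked example and prior threshold", {
  b <- sqrt(0.5)
  X <- matrix(c(-b, b, 2 - b, 2 + b), ncol = 1) # means 0, 2; pooled var 1
  y <- c("SVB", "SVB", "VB", "VB")
  m <- fit_lda(X, y, priors = c(0.5, 0.5))
  expect_equal(unname(m$a_hat), -2)
  expect_equal(m$threshold, 0)
  expect_equal(m$aper, 0) # perfectly separated
  expect_equal(unname(lda_score(m, matrix(0.5))), 1)
  expect_equal(as.character(predict(m, matrix(0.5))), "SVB")
  # midpoint with equal priors: lambda = 0, equality -> class 2 (VB)
  expect_equal(as.character(predict(m, matrix(1))), "VB")

  mp <- fit_lda(X, y, priors = c(0.3, 0.7))
  expect_equal(mp$threshold, log(7 / 3))
  expect_equal(as.character(predict(mp, matrix(0.5))), "SVB") # 1 > 0.847
  expect_equal(as.character(predict(mp, matrix(0.6))), "VB")  # 0.8 < 0.847

  # collinear columns raise the conditioning error
  Xc <- cbind(rnorm(20), 0)
  Xc[, 2] <- 2 * Xc[, 1]
  expect_error(fit_lda(Xc, rep(c("SVB", "VB"), 10)),
               class = "hbclass_conditioning_error")
})

test_that("LDA recovers the boundary of symmetric Gaussian classes", {
  set.seed(101)
  n <- 2000
  X <- matrix(c(rnorm(n, 0, 1), rnorm(n, 2, 1)), ncol = 1)
  y <- rep(c("SVB", "VB"), each = n)
  m <- fit_lda(X, y, priors = c(0.5, 0.5))
  boundary <- (m$mu1 + m$mu2) / 2 # lambda = 0 at the midpoint of means
  se <- sqrt(2 / n)
  expect_lt(abs(unname(boundary) - 1), 3 * se)
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(77)
  X <- cbind(rnorm(200), rnorm(200))
  X[101:200, ] <- X[101:200, ] + 1.5
  y <- rep(c("SVB", "VB"), each = 100)
  m <- fit_lda(X, y, priors = c(0.5, 0.5))
  ml <- MASS::lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  agree <- mean(predict(m, X) == predict(ml, X)$class)
  expect_gte(agree, 0.99)
  # coefficient direction matches up to scale
  ratio <- m$a_hat / as.numeric(ml$scaling)
  expect_equal(ratio[1], ratio[2], tolerance = 1e-6)
})

test_that("all four predictors are pure functions and serialize losslessly", {
  set.seed(12)
  tab <- gen_feature_table(n_per_class = 60, seed = 12)
  X <- tab$expanded[, c(6, 15, 18)]
  y <- tab$labels
  models <- list(
    tree = fit_tree(X, y),
    lda = fit_lda(X, y, priors = c(0.5, 0.5)),
    fuzzy = fit_fuzzy(X, y),
    cluster = { set.seed(1); fit_cluster(X, y, k = 3) })
  Xn <- tab$expanded[1:30, c(6, 15, 18)]
  for (nm in names(models)) {
    m <- models[[nm]]
    expect_identical(predict(m, Xn), predict(m, Xn), info = nm)
    path <- file.path(tempdir(), paste0(nm, ".json"))
    model_to_json(m, path)
    back <- model_from_json(path)
    expect_equal(predict(back, Xn), predict(m, Xn), info = nm)
  }
})
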
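# Independent brute-force oracles used to verify the optimised code paths.

# plain-R exhaustive split search, mirroring the documented contract:
# per-node prior reweighting, midpoint thresholds, left iff x < thr,
# ties to lowest feature index then lowest threshold
oracle_best_split <- function(X, y, criterion = "deviance",
                              priors = c(0.5, 0.5)) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("SVB", "VB"))
  n1 <- sum(y == "SVB"); n2 <- sum(y == "VB")
  if (n1 == 0 || n2 == 0) return(list(feature = NA, threshold = NA, goodness = NA))
  w <- c(priors[1] / n1, priors[2] / n2)
  ent <- function(p1) {
    s <- 0
    if (p1 > 0) s <- s - p1 * log(p1)
    if (p1 < 1) s <- s - (1 - p1) * log(1 - p1)
    s
  }
  gin <- function(p1) 2 * p1 * (1 - p1)
  parent <- switch(criterion, deviance = ent(priors[1]),
                   gini = gin(priors[1]), twoing = 0)
  best <- list(feature = NA, threshold = NA, goodness = -1)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (head(v, -1) + diff(v) / 2)) {
      left <- X[, j] < t
      m1L <- w[1] * sum(y[left] == "SVB"); m2L <- w[2] * sum(y[left] == "VB")
      m1R <- priors[1] - m1L; m2R <- priors[2] - m2L
      mL <- m1L + m2L; mR <- m1R + m2R
      if (mL <= 0 || mR <= 0) next
      good <- if (criterion == "twoing") {
        mL * mR / 4 * (abs(m1L / mL - m1R / mR) + abs(m2L / mL - m2R / mR))^2
      } else {
        f <- if (criterion == "deviance") ent else gin
        parent - mL * f(m1L / mL) - mR * f(m1R / mR)
      }
      if (good > best$goodness + 1e-12) best <- list(feature = j, threshold = t,
                                                     goodness = good)
    }
  }
  if (is.na(best$feature)) return(list(feature = NA, threshold = NA, goodness = NA))
  best
}

# literal 37-step threshold scan of the OCT basic rule
oracle_find_oct <- function(vel_windows, prev_oct = 90) {
  nb <- length(vel_windows)
  if (nb < 2) return(prev_oct)
  corr2 <- function(a, b) {
    ea <- sum(a^2); eb <- sum(b^2)
    if (ea <= 0 || eb <= 0) return(0)
    100 * sum(a * b) / sqrt(ea * eb)
  }
  for (thr in seq(98, 80, by = -0.5)) {
    n_ok <- 0
    for (i in seq_len(nb)) {
      matches <- 0
      for (j in seq_len(nb)) {
        if (i == j) next
        if (corr2(vel_windows[[i]], vel_windows[[j]]) >= thr)
          matches <- matches + 1
      }
      if (matches / (nb - 1) >= 0.25) n_ok <- n_ok + 1
    }
    if (n_ok / nb >= 0.75) return(thr)
  }
  80
}

# optimal k-partition of <= 6 points by total within-cluster squared distance
oracle_kmeans_partition <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n <= 6)
  assigns <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- NULL
  for (r in seq_len(nrow(assigns))) {
    a <- as.integer(assigns[r, ])
    if (length(unique(a)) < k) next
    ss <- 0
    cen <- matrix(NA_real_, k, ncol(X))
    for (j in seq_len(k)) {
      pts <- X[a == j, , drop = FALSE]
      cen[j, ] <- colMeans(pts)
      ss <- ss + sum(sweep(pts, 2, cen[j, ])^2)
    }
    if (is.null(best) || ss < best$ss) best <- list(ss = ss, centroids = cen,
                                                    assign = a)
  }
  best
}

# tiny synthetic beat contexts for Stage-1 unit tests: a nonnegative
# velocity "shape" vector padded to the 45-sample window
make_beat <- function(shape, qrs_dur = 80, p_wave = TRUE, mag = NULL) {
  vel <- numeric(45)
  vel[seq_along(shape)] <- shape
  if (is.null(mag)) mag <- cumsum(vel) + 0.1
  list(fiducial = 1000L, qrs_on = 990L, qrs_off = 990L + round(qrs_dur / 4),
       vel_win = vel, mag_win = mag, qrs_dur = qrs_dur,
       qrs_act = 100 * mean(mag) / max(mag),
       qrs_mob = 100 * sum(vel) / sum(mag), p_wave = p_wave)
}

# two orthogonal window shapes (disjoint support)
shape_narrow <- function() c(rep(0, 2), 1, 3, 1, rep(0, 10))
shape_wide <- function() c(rep(0, 20), 1, 2, 3, 3, 2, 1)
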
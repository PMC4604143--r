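## Synthetic data: (a) annotated two-lead ECG streams with narrow normal
## beats (P wave present) and wide premature ventricular beats (no P wave,
## compensatory pause) built from Gaussian bumps; (b) feature tables drawn
## from the class-conditional distributions observed at the Stage-2 input
## (continuous features Gaussian, discrete features categorical).

gauss_bump <- function(t, center, amp, sigma) amp * exp(-((t - center)^2) / (2 * sigma^2))

#' Generate an annotated synthetic two-lead ECG stream
#'
#' Normal beats are narrow (default 90 ms QRS) with a P wave; a fraction
#' `pvc_rate` of the post-learning beats is replaced by wide (default
#' 160 ms) premature ventricular beats without P wave, occurring at
#' `prematurity` of the underlying RR interval and followed by a
#' compensatory pause (the next normal beat keeps its grid position).
#' PVCs are never planted in the first 10 s (the learning period) and never
#' adjacent. Each beat is a sum of Gaussian bumps (P, QRS, T) on two leads;
#' Gaussian noise of RMS `noise_rms` is added per lead. Annotations mark
#' each R peak with N or V. A fixed seed makes the output byte-identical.
#'
#' @param duration_s record length in seconds (>= 30).
#' @param heart_rate underlying rate in bpm.
#' @param pvc_rate fraction of eligible beats replaced by PVCs, in \[0, 1).
#' @param prematurity PVC timing as a fraction of the RR interval.
#' @param noise_rms additive Gaussian noise RMS (mV).
#' @param p_wave_amp P-wave amplitude (mV).
#' @param qrs_width_normal,qrs_width_pvc QRS widths (ms).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return An [ecg_record()] with N/V annotations.
#' @export
gen_ecg_stream <- function(duration_s = 120, heart_rate = 75, pvc_rate = 0,
                           prematurity = 0.7, noise_rms = 0,
                           p_wave_amp = 0.15, qrs_width_normal = 90,
                           qrs_width_pvc = 160, fs = 250, seed = NULL) {
  if (duration_s < 30) stop("duration_s must be at least 30 s")
  if (pvc_rate < 0 || pvc_rate >= 1) stop("pvc_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  rr <- 60 / heart_rate
  grid <- seq(1.0, duration_s - 1.0, by = rr) # grid beat times (s)
  nbeat <- length(grid)
  is_pvc <- rep(FALSE, nbeat)
  # eligible: after the learning period, not first/last, not adjacent
  eligible <- which(grid > 12 & seq_len(nbeat) > 1 & seq_len(nbeat) < nbeat)
  n_pvc <- round(pvc_rate * nbeat)
  picked <- integer(0)
  for (j in sample(eligible)) {
    if (length(picked) >= n_pvc) break
    if (!any(abs(picked - j) <= 1)) picked <- c(picked, j)
  }
  is_pvc[picked] <- TRUE
  t_beat <- grid
  t_beat[picked] <- grid[picked - 1] + prematurity * rr
  tt <- (seq_len(round(duration_s * fs)) - 1) / fs
  l1 <- numeric(length(tt)); l2 <- numeric(length(tt))
  sig_n <- qrs_width_normal / 1000 / 4
  sig_v <- qrs_width_pvc / 1000 / 4
  for (k in seq_len(nbeat)) {
    tc <- t_beat[k]
    if (is_pvc[k]) {
      l1 <- l1 + gauss_bump(tt, tc, 1.3, sig_v) +
        gauss_bump(tt, tc + 0.28, -0.4, 0.06)
      l2 <- l2 + gauss_bump(tt, tc, -0.9, sig_v) +
        gauss_bump(tt, tc + 0.28, 0.3, 0.06)
    } else {
      l1 <- l1 + gauss_bump(tt, tc - 0.16, p_wave_amp, 0.022) +
        gauss_bump(tt, tc, 1.0, sig_n) +
        gauss_bump(tt, tc + 0.25, 0.3, 0.05)
      l2 <- l2 + gauss_bump(tt, tc - 0.16, 0.6 * p_wave_amp, 0.022) +
        gauss_bump(tt, tc, 0.6, sig_n) +
        gauss_bump(tt, tc + 0.25, 0.2, 0.05)
    }
  }
  if (noise_rms > 0) {
    l1 <- l1 + rnorm(length(tt), 0, noise_rms)
    l2 <- l2 + rnorm(length(tt), 0, noise_rms)
  }
  ann <- data.frame(sample = as.integer(round(t_beat * fs)),
                    source_label = ifelse(is_pvc, "V", "N"),
                    stringsAsFactors = FALSE)
  ecg_record(l1, l2, fs, ann)
}

#' Class-conditional distribution defaults of the 20 basic features
#'
#' Parameters of the class-conditional feature distributions at the Stage-2
#' input: observation frequencies for the discrete features F1-F5 and
#' mean/std for the continuous features F6-F20 (SVB vs VB).
#'
#' @return A list with `discrete` (per-feature per-class frequencies) and
#'   `continuous` (matrices `mean_svb`, `sd_svb`, `mean_vb`, `sd_vb`).
#' @export
feature_distribution_defaults <- function() {
  cont <- data.frame(
    feature = paste0("F", 6:20),
    mean_svb = c(89.4, 91.6, 91.8, 138.6, 122.7, 15.9, 124.8, 113.9, 10.9,
                 90.8, 93.4, -2.6, 100.1, 100.0, 4.7),
    sd_svb   = c(12.0, 12.5, 12.2, 50.0, 32.2, 44.7, 35.9, 32.9, 33.7,
                 22.4, 19.6, 18.4, 12.8, 12.0, 5.6),
    mean_vb  = c(60.6, 93.3, 93.5, 184.1, 126.4, 57.7, 172.0, 109.9, 62.1,
                 60.0, 92.5, -32.5, 73.1, 121.5, 5.7),
    sd_vb    = c(24.9, 15.8, 14.5, 38.4, 29.3, 39.4, 34.7, 29.2, 38.4,
                 19.0, 18.6, 22.3, 16.4, 23.1, 7.7))
  disc <- list(
    # match-code features: frequencies of (reference=0, other=1, none=-1)
    F1 = list(values = c(0, 1, -1), svb = c(0, 0.686, 0.314),
              vb = c(0, 0.713, 0.287)),
    F2 = list(values = c(0, 1, -1), svb = c(0.480, 0.311, 0.209),
              vb = c(0.823, 0.109, 0.068)),
    F3 = list(values = c(0, 1, -1), svb = c(0.489, 0.311, 0.200),
              vb = c(0.814, 0.108, 0.078)),
    # P-wave presence: frequency of 1
    F4 = list(values = c(1, 0), svb = c(0.874, 0.126), vb = c(0.620, 0.380)),
    F5 = list(values = c(1, 0), svb = c(0.902, 0.098), vb = c(0.949, 0.051)))
  list(discrete = disc, continuous = cont)
}

#' Generate a synthetic Stage-2 feature table
#'
#' Draws `n_per_class` beats per class: discrete features F1-F5 from the
#' class-conditional observation frequencies, continuous features F6-F20
#' from class-conditional Gaussians (defaults from
#' [feature_distribution_defaults()]), with an optional Gaussian-copula
#' correlation between F6 and F18. Correlation-type features (F6-F8) are
#' clipped to \[0, 100\]. The 210-column expansion is applied.
#'
#' @param n_per_class beats per class (>= 1).
#' @param params distribution parameters, as from
#'   [feature_distribution_defaults()].
#' @param rho_f6_f18 within-class correlation of the (F6, F18) pair
#'   (default 0: all continuous features independent).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return List with `basic` (2n x 20 matrix), `expanded` (2n x 210),
#'   `labels` (factor SVB/VB).
#' @export
gen_feature_table <- function(n_per_class = 5000,
                              params = feature_distribution_defaults(),
                              rho_f6_f18 = 0, seed = NULL) {
  stopifnot(n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_class <- function(cl, n) {
    out <- matrix(NA_real_, n, 20, dimnames = list(NULL, paste0("F", 1:20)))
    for (f in names(params$discrete)) {
      d <- params$discrete[[f]]
      pr <- if (cl == "SVB") d$svb else d$vb
      out[, f] <- sample(d$values, n, replace = TRUE, prob = pr)
    }
    cont <- params$continuous
    mu <- if (cl == "SVB") cont$mean_svb else cont$mean_vb
    sdv <- if (cl == "SVB") cont$sd_svb else cont$sd_vb
    z <- matrix(rnorm(n * nrow(cont)), n)
    if (rho_f6_f18 != 0) {
      i6 <- match("F6", cont$feature); i18 <- match("F18", cont$feature)
      z[, i18] <- rho_f6_f18 * z[, i6] + sqrt(1 - rho_f6_f18^2) * z[, i18]
    }
    for (j in seq_len(nrow(cont)))
      out[, cont$feature[j]] <- mu[j] + sdv[j] * z[, j]
    for (f in c("F6", "F7", "F8"))
      out[, f] <- pmin(pmax(out[, f], 0), 100)
    out
  }
  basic <- rbind(draw_class("SVB", n_per_class),
                 draw_class("VB", n_per_class))
  labels <- svb_vb_factor(rep(.classes, each = n_per_class))
  list(basic = basic, expanded = expand_features(basic), labels = labels)
}
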
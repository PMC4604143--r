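## The 20 basic time-domain features F1-F20 of a beat and their 210-element
## second-order expansion (20 basic values + 190 pairwise products).
##
## F1-F3   template match codes for current/previous/next beat
##         (reference = 0, other template = 1, no match = -1)
## F4-F5   P-wave presence of the current beat / reference template (0/1)
## F6-F8   correlation (%) of current/previous/next beat vs the reference
## F9-F11  QRSdur (ms): beat, reference, beat - reference
## F12-F14 QRSact (%): beat, reference, beat - reference
## F15-F17 QRSmob (%): beat, reference, beat - reference
## F18-F20 curRR, nextRR, relRRv (%)

#' QRS duration between the QRS boundaries
#' @param qrs_on,qrs_off 0-based boundary sample indices (`qrs_off >= qrs_on`).
#' @param fs sampling rate in Hz.
#' @return Duration in ms.
#' @export
qrs_duration <- function(qrs_on, qrs_off, fs = 250) {
  stopifnot(qrs_off >= qrs_on)
  (qrs_off - qrs_on) * 1000 / fs
}

#' Relative QRS activity
#'
#' Mean composite magnitude within the 180 ms window normalised to its
#' maximum: `100 * mean(mag) / max(mag)`; 0 for an all-zero window.
#'
#' @param mag_window 180 ms magnitude slice.
#' @return Percent.
#' @export
qrs_activity <- function(mag_window) {
  stopifnot(length(mag_window) > 0)
  mx <- max(mag_window)
  if (mx <= 0) {
    warning("all-zero magnitude window; QRSact set to 0")
    return(0)
  }
  100 * mean(mag_window) / mx
}

#' QRS mobility
#'
#' Velocity area over magnitude area within the 180 ms window:
#' `100 * sum(vel) / sum(mag)` — a time-domain higher/lower frequency
#' content ratio.
#'
#' @param vel_window,mag_window equal-length 180 ms slices.
#' @return Percent.
#' @export
qrs_mobility <- function(vel_window, mag_window) {
  stopifnot(length(vel_window) == length(mag_window))
  sm <- sum(mag_window)
  if (sm <= 0) {
    warning("zero magnitude area; QRSmob set to 0")
    return(0)
  }
  100 * sum(vel_window) / sm
}

#' RR-interval features
#'
#' `curRR`/`nextRR` are the current/next RR intervals normalised to the mean
#' of the last four RR intervals (fewer when fewer are available); `relRRv`
#' is the mean absolute successive difference of the trailing 10 s RR
#' intervals normalised to their mean.
#'
#' @param rr_last4 up to four preceding RR intervals (ms).
#' @param rr_cur,rr_next current and next RR interval (ms).
#' @param rr_10s RR intervals of the trailing 10 s (ms).
#' @return List with `curRR`, `nextRR`, `relRRv` in percent.
#' @export
rr_features <- function(rr_last4, rr_cur, rr_next, rr_10s) {
  if (!length(rr_last4) || !length(rr_10s))
    stop("at least one RR interval is required in rr_last4 and rr_10s")
  m4 <- mean(rr_last4)
  if (m4 <= 0) stop("mean of last-four RR intervals must be positive")
  rrv <- if (length(rr_10s) >= 2L) mean(abs(diff(rr_10s))) else 0
  list(curRR = 100 * rr_cur / m4,
       nextRR = 100 * rr_next / m4,
       relRRv = 100 * rrv / mean(rr_10s))
}

# learning-period defaults for the reference-template features
feature_defaults <- function() {
  list(p_wave = 1, corr = 80, qrs_dur = 100, qrs_act = 100, qrs_mob = 100)
}

match_code <- function(outcome) {
  switch(outcome, MATCHED_REFERENCE = 0, MATCHED_OTHER = 1, NONE = -1,
         stop("unknown Stage-1 outcome: ", outcome))
}

#' Assemble the 20 basic features of a beat
#'
#' Combines the Stage-1 outcomes and morphology descriptors of the beat and
#' its neighbours with the reference-template descriptors and the RR
#' features. During the learning period (no reference template,
#' `ref = NULL`) the defaults are used for the reference-side quantities:
#' P wave present, corr = 80%, QRSdur = 100 ms, QRSact = 100%,
#' QRSmob = 100%. Missing neighbours at record edges take the same defaults
#' (match code 0, corr 80, P wave present).
#'
#' @param beat a [beat_context()] of the current beat.
#' @param outcome,prev_outcome,next_outcome Stage-1 outcomes
#'   (`"MATCHED_REFERENCE"`, `"MATCHED_OTHER"`, `"NONE"`) of the current,
#'   previous and next beat; `NULL` neighbour outcome means a record edge.
#' @param corr_cur,corr_prev,corr_next correlations (%) of the current,
#'   previous and next beat against the reference template (`NA` allowed for
#'   missing neighbours or during learning).
#' @param ref the reference template (a `template_bank` template) or `NULL`
#'   during the learning period.
#' @param rr output of [rr_features()].
#' @return Named numeric vector `F1` .. `F20`.
#' @export
assemble_basic <- function(beat, outcome, prev_outcome = NULL,
                           next_outcome = NULL, corr_cur = NA,
                           corr_prev = NA, corr_next = NA, ref = NULL,
                           rr = list(curRR = 100, nextRR = 100, relRRv = 0)) {
  d <- feature_defaults()
  f <- numeric(20)
  f[1] <- match_code(outcome)
  f[2] <- if (is.null(prev_outcome)) 0 else match_code(prev_outcome)
  f[3] <- if (is.null(next_outcome)) 0 else match_code(next_outcome)
  f[4] <- as.numeric(isTRUE(beat$p_wave))
  f[5] <- if (is.null(ref)) d$p_wave else as.numeric(isTRUE(ref$p_wave))
  f[6] <- if (is.na(corr_cur)) d$corr else corr_cur
  f[7] <- if (is.na(corr_prev)) d$corr else corr_prev
  f[8] <- if (is.na(corr_next)) d$corr else corr_next
  f[9] <- beat$qrs_dur
  f[10] <- if (is.null(ref)) d$qrs_dur else ref$qrs_dur
  f[11] <- f[9] - f[10]
  f[12] <- beat$qrs_act
  f[13] <- if (is.null(ref)) d$qrs_act else ref$qrs_act
  f[14] <- f[12] - f[13]
  f[15] <- beat$qrs_mob
  f[16] <- if (is.null(ref)) d$qrs_mob else ref$qrs_mob
  f[17] <- f[15] - f[16]
  f[18] <- rr$curRR
  f[19] <- rr$nextRR
  f[20] <- rr$relRRv
  names(f) <- paste0("F", 1:20)
  f
}

#' Names of the expanded feature vector
#'
#' The deterministic column order of the expansion: the `n` basic features
#' `F1..Fn` followed by the `n(n-1)/2` pairwise products `FixFj` for
#' unordered pairs `i < j` in lexicographic order (`F1xF2, F1xF3, ...,
#' F19xF20`). For `n = 20` the length is 210.
#'
#' @param n number of basic features (default 20).
#' @return Character vector of column names.
#' @export
expanded_feature_names <- function(n = 20) {
  base <- paste0("F", seq_len(n))
  if (n < 2L) return(base)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  c(base, paste0("F", pairs[, "row"], "xF", pairs[, "col"]))
}

#' Second-order expansion of a basic feature vector
#'
#' Returns the basic features followed by all pairwise products `fi * fj`
#' (`i < j`, lexicographic pair order, no squared terms):
#' `n + n(n-1)/2` values, i.e. 210 for the 20 basic features.
#'
#' @param basic numeric vector (or matrix with beats in rows) of basic
#'   features; all values must be finite.
#' @return A named numeric vector, or a matrix when `basic` is a matrix.
#' @export
expand_features <- function(basic) {
  if (is.matrix(basic)) {
    out <- t(apply(basic, 1, expand_features))
    colnames(out) <- expanded_feature_names(ncol(basic))
    return(out)
  }
  if (!all(is.finite(basic))) stop("basic features must all be finite")
  n <- length(basic)
  if (n < 2L) {
    out <- basic
    names(out) <- expanded_feature_names(n)
    return(out)
  }
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  out <- c(basic, basic[pairs[, "row"]] * basic[pairs[, "col"]])
  names(out) <- expanded_feature_names(n)
  out
}

# ---------------------------------------------------------------------------
# TSV interchange: beat id + 20 basic + 210 expanded columns (231 columns)

#' Write a feature table in the TSV interchange format
#'
#' Fixed 232-column layout: `beat_id`, `label`, the 20 basic features, then
#' the 210 expanded columns.
#'
#' @param basic matrix of basic features (beats in rows, 20 columns).
#' @param labels SVB/VB class labels.
#' @param path output file.
#' @export
write_feature_table <- function(basic, labels, path) {
  expanded <- expand_features(basic)
  df <- data.frame(beat_id = seq_len(nrow(basic)) - 1L,
                   label = as.character(labels), check.names = FALSE)
  b <- as.data.frame(basic); names(b) <- paste0("basic_", paste0("F", 1:20))
  e <- as.data.frame(expanded)
  write.table(cbind(df, b, e), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV file.
#' @return List with `basic` (matrix), `expanded` (matrix), `labels` (factor).
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  basic <- as.matrix(df[, paste0("basic_F", 1:20)])
  colnames(basic) <- paste0("F", 1:20)
  expanded <- as.matrix(df[, expanded_feature_names(20)])
  list(basic = basic, expanded = expanded,
       labels = svb_vb_factor(df$label))
}
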
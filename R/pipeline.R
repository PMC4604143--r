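## End-to-end two-stage classification of a record: Stage-1 template
## learning/matching with per-10-s ACT adaptation, feature extraction for
## the non-matched beats, and a Stage-2 model decision. Stage-2 decisions
## are delayed by one beat (the next beat's Stage-1 outcome enters the
## feature vector); the final beat uses the learning-period defaults for
## the missing neighbour.

#' Run the two-stage beat classifier over a record
#'
#' The record must be preprocessed (250 Hz; see [resample_linear()] and
#' [bandpass()]). Detections default to the annotation fiducials; a custom
#' detector can be plugged in and is paired to the annotations within
#' 150 ms. The reference template is learned on the first 10 s segment
#' containing beats; every later beat is matched against the template bank
#' (reference-matched beats are fast-assigned to SVB), and non-matched
#' beats receive the 20 basic features, the 210-column expansion and a
#' Stage-2 model decision. Learning-period beats are replayed against the
#' learned bank (without updating it) and use the learning-period default
#' reference features.
#'
#' @param record an [ecg_record()] at 250 Hz with annotations.
#' @param model a trained Stage-2 model (`cluster_model`, `fuzzy_model`,
#'   `lda_model` or `beat_tree`), or `NULL` to run Stage 1 and feature
#'   extraction only (Stage-2 decisions reported as `NA`) — useful for
#'   building training feature tables from annotated records.
#' @param feature_idx column indices of the 210-column expansion the model
#'   was trained on; defaults to matching the model's stored feature names.
#' @param detector optional function `(record) -> sample indices`; `NULL`
#'   uses the annotation fiducials directly.
#' @param learning_s learning-period length in seconds (default 10).
#' @return List of class `two_stage_result`: `decisions` (one row per
#'   scored beat: `sample`, `source_label`, `aami`, `binary`, `outcome`,
#'   `corr_ref`, `provenance`, `decision`), `bank` (final template bank),
#'   `basic` (matrix of basic features of the scored beats),
#'   `unpaired_detections`, `skipped` (fiducials without delineation
#'   margin).
#' @export
run_two_stage <- function(record, model = NULL, feature_idx = NULL,
                          detector = NULL, learning_s = 10) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- length(record$lead1)
  if (n / fs <= learning_s)
    stop("record shorter than the learning period")
  if (!is.null(model) && is.null(feature_idx)) {
    feature_idx <- match(model$feature_names, expanded_feature_names(20))
    if (anyNA(feature_idx))
      stop("cannot map the model's feature names onto the 210-column expansion; pass feature_idx")
  }
  ann <- record$annotations
  if (!nrow(ann)) stop("record has no annotations")
  unpaired <- numeric(0)
  if (is.null(detector)) {
    scored <- ann
  } else {
    det <- sort(detector(record))
    pr <- pair_detections(det, ann$sample, fs = fs)
    scored <- ann[pr$pairs$ann_idx, , drop = FALSE]
    scored$sample <- pr$pairs$detection
    unpaired <- pr$unpaired_detections
  }
  scored <- scored[order(scored$sample), , drop = FALSE]
  comp <- composite_leads(record)
  ctx <- lapply(scored$sample, function(s)
    suppressWarnings(beat_context(comp$vel, comp$mag, s, fs)))
  ok <- !vapply(ctx, is.null, TRUE)
  skipped <- scored$sample[!ok]
  scored <- scored[ok, , drop = FALSE]
  ctx <- ctx[ok]
  nb <- nrow(scored)
  if (!nb) stop("no delineable beats in the record")
  fid <- scored$sample
  seg_len <- learning_s * fs
  seg_of <- floor(fid / seg_len) # 0-based segment index
  # learning segment: first one containing beats
  learn_seg <- min(seg_of)
  learn_idx <- which(seg_of == learn_seg)
  bank <- learn_reference(ctx[learn_idx])
  outcome <- character(nb)
  corr_ref <- numeric(nb)
  # replay learning beats against the learned bank without updating it
  for (i in learn_idx) {
    mu <- match_and_update(ctx[[i]], bank, beat_index = i)
    outcome[i] <- mu$outcome
    corr_ref[i] <- mu$corr_ref
  }
  # stream the remaining beats with per-segment ACT adaptation
  rest <- which(seg_of > learn_seg)
  if (length(rest)) {
    cur_seg <- seg_of[rest[1]]
    seg_wins <- list()
    close_segment <- function() {
      oct <- find_oct(seg_wins, prev_oct = tail_oct(bank))
      bank$oct_history <<- c(bank$oct_history, oct)
      bank$act <<- update_act(bank$act, oct)
      bank$segment_index <<- bank$segment_index + 1L
      seg_wins <<- list()
    }
    for (i in rest) {
      if (seg_of[i] > cur_seg) {
        close_segment()
        cur_seg <- seg_of[i]
      }
      mu <- match_and_update(ctx[[i]], bank, beat_index = i)
      outcome[i] <- mu$outcome
      corr_ref[i] <- mu$corr_ref
      bank <- mu$bank
      seg_wins[[length(seg_wins) + 1L]] <- ctx[[i]]$vel_win
    }
    close_segment()
  }
  # second pass: features + Stage-2 decisions (delayed by one beat)
  ref <- bank$templates[[which(vapply(bank$templates, `[[`, TRUE,
                                      "is_reference"))[1]]]
  rr_ms <- diff(fid) * 1000 / fs
  basic <- matrix(NA_real_, nb, 20, dimnames = list(NULL, paste0("F", 1:20)))
  decision <- character(nb)
  provenance <- character(nb)
  for (i in seq_len(nb)) {
    in_learning <- seg_of[i] == learn_seg
    rr_cur <- if (i > 1) rr_ms[i - 1] else NA
    rr_next <- if (i < nb) rr_ms[i] else NA
    last4 <- if (i > 1) rr_ms[max(1, i - 4):(i - 1)] else numeric(0)
    in10 <- which(fid >= fid[i] - 10 * fs & fid <= fid[i])
    rr10 <- if (length(in10) >= 2) diff(fid[in10]) * 1000 / fs else numeric(0)
    rr <- if (!length(last4)) {
      list(curRR = 100, nextRR = 100, relRRv = 0)
    } else {
      rr_features(last4, rr_cur,
                  if (is.na(rr_next)) mean(last4) else rr_next,
                  if (length(rr10)) rr10 else last4)
    }
    basic[i, ] <- assemble_basic(
      ctx[[i]], outcome[i],
      prev_outcome = if (i > 1) outcome[i - 1] else NULL,
      next_outcome = if (i < nb) outcome[i + 1] else NULL,
      corr_cur = if (in_learning) NA else corr_ref[i],
      corr_prev = if (i > 1 && seg_of[i - 1] > learn_seg) corr_ref[i - 1] else NA,
      corr_next = if (i < nb && seg_of[i + 1] > learn_seg) corr_ref[i + 1] else NA,
      ref = if (in_learning) NULL else ref,
      rr = rr)
    if (outcome[i] == "MATCHED_REFERENCE") {
      decision[i] <- "SVB"
      provenance[i] <- "stage1"
    } else {
      provenance[i] <- "stage2"
    }
  }
  s2 <- which(provenance == "stage2")
  if (length(s2)) {
    if (is.null(model)) {
      decision[s2] <- NA_character_
    } else {
      expanded <- expand_features(basic[s2, , drop = FALSE])
      decision[s2] <- as.character(
        predict(model, expanded[, feature_idx, drop = FALSE]))
    }
  }
  structure(list(
    decisions = data.frame(sample = fid,
                           source_label = scored$source_label,
                           aami = scored$aami, binary = scored$binary,
                           outcome = outcome, corr_ref = corr_ref,
                           provenance = provenance, decision = decision,
                           segment = seg_of, stringsAsFactors = FALSE),
    bank = bank, basic = basic, unpaired_detections = unpaired,
    skipped = skipped, learning_segment = learn_seg),
    class = "two_stage_result")
}

tail_oct <- function(bank) bank$oct_history[length(bank$oct_history)]

#' @export
print.two_stage_result <- function(x, ...) {
  d <- x$decisions
  cat(sprintf("<two_stage_result> %d scored beat(s): %d stage1 fast-track, %d stage2\n",
              nrow(d), sum(d$provenance == "stage1"),
              sum(d$provenance == "stage2")))
  print(score_combined(d$decision, d$aami))
  invisible(x)
}

#' Evaluate a two-stage run
#'
#' @param result a `two_stage_result`.
#' @param post_learning_only drop the learning-segment beats from scoring
#'   (default FALSE).
#' @return List with `stage1` counts + metrics (reference-match
#'   accounting) and the combined `report` from [score_combined()].
#' @export
evaluate_two_stage <- function(result, post_learning_only = FALSE) {
  d <- result$decisions
  if (post_learning_only) d <- d[d$segment > result$learning_segment, ]
  st1 <- score_stage1(d$outcome == "MATCHED_REFERENCE", d$binary)
  list(stage1 = list(counts = st1, metrics = beat_metrics(st1)),
       report = score_combined(d$decision, d$aami))
}
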
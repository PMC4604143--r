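## Se/Sp/PPV accounting for the SVB/VB task. Negatives are the SVB class
## (N+S beats), positives the VB class (V+F beats); Q beats are excluded
## from all counts.

#' Confusion counts for SVB/VB decisions
#'
#' @param truth,decision SVB/VB factors (or character vectors) of equal
#'   length; rows with a truth outside SVB/VB are excluded.
#' @return List of class `confusion_counts`: `TN`, `FP`, `TP`, `FN`.
#' @export
confusion_counts <- function(truth, decision) {
  truth <- as.character(truth); decision <- as.character(decision)
  keep <- truth %in% .classes
  truth <- truth[keep]; decision <- decision[keep]
  structure(list(
    TN = sum(truth == "SVB" & decision == "SVB"),
    FP = sum(truth == "SVB" & decision == "VB"),
    TP = sum(truth == "VB" & decision == "VB"),
    FN = sum(truth == "VB" & decision == "SVB")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TN=%d FP=%d TP=%d FN=%d\n",
              x$TN, x$FP, x$TP, x$FN))
  m <- beat_metrics(x)
  cat(sprintf("  Se=%s Sp=%s PPV=%s\n",
              fmt_pct(m$Se), fmt_pct(m$Sp), fmt_pct(m$PPV)))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f%%", x)

#' Sensitivity, specificity and positive predictive value
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `PPV = TP/(TP+FP)`, each in
#' percent. A metric with a zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts a [confusion_counts()] object or a list with TN/FP/TP/FN.
#' @return List with `Se`, `Sp`, `PPV` in percent.
#' @export
beat_metrics <- function(counts) {
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(Se = safe(counts$TP, counts$TP + counts$FN),
       Sp = safe(counts$TN, counts$TN + counts$FP),
       PPV = safe(counts$TP, counts$TP + counts$FP))
}

#' Stage-1 confusion counts
#'
#' Stage-1 accounting treats a match to the predominant (reference) template
#' as an SVB decision: TN = N/S beats matched, FP = N/S beats non-matched,
#' TP = V/F beats non-matched, FN = V/F beats matched. Beats matched to a
#' non-reference template count as non-matched. Q beats are excluded.
#'
#' @param matched logical: beat matched the reference template.
#' @param binary SVB/VB/EXCLUDED annotation classes.
#' @return A [confusion_counts()] object.
#' @export
score_stage1 <- function(matched, binary) {
  confusion_counts(binary, ifelse(matched, "SVB", "VB"))
}

#' Combined two-stage evaluation report
#'
#' Pools the Stage-1 fast-track SVB assignments with the Stage-2 decisions:
#' TN = N/S beats decided SVB by either stage, FP = N/S beats decided VB,
#' TP = V/F beats decided VB, FN = V/F beats decided SVB. The V-only
#' figures restrict the positive class to beats annotated V (F beats are
#' excluded from both the Se denominator and the PPV numerator/denominator).
#'
#' @param decisions SVB/VB decisions per scored beat.
#' @param aami AAMI classes (N, S, V, F, Q) per beat; Q beats are excluded.
#' @return List of class `eval_report` with `combined` counts + metrics and
#'   `v_only` Se/PPV.
#' @export
score_combined <- function(decisions, aami) {
  decisions <- as.character(decisions); aami <- as.character(aami)
  keep <- aami %in% c("N", "S", "V", "F")
  decisions <- decisions[keep]; aami <- aami[keep]
  binary <- ifelse(aami %in% c("N", "S"), "SVB", "VB")
  combined <- confusion_counts(binary, decisions)
  keep_v <- aami != "F"
  v_counts <- confusion_counts(ifelse(aami[keep_v] == "V", "VB", "SVB"),
                               decisions[keep_v])
  mv <- beat_metrics(v_counts)
  structure(list(combined = combined,
                 metrics = beat_metrics(combined),
                 v_only = list(counts = v_counts, Se = mv$Se, PPV = mv$PPV)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n combined: ")
  print(x$combined)
  cat(sprintf(" V-only: Se=%s PPV=%s\n", fmt_pct(x$v_only$Se),
              fmt_pct(x$v_only$PPV)))
  invisible(x)
}

#' Beat-count bookkeeping of a Stage-1 run
#'
#' From the number of reference-matched beats, the total analysed beats and
#' the per-class counts fed to Stage 2, computes the fast-track and residual
#' percentages and checks that the Stage-2 class counts sum to the
#' non-matched total.
#'
#' @param matched number of beats matched to the reference template.
#' @param total total analysed beats.
#' @param stage2_counts named vector of per-class beat counts fed to Stage 2.
#' @return List with `matched_pct`, `nonmatched_pct` (one decimal, as
#'   printed in reports), `nonmatched` and `stage2_total`.
#' @export
stage1_count_summary <- function(matched, total, stage2_counts = NULL) {
  nonmatched <- total - matched
  out <- list(matched_pct = round(100 * matched / total, 1),
              nonmatched_pct = round(100 * nonmatched / total, 1),
              nonmatched = nonmatched,
              stage2_total = if (is.null(stage2_counts)) NA_integer_
                             else sum(stage2_counts))
  out
}
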
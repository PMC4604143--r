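## Stage 1: PQRST waveform preprocessor. Learns the predominant (reference)
## beat template in the first 10 s, maintains a bank of up to 8 templates,
## and fast-assigns beats whose composite-velocity correlation against the
## reference exceeds the adaptive correlation threshold (ACT) to the SVB
## class. The ACT tracks a per-10-s optimal correlation threshold (OCT).

# 180 ms analysis window after QRS onset, in samples
stage1_window <- function(fs = 250) as.integer(round(0.180 * fs))

# half-open slice [start, start + n) of x, zero-padded at record edges;
# start is 0-based
slice_window <- function(x, start, n) {
  idx <- start + seq_len(n) # 1-based positions start+1 .. start+n
  out <- numeric(n)
  ok <- idx >= 1L & idx <= length(x)
  out[ok] <- x[idx[ok]]
  out
}

#' Delineate QRS boundaries around a fiducial point
#'
#' The onset is the last sample before the fiducial where the smoothed
#' composite velocity stays below 10% of the beat's peak velocity for at
#' least 20 ms (searched up to 150 ms back); the offset is found
#' symmetrically forward (searched up to 300 ms). On a flat (degenerate)
#' signal the fallback is `fiducial - 1` / `fiducial + 1`.
#'
#' @param vel,mag composite velocity and magnitude series.
#' @param fiducial 0-based sample index of the beat (R-peak position).
#' @param fs sampling rate in Hz.
#' @return A list with 0-based `qrs_on` and `qrs_off`.
#' @export
delineate_qrs <- function(vel, mag, fiducial, fs = 250) {
  n <- length(vel)
  margin <- as.integer(round(0.300 * fs))
  if (fiducial < margin || fiducial > n - 1L - margin) {
    warning("beat at sample ", fiducial, " lacks the 300 ms delineation margin; skipped")
    return(NULL)
  }
  # 5-point moving-average smoothing of the velocity
  k <- 5L
  sm <- as.numeric(stats::filter(vel, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  back <- as.integer(round(0.150 * fs))
  fwd <- as.integer(round(0.300 * fs))
  run <- as.integer(round(0.020 * fs)) # >= 20 ms below threshold
  seg <- sm[(fiducial - back + 1L):(fiducial + back + 1L)] # peak search near beat
  peak <- max(seg)
  if (peak <= 0) {
    return(list(qrs_on = fiducial - 1L, qrs_off = fiducial + 1L))
  }
  thr <- 0.10 * peak
  below <- function(i) sm[i + 1L] < thr # i is 0-based
  # onset: scan backwards from fiducial for a run of `run` quiet samples
  qrs_on <- NA_integer_
  i <- fiducial - 1L
  quiet <- 0L
  while (i >= fiducial - back) {
    quiet <- if (below(i)) quiet + 1L else 0L
    if (quiet >= run) { qrs_on <- i + quiet - 1L; break }
    i <- i - 1L
  }
  if (is.na(qrs_on)) qrs_on <- fiducial - back
  # offset: symmetric forward scan
  qrs_off <- NA_integer_
  i <- fiducial + 1L
  quiet <- 0L
  while (i <= fiducial + fwd) {
    quiet <- if (below(i)) quiet + 1L else 0L
    if (quiet >= run) { qrs_off <- i - quiet + 1L; break }
    i <- i + 1L
  }
  if (is.na(qrs_off)) qrs_off <- fiducial + fwd
  if (qrs_on >= qrs_off) { qrs_on <- fiducial - 1L; qrs_off <- fiducial + 1L }
  list(qrs_on = as.integer(qrs_on), qrs_off = as.integer(qrs_off))
}

#' Detect a P wave preceding a QRS onset
#'
#' Looks for a local maximum of the composite magnitude within
#' `[qrs_on - 200 ms, qrs_on - 40 ms]` exceeding both 5% of the beat's peak
#' magnitude and twice the search window's median magnitude. With less than
#' 200 ms of signal before the onset, the learning-period default (`TRUE`)
#' is returned.
#'
#' @param mag composite magnitude series.
#' @param qrs_on 0-based QRS onset index.
#' @param fs sampling rate in Hz.
#' @return Logical: P wave present.
#' @export
detect_p_wave <- function(mag, qrs_on, fs = 250) {
  pre <- as.integer(round(0.200 * fs))
  gap <- as.integer(round(0.040 * fs))
  if (qrs_on - pre < 0L) return(TRUE)
  win <- mag[(qrs_on - pre + 1L):(qrs_on - gap + 1L)]
  if (length(win) < 3L) return(TRUE)
  peak_beat <- max(slice_window(mag, qrs_on, stage1_window(fs)))
  # interior local maxima of the search window
  locmax <- which(diff(sign(diff(win))) < 0) + 1L
  if (!length(locmax)) return(FALSE)
  best <- max(win[locmax])
  best > 0.05 * peak_beat && best > 2 * median(win)
}

#' Correlation of a beat velocity window against a template
#'
#' `corr = 100 * sum(Bvel * Tvel) / sqrt(sum(Bvel^2) * sum(Tvel^2))` (%),
#' which lies in \[0, 100\] for nonnegative velocity windows and is invariant
#' to positive scaling of either window.
#'
#' @param beat_vel,template_vel equal-length 180 ms velocity windows.
#' @return Correlation in percent.
#' @export
correlation <- function(beat_vel, template_vel) {
  if (length(beat_vel) != length(template_vel))
    stop("beat and template windows must have equal length")
  et <- sum(template_vel^2)
  if (et <= 0) stop("template velocity window has zero energy")
  eb <- sum(beat_vel^2)
  if (eb <= 0) {
    warning("zero-energy beat window; correlation set to 0")
    return(0)
  }
  100 * sum(beat_vel * template_vel) / sqrt(eb * et)
}

# pairwise correlation matrix of a list of velocity windows (zero-energy
# windows correlate 0 with everything)
corr_matrix <- function(wins) {
  m <- do.call(rbind, wins)
  e <- sqrt(rowSums(m^2))
  cp <- m %*% t(m)
  denom <- outer(e, e)
  out <- matrix(0, nrow(m), nrow(m))
  ok <- denom > 0
  out[ok] <- 100 * cp[ok] / denom[ok]
  out
}

#' Optimal correlation threshold of a 10 s segment
#'
#' Scans thresholds from 98% downwards in 0.5% steps and returns the highest
#' one satisfying the basic rule: at least 75% of the segment's beats
#' correlate at or above the threshold with at least 25% of the other beats.
#' Returns 80 if no threshold qualifies, and `prev_oct` (default 90) for
#' segments with fewer than two beats.
#'
#' @param vel_windows list of 180 ms velocity windows of the segment's beats.
#' @param prev_oct fallback for segments with < 2 beats.
#' @return The OCT in percent.
#' @export
find_oct <- function(vel_windows, prev_oct = 90) {
  nb <- length(vel_windows)
  if (nb < 2L) return(prev_oct)
  cm <- corr_matrix(vel_windows)
  diag(cm) <- NA
  for (thr in seq(98, 80, by = -0.5)) {
    frac_match <- rowMeans(cm >= thr, na.rm = TRUE)
    if (mean(frac_match >= 0.25) >= 0.75) return(thr)
  }
  80
}

#' Adaptive correlation threshold update
#'
#' `ACT(i) = 0.75 * ACT(i-1) + 0.25 * OCT(i-1)`, clipped to \[80, 98\].
#'
#' @param act_prev,oct_prev previous ACT and OCT in percent.
#' @return The updated ACT.
#' @export
update_act <- function(act_prev, oct_prev) {
  min(98, max(80, 0.75 * act_prev + 0.25 * oct_prev))
}

# ---------------------------------------------------------------------------
# Beat contexts and templates

#' Build the Stage-1 context of one beat
#'
#' Delineates the QRS, slices the 180 ms velocity and magnitude windows from
#' the onset, and computes the per-beat morphology descriptors.
#'
#' @param vel,mag composite leads.
#' @param fiducial 0-based beat fiducial (R-peak) index.
#' @param fs sampling rate in Hz.
#' @return A list (`beat_context`) with `fiducial`, `qrs_on`, `qrs_off`,
#'   `vel_win`, `mag_win`, `qrs_dur` (ms), `qrs_act` (%), `qrs_mob` (%),
#'   `p_wave`; or `NULL` when the beat lacks the delineation margin.
#' @export
beat_context <- function(vel, mag, fiducial, fs = 250) {
  d <- delineate_qrs(vel, mag, fiducial, fs)
  if (is.null(d)) return(NULL)
  n <- stage1_window(fs)
  vw <- slice_window(vel, d$qrs_on, n)
  mw <- slice_window(mag, d$qrs_on, n)
  list(fiducial = fiducial, qrs_on = d$qrs_on, qrs_off = d$qrs_off,
       vel_win = vw, mag_win = mw,
       qrs_dur = qrs_duration(d$qrs_on, d$qrs_off, fs),
       qrs_act = qrs_activity(mw),
       qrs_mob = qrs_mobility(vw, mw),
       p_wave = detect_p_wave(mag, d$qrs_on, fs))
}

new_template <- function(beat, is_reference = FALSE, beat_index = 0L) {
  list(vel_avg = beat$vel_win, mag_avg = beat$mag_win, members = 1L,
       qrs_dur = beat$qrs_dur, qrs_act = beat$qrs_act, qrs_mob = beat$qrs_mob,
       p_wave = beat$p_wave, is_reference = is_reference, last_hit = beat_index)
}

# exponential running average with new-beat weight `w`
blend_template <- function(tpl, beat, beat_index, w = 1 / 8) {
  tpl$vel_avg <- (1 - w) * tpl$vel_avg + w * beat$vel_win
  tpl$mag_avg <- (1 - w) * tpl$mag_avg + w * beat$mag_win
  tpl$qrs_dur <- (1 - w) * tpl$qrs_dur + w * beat$qrs_dur
  tpl$qrs_act <- (1 - w) * tpl$qrs_act + w * beat$qrs_act
  tpl$qrs_mob <- (1 - w) * tpl$qrs_mob + w * beat$qrs_mob
  tpl$members <- tpl$members + 1L
  tpl$last_hit <- beat_index
  tpl
}

#' Learn the predominant (reference) beat template from the learning period
#'
#' Beats of the learning window (first 10 s) are greedily grouped into
#' subgroups of similar morphology: a beat joins the first subgroup whose
#' running average it correlates with at or above the grouping threshold,
#' otherwise it founds a new subgroup. Each subgroup is scored by
#' `0.7 * members/max_members + 0.3 * (1 - qrs_dur/max_qrs_dur)` (the largest
#' subgroup with the shortest QRS duration); the winner's average becomes the
#' reference template and the ACT is initialised to the segment's OCT.
#'
#' @param beats list of [beat_context()] objects from the learning window.
#' @param size_weight,dur_weight subgroup score weights (default 0.7 / 0.3).
#' @return A `template_bank`: list with `templates` (reference first), `act`,
#'   `oct_history`, `segment_index`.
#' @export
learn_reference <- function(beats, size_weight = 0.7, dur_weight = 0.3) {
  beats <- Filter(Negate(is.null), beats)
  if (!length(beats)) stop("no beats in the learning window; learning deferred")
  oct0 <- find_oct(lapply(beats, `[[`, "vel_win"), prev_oct = 90)
  groups <- list() # each: list(sum_vel, sum_mag, members, idx)
  for (b in seq_along(beats)) {
    beat <- beats[[b]]
    placed <- FALSE
    for (g in seq_along(groups)) {
      avg <- groups[[g]]$sum_vel / groups[[g]]$members
      cr <- if (sum(avg^2) > 0 && sum(beat$vel_win^2) > 0)
        correlation(beat$vel_win, avg) else 0
      if (cr >= oct0) {
        groups[[g]]$sum_vel <- groups[[g]]$sum_vel + beat$vel_win
        groups[[g]]$sum_mag <- groups[[g]]$sum_mag + beat$mag_win
        groups[[g]]$members <- groups[[g]]$members + 1L
        groups[[g]]$idx <- c(groups[[g]]$idx, b)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- list(sum_vel = beat$vel_win,
                                            sum_mag = beat$mag_win,
                                            members = 1L, idx = b)
    }
  }
  sizes <- vapply(groups, `[[`, 0L, "members")
  durs <- vapply(groups, function(g)
    mean(vapply(beats[g$idx], `[[`, 0, "qrs_dur")), 0)
  score <- size_weight * sizes / max(sizes) +
    dur_weight * (1 - durs / max(max(durs), .Machine$double.eps))
  win <- which.max(score)
  g <- groups[[win]]
  members <- beats[g$idx]
  ref <- list(
    vel_avg = g$sum_vel / g$members,
    mag_avg = g$sum_mag / g$members,
    members = g$members,
    qrs_dur = durs[win],
    qrs_act = mean(vapply(members, `[[`, 0, "qrs_act")),
    qrs_mob = mean(vapply(members, `[[`, 0, "qrs_mob")),
    p_wave = mean(vapply(members, `[[`, TRUE, "p_wave")) >= 0.5,
    is_reference = TRUE, last_hit = 0L
  )
  structure(list(templates = list(ref), act = oct0,
                 oct_history = oct0, segment_index = 1L),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d template(s), ACT = %.1f%%, segment %d\n",
              length(x$templates), x$act, x$segment_index))
  for (i in seq_along(x$templates)) {
    t <- x$templates[[i]]
    cat(sprintf("  [%d]%s members=%d QRSdur=%.0f ms P=%s\n", i,
                if (t$is_reference) "*" else " ", t$members, t$qrs_dur,
                t$p_wave))
  }
  invisible(x)
}

#' Match a beat against the template bank and update it
#'
#' The beat is first compared to the reference template: correlation at or
#' above the ACT yields `MATCHED_REFERENCE` (the Stage-1 SVB fast track) and
#' a running-average update of the reference (new-beat weight 1/8).
#' Otherwise the non-reference templates are tried in bank order; the first
#' with correlation at or above the ACT yields `MATCHED_OTHER` and is
#' updated. With no match the outcome is `NONE` and a new single-member
#' template is created iff the bank holds fewer than 8 templates (no
#' replacement).
#'
#' @param beat a [beat_context()].
#' @param bank a `template_bank` with a reference template.
#' @param beat_index running beat counter recorded as `last_hit`.
#' @return List: `outcome` (`"MATCHED_REFERENCE"`, `"MATCHED_OTHER"`,
#'   `"NONE"`), `template` (index matched or created, `NA` if the bank was
#'   full), `corr_ref` (correlation vs the reference), updated `bank`.
#' @export
match_and_update <- function(beat, bank, beat_index = 0L) {
  stopifnot(inherits(bank, "template_bank"), length(bank$templates) >= 1L)
  tpls <- bank$templates
  ref_i <- which(vapply(tpls, `[[`, TRUE, "is_reference"))[1]
  beat_zero <- sum(beat$vel_win^2) <= 0
  cr <- function(tpl) {
    if (beat_zero || sum(tpl$vel_avg^2) <= 0) 0
    else suppressWarnings(correlation(beat$vel_win, tpl$vel_avg))
  }
  corr_ref <- cr(tpls[[ref_i]])
  if (corr_ref >= bank$act) {
    bank$templates[[ref_i]] <- blend_template(tpls[[ref_i]], beat, beat_index)
    return(list(outcome = "MATCHED_REFERENCE", template = ref_i,
                corr_ref = corr_ref, bank = bank))
  }
  for (i in seq_along(tpls)) {
    if (i == ref_i) next
    if (cr(tpls[[i]]) >= bank$act) {
      bank$templates[[i]] <- blend_template(tpls[[i]], beat, beat_index)
      return(list(outcome = "MATCHED_OTHER", template = i,
                  corr_ref = corr_ref, bank = bank))
    }
  }
  created <- NA_integer_
  if (length(tpls) < 8L) {
    bank$templates[[length(tpls) + 1L]] <-
      new_template(beat, is_reference = FALSE, beat_index = beat_index)
    created <- length(tpls) + 1L
  }
  list(outcome = "NONE", template = created, corr_ref = corr_ref, bank = bank)
}

# ---------------------------------------------------------------------------
# Bank serialization (versioned JSON) for resumable streaming

#' Serialize a template bank to JSON
#' @param bank a `template_bank`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
bank_to_json <- function(bank, path = NULL) {
  stopifnot(inherits(bank, "template_bank"))
  doc <- list(format = "hbclass/template_bank", version = 1L,
              act = bank$act, oct_history = bank$oct_history,
              segment_index = bank$segment_index, templates = bank$templates)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a template bank from JSON
#' @param json a JSON string or file path produced by [bank_to_json()].
#' @return A `template_bank`.
#' @export
bank_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "hbclass/template_bank"))
    stop("not a template bank document")
  tpls <- lapply(doc$templates, function(t) {
    t$vel_avg <- as.numeric(t$vel_avg)
    t$mag_avg <- as.numeric(t$mag_avg)
    t$members <- as.integer(t$members)
    t$last_hit <- as.integer(t$last_hit)
    t
  })
  structure(list(templates = tpls, act = doc$act,
                 oct_history = as.numeric(doc$oct_history),
                 segment_index = as.integer(doc$segment_index)),
            class = "template_bank")
}
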
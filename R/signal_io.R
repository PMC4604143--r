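## Two-lead ECG records: construction, WFDB-style I/O, resampling to 250 Hz,
## 0.05-75 Hz band-pass, composite magnitude/velocity leads, AAMI label
## mapping and detection/annotation pairing.
##
## Conventions: all sample indices are 0-based; windows are half-open
## [start, end). The processing sampling rate is 250 Hz.

#' Construct a two-lead ECG record
#'
#' @param lead1,lead2 numeric sample series (mV); must have equal length.
#' @param fs sampling rate in Hz.
#' @param annotations data frame with columns `sample` (0-based fiducial
#'   index), `source_label` (database beat symbol) and, optionally, the
#'   derived columns `aami` and `binary`; missing derived columns are filled
#'   by [map_annotation()].
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(lead1, lead2, fs, annotations = NULL) {
  lead1 <- as.numeric(lead1)
  lead2 <- as.numeric(lead2)
  if (length(lead1) != length(lead2))
    stop("lead1 and lead2 must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0), source_label = character(0),
                              stringsAsFactors = FALSE)
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("sample", "source_label") %in% names(annotations)))
    stop("annotations need columns 'sample' and 'source_label'")
  if (nrow(annotations) &&
      (min(annotations$sample) < 0 || max(annotations$sample) >= length(lead1)))
    stop("annotation fiducials must lie within [0, record length)")
  if (!all(c("aami", "binary") %in% names(annotations)) && nrow(annotations)) {
    m <- map_annotation(annotations$source_label)
    annotations$aami <- m$aami
    annotations$binary <- m$binary
  } else if (!nrow(annotations)) {
    annotations$aami <- character(0)
    annotations$binary <- character(0)
  }
  structure(list(lead1 = lead1, lead2 = lead2, fs = fs,
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x 2 leads @ %g Hz (%.1f s), %d annotated beats\n",
              length(x$lead1), x$fs, length(x$lead1) / x$fs, nrow(x$annotations)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$aami)
    cat("  beats:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# WFDB-style record I/O (text .hea header + 16-bit .dat, two signals) and the
# plain-text TSV annotation dialect (<record>.ann.tsv: sample_index <tab>
# source_label).

#' Write a record in WFDB format (format-16 signals) plus TSV annotations
#'
#' @param record an [ecg_record()].
#' @param path record path without extension; `<path>.hea`, `<path>.dat` and
#'   `<path>.ann.tsv` are written.
#' @param gain ADC units per mV (default 200).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  name <- basename(path)
  n <- length(record$lead1)
  adc <- function(x) {
    v <- as.integer(round(x * gain))
    pmin(pmax(v, -32768L), 32767L)
  }
  s1 <- adc(record$lead1); s2 <- adc(record$lead2)
  hdr <- c(
    sprintf("%s 2 %g %d", name, record$fs, n),
    sprintf("%s.dat 16 %d/mV 16 0 %d 0 0 lead1", name, gain, s1[1]),
    sprintf("%s.dat 16 %d/mV 16 0 %d 0 0 lead2", name, gain, s2[1])
  )
  writeLines(hdr, paste0(path, ".hea"))
  inter <- integer(2L * n)
  inter[seq(1L, 2L * n, by = 2L)] <- s1
  inter[seq(2L, 2L * n, by = 2L)] <- s2
  writeBin(inter, paste0(path, ".dat"), size = 2L, endian = "little")
  ann <- record$annotations
  write.table(data.frame(sample = ann$sample, source_label = ann$source_label),
              paste0(path, ".ann.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a WFDB record (header + format-16 signals) with TSV annotations
#'
#' Parses the text header for the signal count, sampling rate, sample count
#' and per-signal gain/baseline, then decodes the interleaved 16-bit signal
#' file. Only format 16 is supported. Annotations are read from
#' `<path>.ann.tsv` when present.
#'
#' @param path record path without extension.
#' @return An [ecg_record()] at the native sampling rate.
#' @export
load_record <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing header file: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed WFDB header: ", hea)
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (is.na(nsig) || nsig < 2L)
    stop("record must have at least 2 signals (found ", nsig, ")")
  sig <- lapply(lines[2:(1L + nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmt <- vapply(sig, function(s) sub("x.*$", "", s[2]), "")
  if (!all(fmt == "16")) stop("unsupported WFDB signal format: ", fmt[fmt != "16"][1])
  gain <- vapply(sig, function(s) {
    g <- as.numeric(sub("[(/].*$", "", s[3]))
    if (is.na(g) || g == 0) 200 else g
  }, 0)
  baseline <- vapply(sig, function(s) {
    b <- regmatches(s[3], regexpr("\\(([-0-9]+)\\)", s[3]))
    if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
  }, 0)
  dat <- paste0(path, ".dat")
  if (!file.exists(dat)) stop("missing signal file: ", dat)
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp) stop("signal file shorter than header declares")
  lead1 <- (raw[seq(1L, nsig * nsamp, by = nsig)] - baseline[1]) / gain[1]
  lead2 <- (raw[seq(2L, nsig * nsamp, by = nsig)] - baseline[2]) / gain[2]
  annp <- paste0(path, ".ann.tsv")
  ann <- NULL
  if (file.exists(annp)) {
    ann <- read.delim(annp, stringsAsFactors = FALSE,
                      colClasses = c("integer", "character"))
  }
  ecg_record(lead1, lead2, fs, ann)
}

# ---------------------------------------------------------------------------

# round half away from zero (used for fiducial rescaling)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Linearly resample a record to a target sampling rate
#'
#' Piecewise-linear interpolation of each lead onto a grid of
#' `round(n * target_fs / fs)` samples; annotation fiducials are rescaled by
#' `target_fs / fs` and rounded half away from zero. A record already at the
#' target rate is returned unchanged.
#'
#' @param record an [ecg_record()].
#' @param target_fs target sampling rate in Hz (default 250).
#' @return An [ecg_record()] at `target_fs`.
#' @export
resample_linear <- function(record, target_fs = 250) {
  stopifnot(inherits(record, "ecg_record"), record$fs > 0)
  if (record$fs == target_fs) return(record)
  n_in <- length(record$lead1)
  n_out <- round(n_in * target_fs / record$fs)
  t_in <- (seq_len(n_in) - 1L) / record$fs
  t_out <- (seq_len(n_out) - 1L) / target_fs
  interp <- function(y) approx(t_in, y, xout = t_out, rule = 2)$y
  ann <- record$annotations
  if (nrow(ann)) {
    ann$sample <- as.integer(round_half_away(ann$sample * target_fs / record$fs))
    ann$sample <- pmin(ann$sample, n_out - 1L)
  }
  ecg_record(interp(record$lead1), interp(record$lead2), target_fs, ann)
}

#' Zero-phase band-pass filter (0.05-75 Hz by default)
#'
#' A 2nd-order Butterworth high-pass at `low` cascaded with a 4th-order
#' Butterworth low-pass at `high`, each applied forward-backward
#' (zero phase) per lead. Length is preserved.
#'
#' @param record an [ecg_record()] at 250 Hz.
#' @param low,high band edges in Hz; require `0 < low < high < fs/2`.
#' @return The filtered [ecg_record()].
#' @export
bandpass <- function(record, low = 0.05, high = 75) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2")
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  filt <- function(x) {
    y <- signal::filtfilt(hp, x)
    signal::filtfilt(lp, y)
  }
  ecg_record(filt(record$lead1), filt(record$lead2), fs, record$annotations)
}

#' Composite magnitude and velocity leads
#'
#' `mag[i] = sqrt(lead1[i]^2 + lead2[i]^2)`;
#' `vel[i] = sqrt(d1[i]^2 + d2[i]^2)` where `d` is the first-order difference
#' of adjacent samples, with `vel[1] = 0` by convention.
#'
#' @param record an [ecg_record()].
#' @return A list with components `mag` and `vel` (equal length, nonnegative).
#' @export
composite_leads <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  l1 <- record$lead1; l2 <- record$lead2
  mag <- sqrt(l1^2 + l2^2)
  vel <- c(0, sqrt(diff(l1)^2 + diff(l2)^2))
  list(mag = mag, vel = vel)
}

# ---------------------------------------------------------------------------

# MIT-style beat symbols -> AAMI EC57 classes.
#  N: sinus node beats incl. left/right bundle branch block
#  S: supraventricular ectopic (atrial/nodal premature or escape, aberrated)
#  V: ventricular ectopic (premature, R-on-T, escape)
#  F: fusion of ventricular and normal
#  Q: unclassified (unknown, paced, fusion of paced and normal)
.aami_map <- c(
  "N" = "N", "L" = "N", "R" = "N", "B" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S", "e" = "S", "j" = "S", "n" = "S",
  "V" = "V", "E" = "V", "r" = "V",
  "F" = "F",
  "Q" = "Q", "/" = "Q", "f" = "Q", "?" = "Q"
)

#' Map database beat symbols to AAMI EC57 classes and the SVB/VB partition
#'
#' The five AAMI groups are N (sinus incl. bundle branch block),
#' S (supraventricular ectopic), V (ventricular ectopic), F (fusion of
#' ventricular and normal) and Q (unknown/paced). The binary task groups
#' N+S as SVB, V+F as VB; Q beats are EXCLUDED from scoring.
#'
#' @param source_label character vector of database beat symbols.
#' @return A data frame with columns `source_label`, `aami`, `binary`.
#' @export
map_annotation <- function(source_label) {
  source_label <- as.character(source_label)
  aami <- unname(.aami_map[source_label])
  unknown <- is.na(aami)
  if (any(unknown)) {
    warning("unknown beat label(s) mapped to Q: ",
            paste(unique(source_label[unknown]), collapse = " "))
    aami[unknown] <- "Q"
  }
  binary <- ifelse(aami %in% c("N", "S"), "SVB",
                   ifelse(aami %in% c("V", "F"), "VB", "EXCLUDED"))
  data.frame(source_label = source_label, aami = aami, binary = binary,
             stringsAsFactors = FALSE)
}

#' Pair detections with annotations within a time window
#'
#' Greedy one-to-one nearest matching: candidate (detection, annotation)
#' pairs within `window_ms` are accepted in order of increasing time
#' difference, each detection and each annotation used at most once.
#'
#' @param detections sorted 0-based sample indices of detected beats.
#' @param ann_samples sorted 0-based fiducial indices of annotated beats.
#' @param fs sampling rate in Hz.
#' @param window_ms pairing window (default 150 ms).
#' @return A list with `pairs` (data frame: `detection`, `annotation` sample
#'   indices and `ann_idx` row of the annotation), `unpaired_detections` and
#'   `unpaired_annotations`.
#' @export
pair_detections <- function(detections, ann_samples, fs = 250, window_ms = 150) {
  detections <- as.numeric(detections)
  ann_samples <- as.numeric(ann_samples)
  win <- window_ms * fs / 1000
  cand <- NULL
  if (length(detections) && length(ann_samples)) {
    cand <- expand.grid(d = seq_along(detections), a = seq_along(ann_samples))
    cand$dt <- abs(detections[cand$d] - ann_samples[cand$a])
    cand <- cand[cand$dt <= win, , drop = FALSE]
    cand <- cand[order(cand$dt, cand$d, cand$a), , drop = FALSE]
  }
  used_d <- logical(length(detections))
  used_a <- logical(length(ann_samples))
  pd <- integer(0); pa <- integer(0)
  for (i in seq_len(NROW(cand))) {
    d <- cand$d[i]; a <- cand$a[i]
    if (!used_d[d] && !used_a[a]) {
      used_d[d] <- TRUE; used_a[a] <- TRUE
      pd <- c(pd, d); pa <- c(pa, a)
    }
  }
  ord <- order(pd)
  list(
    pairs = data.frame(detection = detections[pd[ord]],
                       annotation = ann_samples[pa[ord]],
                       ann_idx = pa[ord]),
    unpaired_detections = detections[!used_d],
    unpaired_annotations = ann_samples[!used_a]
  )
}
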
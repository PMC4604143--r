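test_that("correlation matches the normalised inner-product formula", {
  w <- runif(45)
  expect_equal(correlation(w, w), 100)
  expect_equal(correlation(2 * w, w), 100) # scale invariance
  expect_equal(correlation(c(1, 0), c(1, 1)), 100 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(correlation(c(1, 0), c(1, 1)), 2), 70.71)
  expect_warning(z <- correlation(c(0, 0), c(1, 1)), "zero-energy")
  expect_equal(z, 0)
  expect_error(correlation(c(1, 1), c(0, 0)), "template")
})

test_that("ACT update has the documented fixed point and bounds", {
  expect_equal(update_act(90, 90), 90)
  expect_equal(update_act(98, 80), 93.5)
  expect_equal(update_act(80, 98), 84.5)
  # geometric convergence to a constant OCT, always inside [80, 98]
  for (c0 in c(82, 90, 97)) {
    act <- 98
    for (i in 1:12) {
      act <- update_act(act, c0)
      expect_true(act >= 80 && act <= 98)
      expect_equal(abs(act - c0), 0.75^i * abs(98 - c0), tolerance = 1e-9)
    }
  }
})

test_that("OCT scan equals the brute-force threshold oracle", {
  identical_beats <- replicate(6, c(1, 2, 3, 2, 1), simplify = FALSE)
  expect_equal(find_oct(identical_beats), 98)

  orth <- lapply(1:5, function(i) { v <- numeric(45); v[i * 5] <- 1; v })
  expect_equal(find_oct(orth), 80)

  expect_equal(find_oct(list(), prev_oct = 91), 91)
  expect_equal(find_oct(list(c(1, 2))), 90) # < 2 beats, default fallback

  # graded-similarity segments: shifted bumps give a spread of pairwise
  # correlations; the fast path must equal the literal 37-step scan
  for (spread in c(1, 2, 3, 5)) {
    wins <- lapply(1:8, function(k)
      exp(-((1:45) - (10 + k * spread))^2 / (2 * 16)))
    expect_equal(find_oct(wins), oracle_find_oct(wins), info = spread)
  }
})

test_that("reference learning picks the largest / shortest-QRS subgroup", {
  narrow <- make_beat(shape_narrow(), qrs_dur = 80)
  wide <- make_beat(shape_wide(), qrs_dur = 160)

  bank <- learn_reference(c(replicate(8, narrow, simplify = FALSE),
                            replicate(2, wide, simplify = FALSE)))
  ref <- bank$templates[[1]]
  expect_true(ref$is_reference)
  expect_equal(ref$members, 8L)
  expect_equal(ref$vel_avg, narrow$vel_win)

  # single morphology: one subgroup, reference = its average
  bank1 <- learn_reference(replicate(10, narrow, simplify = FALSE))
  expect_length(bank1$templates, 1)
  expect_equal(bank1$templates[[1]]$vel_avg, narrow$vel_win)

  # equal-sized subgroups: the shorter-QRS one wins on the duration term
  bank2 <- learn_reference(c(replicate(5, narrow, simplify = FALSE),
                             replicate(5, wide, simplify = FALSE)))
  expect_equal(bank2$templates[[1]]$qrs_dur, 80)
  expect_error(learn_reference(list()), "no beats")
})

test_that("template matching fast-tracks, creates and caps templates", {
  narrow <- make_beat(shape_narrow())
  bank <- learn_reference(replicate(8, narrow, simplify = FALSE))

  hit <- match_and_update(narrow, bank, 1L)
  expect_equal(hit$outcome, "MATCHED_REFERENCE")
  expect_equal(hit$corr_ref, 100)

  # orthogonal beat: no match, new template created while under the cap
  wide <- make_beat(shape_wide())
  bank3 <- hit$bank
  for (i in 1:2) bank3 <- match_and_update(make_beat({
    v <- numeric(30); v[10 + i] <- 1; v
  }), bank3, i)$bank
  expect_length(bank3$templates, 3)
  miss <- match_and_update(wide, bank3, 5L)
  expect_equal(miss$outcome, "NONE")
  expect_length(miss$bank$templates, 4)

  # fill to 8 and verify the cap (no replacement)
  bank8 <- miss$bank
  i <- 0
  while (length(bank8$templates) < 8) {
    i <- i + 1
    v <- numeric(45); v[30 + i] <- 1
    bank8 <- match_and_update(make_beat(v), bank8, 10L + i)$bank
  }
  v <- numeric(45); v[45] <- 1
  full <- match_and_update(make_beat(v), bank8, 99L)
  expect_equal(full$outcome, "NONE")
  expect_length(full$bank$templates, 8)
  expect_true(is.na(full$template))

  # second template is matched (and updated) when the reference is not
  other <- match_and_update(wide, miss$bank, 6L)
  expect_equal(other$outcome, "MATCHED_OTHER")
})

test_that("template running average has the matched-beat fixed point", {
  narrow <- make_beat(shape_narrow())
  bank <- learn_reference(replicate(4, narrow, simplify = FALSE))
  for (k in 1:10) bank <- match_and_update(narrow, bank, k)$bank
  expect_equal(bank$templates[[1]]$vel_avg, narrow$vel_win)
  expect_equal(bank$templates[[1]]$members, 14L)
})

test_that("QRS delineation brackets constructed pulses", {
  fs <- 250
  n <- 2000
  fid <- 1000L
  tri <- function(width_ms, center) {
    half <- round(width_ms / 2 * fs / 1000)
    v <- numeric(n)
    idx <- (center - half):(center + half)
    v[idx + 1] <- 1 - abs(idx - center) / half
    v
  }
  v80 <- tri(80, fid)
  d80 <- delineate_qrs(v80, v80, fid, fs)
  span80 <- (d80$qrs_off - d80$qrs_on) * 1000 / fs
  expect_true(span80 >= 70 && span80 <= 100)

  flat <- delineate_qrs(numeric(n), numeric(n), fid, fs)
  expect_equal(flat$qrs_on, fid - 1L)
  expect_equal(flat$qrs_off, fid + 1L)

  v160 <- tri(160, fid)
  d160 <- delineate_qrs(v160, v160, fid, fs)
  expect_gt(d160$qrs_off - d160$qrs_on, d80$qrs_off - d80$qrs_on)

  expect_warning(out <- delineate_qrs(v80, v80, 10L, fs), "margin")
  expect_null(out)
})

test_that("P-wave detector separates constructed positives and negatives", {
  fs <- 250
  n <- 1500
  qrs_on <- 1000L
  base <- numeric(n)
  qrs <- base
  qrs[(qrs_on + 1):(qrs_on + 20)] <- 1 # QRS bump after onset
  with_p <- qrs
  p_center <- qrs_on - 30 # 120 ms before onset
  with_p[(p_center - 5):(p_center + 5)] <- 0.2 * c(1:6, 5:1) / 6
  expect_true(detect_p_wave(with_p, qrs_on, fs))
  expect_false(detect_p_wave(qrs, qrs_on, fs))
  set.seed(5)
  noisy <- qrs
  noisy[(qrs_on - 50):(qrs_on - 10)] <- abs(rnorm(41, 0, 0.01))
  expect_false(detect_p_wave(noisy, qrs_on, fs))
  expect_true(detect_p_wave(qrs, 10L, fs)) # insufficient pre-window default
})

test_that("template banks serialize to JSON and reload bit-identically", {
  narrow <- make_beat(shape_narrow())
  wide <- make_beat(shape_wide())
  bank <- learn_reference(c(replicate(5, narrow, simplify = FALSE),
                            replicate(2, wide, simplify = FALSE)))
  bank <- match_and_update(wide, bank, 9L)$bank
  path <- file.path(tempdir(), "bank.json")
  bank_to_json(bank, path)
  back <- bank_from_json(path)
  expect_equal(back, bank)
  # matching behaviour is unchanged after a round trip
  a <- match_and_update(narrow, bank, 10L)
  b <- match_and_update(narrow, back, 10L)
  expect_equal(a$outcome, b$outcome)
  expect_equal(a$corr_ref, b$corr_ref)
})
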
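test_that("band-pass power recovers the analytic power of a sinusoid", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  a <- 2
  x <- a * sin(2 * pi * 4.5 * t)
  p <- bandpass_power(x, "theta", fs)
  centre <- (5 * fs):(25 * fs)
  expect_lt(abs(mean(p[centre]) - a^2 / 2), 0.02 * a^2 / 2)

  # stopband: a 20 Hz tone leaves almost no theta power
  x20 <- a * sin(2 * pi * 20 * t)
  p20 <- bandpass_power(x20, "theta", fs)
  expect_lt(mean(p20[centre]), 0.01 * a^2 / 2)

  expect_equal(bandpass_power(numeric(5000), "theta", fs), numeric(5000))
  expect_error(bandpass_power(x, c(8, 70), fs), "Nyquist")
  expect_length(bandpass_power(x, "lower_alpha", fs), length(x))
})

test_that("trial window medians respect the half-open windows and the mask", {
  fs <- 64
  n <- 20 * fs
  onset <- 10
  # power p before onset, 2p from onset on (step at the onset sample)
  pw <- rep(1, n)
  pw[(onset * fs + 1):n] <- 2
  tp <- trial_band_power(pw, fs, onset, rt = 3)
  expect_equal(tp$B_trial, 1)
  expect_equal(tp$A_trial, 2)
  expect_true(tp$usable)

  const <- trial_band_power(rep(5, n), fs, onset, rt = 3)
  expect_equal(const$B_trial, 5)
  expect_equal(const$A_trial, 5)

  # mask covering 60% of the baseline window makes the trial unusable
  mask <- matrix(c(onset - 1.25, onset - 0.65), 1)
  tpm <- trial_band_power(pw, fs, onset, rt = 3, mask = mask)
  expect_false(tpm$usable)
  expect_lt(tpm$frac_baseline, 0.5)

  expect_error(trial_band_power(pw, fs, onset, rt = 0), "positive")
})

test_that("ERD/ERS follows vertical-averaging-then-ratio order", {
  expect_equal(condition_erders(data.frame(B_trial = 3, A_trial = 3)), 0)
  expect_equal(condition_erders(data.frame(B_trial = 10, A_trial = 5)), -50)
  expect_equal(condition_erders(
    data.frame(B_trial = c(1, 2, 9), A_trial = c(2, 4, 18))), 100)

  # discriminating fixture: medians-then-ratio gives +150; the wrong
  # order (ratio per trial, then median) would give +100
  tp <- data.frame(B_trial = c(1, 2, 10), A_trial = c(5, 4, 11))
  expect_equal(condition_erders(tp), 150)
  wrong <- median((tp$A_trial - tp$B_trial) / tp$B_trial * 100)
  expect_false(isTRUE(all.equal(condition_erders(tp), wrong)))

  expect_warning(v <- condition_erders(data.frame(B_trial = numeric(0),
                                                  A_trial = numeric(0))),
                 "empty")
  expect_true(is.na(v))
  expect_warning(condition_erders(data.frame(B_trial = 0, A_trial = 1)),
                 "baseline")
})

test_that("closed-form oracle: amplitude-modulated sinusoid yields the exact ratio", {
  # noiseless oscillation with baseline amplitude a_B and activity a_A:
  # ERD/ERS must approach (a_A^2 - a_B^2) / a_B^2 * 100
  fs <- 64
  dur <- 40
  t <- seq(1 / fs, dur, by = 1 / fs)
  onset <- 20; rt <- 5
  for (tgt in c(-50, 20, 80)) {
    aB <- 10; aA <- aB * sqrt(1 + tgt / 100)
    env <- rep(aB, length(t))
    env[t > onset & t <= onset + rt] <- aA
    x <- env * sin(2 * pi * 4.5 * t)
    p <- bandpass_power(x, "theta", fs)
    tp <- trial_band_power(p, fs, onset, rt)
    v <- condition_erders(tp)
    expect_lt(abs(v - tgt), 2)
  }
})

test_that("ROI aggregation averages good channels and guards the map", {
  rm2 <- data.frame(channel = c("Fp1", "AF3", "F7"),
                    roi = "F", hemisphere = "left")
  cv <- data.frame(channel = c("Fp1", "AF3", "F7"), value = c(10, 20, 60))
  expect_equal(roi_aggregate(cv, rm2)$value, 30)
  expect_equal(roi_aggregate(cv, rm2, bad_channels = "F7")$value, 15)
  expect_equal(roi_aggregate(cv, rm2, bad_channels = "F7")$n_channels, 2)

  expect_warning(out <- roi_aggregate(cv, rm2,
                                      bad_channels = c("Fp1", "AF3", "F7")),
                 "no good channels")
  expect_true(is.na(out$value))

  dup_map <- rbind(rm2, data.frame(channel = "Fp1", roi = "FTC",
                                   hemisphere = "left"))
  expect_error(roi_aggregate(cv, dup_map), "more than one ROI")
  mid_map <- rbind(rm2, data.frame(channel = "Cz", roi = "F",
                                   hemisphere = "left"))
  expect_error(roi_aggregate(cv, mid_map), "midline")
})

test_that("the default ROI map covers all non-midline channels once", {
  rm <- roi_map_default()
  expect_equal(sort(rm$channel),
               sort(setdiff(montage32(), c("Fz", "Cz", "Pz", "Oz"))))
  expect_equal(nrow(unique(rm[c("roi", "hemisphere")])), 8)
  expect_equal(anyDuplicated(rm$channel), 0)
})

test_that("ERD/ERS is invariant under rescaling of the recording", {
  one <- tiny_participant(seed = 3, blink_rate = 0)
  rec <- one$recording
  ev <- one$events
  ev$strategy <- ifelse(ev$size == "small", "retrieve", "procedure")
  ev$retained <- ev$report == ev$strategy
  base <- participant_erders(rec, ev)
  rec2 <- rec
  rec2$samples <- rec$samples * 3.7
  scaled <- participant_erders(rec2, ev)
  expect_equal(scaled$value, base$value, tolerance = 1e-10)
  # and always above -100 wherever defined
  expect_true(all(base$value > -100, na.rm = TRUE))
})
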
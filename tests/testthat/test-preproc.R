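# Fixtures are built from named montage channels so the frontal-channel
# logic of the ocular stage is exercised realistically.

make_noise_recording <- function(n_chan = 12, dur = 100, fs = 128,
                                 seed = 2) {
  set.seed(seed)
  chans <- montage32()[seq_len(n_chan)]
  samples <- matrix(rnorm(n_chan * dur * fs, sd = 10), n_chan)
  list(samples = samples, channels = chans, fs = fs, bad = character(0),
       mask = matrix(numeric(0), ncol = 2))
}

test_that("flat and noisy channels are detected, clean data passes", {
  rec <- make_noise_recording()
  expect_length(detect_bad_channels(rec)$bad, 0)

  rec$samples[3, ] <- 0
  rec$samples[7, ] <- rec$samples[7, ] * 30   # ~900x the median variance
  bc <- detect_bad_channels(rec)
  expect_setequal(bc$bad, rec$channels[c(3, 7)])
  expect_equal(unname(bc$reasons[rec$channels[3]]), "flat")
  expect_equal(unname(bc$reasons[rec$channels[7]]), "noisy")

  flatrec <- rec
  flatrec$samples[] <- 0
  expect_error(detect_bad_channels(flatrec), "unusable")
})

test_that("common average referencing zeroes the good-channel mean", {
  rec <- make_noise_recording()
  rr <- rereference_common_average(rec, bad = rec$channels[1])
  gi <- 2:12
  expect_lt(max(abs(colMeans(rr$samples[gi, ]))), 1e-10)
  # bad channel left untouched and excluded from the average
  expect_identical(rr$samples[1, ], rec$samples[1, ])

  two <- list(samples = rbind(rnorm(100), -rbind(rnorm(100))[1, ]),
              channels = c("C3", "C4"), fs = 10, bad = character(0))
  two$samples[2, ] <- -two$samples[1, ]
  rr2 <- rereference_common_average(two, character(0))
  expect_equal(rr2$samples, two$samples)

  # a huge artifact on a bad channel cannot leak into good channels
  rec2 <- rec
  rec2$samples[1, ] <- rec2$samples[1, ] + 1e4
  rr3 <- rereference_common_average(rec2, bad = rec$channels[1])
  expect_equal(rr3$samples[gi, ], rr$samples[gi, ])

  expect_error(rereference_common_average(rec, bad = rec$channels[1:11]),
               "fewer than 2")
})

test_that("artifact segments are masked around large excursions", {
  rec <- make_noise_recording(dur = 120)
  rr <- rereference_common_average(rec, character(0))
  expect_equal(nrow(mark_artifact_segments(rr)), 0)

  burst <- rr
  i0 <- 60 * rr$fs
  burst$samples[5, i0:(i0 + 0.5 * rr$fs)] <- 500
  m <- mark_artifact_segments(burst)
  expect_equal(nrow(m), 1)
  expect_lte(m[1, 1], 60)
  expect_gte(m[1, 2], 60.5)
  expect_lte(m[1, 2] - m[1, 1], 0.5 + 2 * 0.25 + 0.2)

  # merged intervals never overlap
  iv <- matrix(c(1, 2, 1.5, 3, 5, 6), ncol = 2, byrow = TRUE)
  mg <- oscarith:::merge_intervals(iv)
  expect_true(all(mg[-1, 1] >= mg[-nrow(mg), 2]))
})

test_that("ICA removes frontal blink components and preserves posterior signal", {
  one <- tiny_participant(seed = 21, n_per_cell = 2, n_ocular_sources = 2,
                          keep_ground_truth = TRUE)
  rec <- one$recording
  gt <- rec$ground_truth
  pre <- preprocess_recording(rec)
  expect_gte(length(pre$report$removed), 1)
  expect_lte(length(pre$report$removed), 3)

  gi <- match(setdiff(rec$channels, pre$report$bad), rec$channels)
  gtr <- gt
  gtr[gi, ] <- sweep(gt[gi, ], 2, colMeans(gt[gi, ]))
  raw <- rereference_common_average(rec, pre$report$bad)

  bw <- signal::butter(4, c(0.5, 4) / (rec$fs / 2), type = "pass")
  fi <- match("Fp1", rec$channels)
  before <- sqrt(mean(signal::filtfilt(bw, raw$samples[fi, ] -
                                       gtr[fi, ])^2))
  after <- sqrt(mean(signal::filtfilt(bw, pre$recording$samples[fi, ] -
                                      gtr[fi, ])^2))
  expect_lt(after / before, 0.25)   # strong frontal blink suppression

  oi <- match("O1", rec$channels)
  expect_gt(cor(pre$recording$samples[oi, ], gtr[oi, ]), 0.95)

  # structure is never altered by cleaning
  expect_identical(dim(pre$recording$samples), dim(rec$samples))
  expect_identical(pre$recording$channels, rec$channels)
  expect_identical(pre$recording$fs, rec$fs)
})

test_that("without blinks no component is flagged and cleaning is idempotent", {
  one <- tiny_participant(seed = 22, n_per_cell = 2, blink_rate = 0)
  rec <- rereference_common_average(one$recording, character(0))
  expect_warning(res <- remove_ocular_ica(rec), "no ocular component")
  expect_identical(res$recording$samples, rec$samples)
})

test_that("ICA preconditions are enforced", {
  rec <- make_noise_recording(dur = 30)
  rr <- rereference_common_average(rec, character(0))
  expect_error(remove_ocular_ica(rr), "60 s")
})
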
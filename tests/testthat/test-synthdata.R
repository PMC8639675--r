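test_that("behavior draws follow the configured condition parameters", {
  cfg <- simulation_config()
  set.seed(11)
  draws <- replicate(10000, generate_behavior("retrieve", "subtraction",
                                              cfg)$rt)
  expect_lt(abs(mean(draws) - 2.07), 0.02 * 2.07)

  cfg0 <- simulation_config(misreport_rate = 0, unknown_rate = 0,
                            acc_probs = within(simulation_config()$acc_probs,
                                               prob <- 1))
  set.seed(12)
  b <- replicate(200, unlist(
    generate_behavior("procedure", "multiplication", cfg0)[c("correct",
                                                             "report")]),
    simplify = FALSE)
  expect_true(all(vapply(b, function(x) x[["correct"]] == "TRUE", TRUE)))
  expect_true(all(vapply(b, function(x) x[["report"]] == "procedure", TRUE)))

  expect_error(generate_behavior("retrieve", "division", cfg),
               "not configured")
})

test_that("inverse-Gaussian variates match the target moments", {
  set.seed(4)
  x <- rinvgauss(50000, mu = 2, lambda = 6)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 2), 0.02)
  expect_lt(abs(var(x) - 2^3 / 6) / (2^3 / 6), 0.1)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- tiny_participant(seed = 9)
  b <- tiny_participant(seed = 9)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  c <- tiny_participant(seed = 10)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("null configuration injects no amplitude modulation", {
  nullfx <- simulation_config()$band_effects
  nullfx$target <- 0
  one <- tiny_participant(seed = 5, band_effects = nullfx, blink_rate = 0,
                          noise_sd = 0)
  rec <- one$recording
  ev <- one$events
  fs <- rec$fs
  ch <- match("O1", rec$channels)
  # oscillation amplitude in the activity window equals the baseline
  # amplitude in every trial when all targets are zero
  ratios <- vapply(seq_len(nrow(ev)), function(i) {
    bs <- ((ev$onset[i] - 1.25) * fs):((ev$onset[i] - 0.25) * fs)
    ac <- (ev$onset[i] * fs):((ev$onset[i] + ev$rt[i]) * fs)
    sqrt(mean(rec$samples[ch, ac]^2) / mean(rec$samples[ch, bs]^2))
  }, numeric(1))
  # non-integer cycle counts in short windows wobble the RMS by a few
  # percent even for a constant envelope
  expect_true(all(abs(ratios - 1) < 0.08))
  expect_lt(abs(mean(ratios) - 1), 0.03)

  # and with a configured positive target the ratio moves accordingly
  fx <- simulation_config()$band_effects
  fx$target <- c(50, 50, 0, 0, 0, 0)
  two <- tiny_participant(seed = 5, band_effects = fx, blink_rate = 0,
                          noise_sd = 0)
  ratios2 <- vapply(which(two$events$size == "small"), function(i) {
    ev2 <- two$events
    bs <- ((ev2$onset[i] - 1.25) * fs):((ev2$onset[i] - 0.25) * fs)
    ac <- (ev2$onset[i] * fs):((ev2$onset[i] + ev2$rt[i]) * fs)
    sqrt(mean(two$recording$samples[ch, ac]^2) /
         mean(two$recording$samples[ch, bs]^2))
  }, numeric(1))
  expect_gt(mean(ratios2), 1.05)
  expect_gt(mean(ratios2), mean(ratios) + 0.04)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(misreport_rate = 0.9, unknown_rate = 0.3))
  bad_fx <- simulation_config()$band_effects
  bad_fx$target[1] <- -120
  expect_error(simulation_config(band_effects = bad_fx), "-100")
  expect_error(simulation_config(fs = 20), "twice")
  expect_error(simulation_config(nonsense = 1), "unknown config")
  expect_error(simulate_participant(simulation_config(), NULL, 1), "empty")
})

test_that("trial timing respects the paradigm structure", {
  one <- tiny_participant(seed = 6, n_per_cell = 2)
  ev <- one$events
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$rt > 0))
  # at least fixation + previous rt + blank between consecutive onsets
  gaps <- diff(ev$onset)
  lower <- 1.5 + ev$rt[-nrow(ev)] + 1.5
  expect_true(all(gaps >= lower - 1e-9))
  # recording long enough to hold the last activity window
  dur <- ncol(one$recording$samples) / one$recording$fs
  expect_gt(dur, ev$onset[nrow(ev)] + ev$rt[nrow(ev)])
})
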
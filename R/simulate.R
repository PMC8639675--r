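# Synthetic multi-participant EEG + behavior generator. The generator
# produces continuous recordings with the statistical structure the
# downstream analysis assumes: 1/f background activity, band-limited
# oscillations whose amplitude is modulated between baseline and activity
# windows by configured ERD/ERS targets, stereotyped frontal blink
# transients, inverse-Gaussian response times, binomial correctness, and
# imperfect verbal strategy reports.

#' Simulation configuration
#'
#' Returns the default configuration of the synthetic dataset, emulating
#' the study conditions: 31 participants, 512 Hz, a 32-channel extended
#' 10-20 montage, condition ERD/ERS targets, response-time and accuracy
#' parameters per strategy x operation cell, and report-noise rates taken
#' from the observed size-by-report contingency structure.
#'
#' Fields (override any via `...`):
#' \describe{
#'   \item{n_participants}{number of simulated children (31).}
#'   \item{fs}{sampling rate in Hz (512).}
#'   \item{channels}{montage labels, see [montage32()].}
#'   \item{band_effects}{data.frame `band`, `strategy`, optional
#'     `operation`/`roi`/`hemisphere` (NA = any), `target` (% ERD/ERS).
#'     Defaults are the study's condition means per band: theta +22.0
#'     (retrieval) / +11.1 (procedure); lower alpha +3.48 / -1.83; upper
#'     alpha -8.84 / -11.48.}
#'   \item{carriers}{oscillation carrier frequencies per band
#'     (4.5, 9, 11.5 Hz), at the band centers so the injected energy stays
#'     inside the analysis passbands.}
#'   \item{osc_amplitude}{baseline oscillation amplitude, microvolts (20).}
#'   \item{noise_sd, noise_exponent}{1/f background: standard deviation in
#'     microvolts (6) and spectral slope (1).}
#'   \item{rt_params}{per-cell inverse-Gaussian means in seconds
#'     (retrieve-sub 2.07, retrieve-mul 2.18, procedure-sub 6.44,
#'     procedure-mul 10.05); shape = `rt_shape_factor` x mean.}
#'   \item{acc_probs}{per-cell correctness probabilities
#'     (0.980, 0.978, 0.910, 0.915).}
#'   \item{misreport_rate, unknown_rate}{probability that a report
#'     contradicts the problem size (0.118) or is "unknown" (0.013).}
#'   \item{blink_rate}{blinks per minute (15, mid-range of spontaneous
#'     blink rates reported for children).}
#'   \item{blink_amplitude}{peak blink amplitude at Fp1/Fp2, microvolts
#'     (300, a typical frontal blink deflection).}
#'   \item{n_ocular_sources}{number of independent ocular generators;
#'     NULL draws 1-3 per participant.}
#'   \item{fixation, blank, lead_in}{trial timing in seconds (1.5, 1.5, 5).}
#'   \item{report_duration}{range of the strategy-report phase, seconds
#'     (c(1.5, 2.5)).}
#'   \item{keep_ground_truth}{if TRUE, each recording carries its
#'     blink-free signal for cleaning-quality checks (memory heavy; only
#'     for small runs).}
#'   \item{seed}{base RNG seed.}
#' }
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_participants = 31L,
    fs = 512,
    channels = montage32(),
    band_effects = data.frame(
      band = rep(c("theta", "lower_alpha", "upper_alpha"), each = 2),
      strategy = rep(c("retrieve", "procedure"), 3),
      target = c(22.0, 11.1, 3.48, -1.83, -8.84, -11.48),
      stringsAsFactors = FALSE),
    carriers = c(theta = 4.5, lower_alpha = 9, upper_alpha = 11.5),
    osc_amplitude = 20,
    noise_sd = 6,
    noise_exponent = 1,
    rt_params = data.frame(
      strategy = c("retrieve", "retrieve", "procedure", "procedure"),
      operation = c("subtraction", "multiplication",
                    "subtraction", "multiplication"),
      mean = c(2.07, 2.18, 6.44, 10.05),
      stringsAsFactors = FALSE),
    rt_shape_factor = 3,
    acc_probs = data.frame(
      strategy = c("retrieve", "retrieve", "procedure", "procedure"),
      operation = c("subtraction", "multiplication",
                    "subtraction", "multiplication"),
      prob = c(0.980, 0.978, 0.910, 0.915),
      stringsAsFactors = FALSE),
    misreport_rate = 0.118,
    unknown_rate = 0.013,
    blink_rate = 15,
    blink_amplitude = 300,
    n_ocular_sources = NULL,
    fixation = 1.5,
    blank = 1.5,
    lead_in = 5,
    report_duration = c(1.5, 2.5),
    rt_floor = 0.5,
    keep_ground_truth = FALSE,
    seed = 20211202L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            all(cfg$rt_params$mean > 0),
            all(cfg$acc_probs$prob >= 0 & cfg$acc_probs$prob <= 1),
            cfg$misreport_rate >= 0, cfg$unknown_rate >= 0,
            cfg$misreport_rate + cfg$unknown_rate <= 1,
            cfg$blink_rate >= 0)
  bd <- band_definitions()
  if (cfg$fs <= 2 * max(bd$high))
    stop("sampling rate must exceed twice the highest band edge")
  if (any(cfg$band_effects$target <= -100))
    stop("ERD/ERS target <= -100% implies negative power")
  invisible(cfg)
}

# Look up the configured ERD/ERS target for one trial/channel context.
# Optional columns operation/roi/hemisphere act as wildcards when absent
# or NA; the first (most specific = earliest) matching row wins.
effect_target <- function(effects, band, strategy, operation, roi, hemisphere) {
  m <- effects$band == band & effects$strategy == strategy
  for (col in c("operation", "roi", "hemisphere")) {
    if (col %in% names(effects)) {
      v <- effects[[col]]
      m <- m & (is.na(v) | v == get(col))
    }
  }
  if (!any(m)) return(0)
  effects$target[which(m)[1]]
}

#' Draw behavior for one trial
#'
#' Given the design condition of a trial (the size-consistent strategy and
#' the operation), draws a response time from the condition's
#' inverse-Gaussian distribution, correctness from the condition's
#' Bernoulli probability, and a verbal strategy report that matches the
#' size-consistent strategy with probability
#' `1 - misreport_rate - unknown_rate`. Uses the current RNG state.
#'
#' @param strategy `"retrieve"` or `"procedure"` (the size-based design
#'   condition).
#' @param operation `"subtraction"` or `"multiplication"`.
#' @param config A [simulation_config()].
#' @return list with `rt` (seconds), `correct` (logical), `report`.
#' @export
generate_behavior <- function(strategy, operation, config = simulation_config()) {
  rp <- config$rt_params
  mu <- rp$mean[rp$strategy == strategy & rp$operation == operation]
  ap <- config$acc_probs
  pr <- ap$prob[ap$strategy == strategy & ap$operation == operation]
  if (!length(mu) || !length(pr))
    stop("condition not configured: ", strategy, " x ", operation)
  rt <- max(config$rt_floor, rinvgauss(1, mu, config$rt_shape_factor * mu))
  correct <- stats::runif(1) < pr
  u <- stats::runif(1)
  other <- if (strategy == "retrieve") "procedure" else "retrieve"
  report <- if (u < config$unknown_rate) "unknown"
            else if (u < config$unknown_rate + config$misreport_rate) other
            else strategy
  list(rt = rt, correct = correct, report = report)
}

# Stereotyped ~300 ms biphasic blink waveform (unit peak amplitude).
blink_waveform <- function(fs) {
  t <- seq(0, 0.3, by = 1 / fs)
  w <- exp(-((t - 0.10) / 0.045)^2) - 0.4 * exp(-((t - 0.21) / 0.07)^2)
  w / max(abs(w))
}

# Frontal-dominant spatial pattern of an ocular source over the montage.
blink_topography <- function(channels) {
  base <- c(Fp1 = 1, Fp2 = 1, AF3 = 0.75, AF4 = 0.75,
            F7 = 0.45, F8 = 0.45, F3 = 0.4, F4 = 0.4, Fz = 0.45,
            FC5 = 0.15, FC6 = 0.15, FC1 = 0.12, FC2 = 0.12)
  w <- base[channels]
  w[is.na(w)] <- 0.04
  unname(w)
}

#' Simulate a multi-participant dataset
#'
#' Builds, for every participant, one continuous recording (trials
#' concatenated with the paradigm timing: 1.5 s fixation, problem until
#' response, strategy-report phase, 1.5 s blank) and the matching trial
#' event table. Each analysis band contributes a carrier oscillation whose
#' amplitude is `a_B` outside and `a_A = a_B * sqrt(1 + target/100)`
#' inside the activity window `[onset, onset + rt)`, so the injected
#' ERD/ERS equals the configured target exactly in the noiseless limit.
#' Oscillations are added on all ROI channels (coherently, emulating
#' widespread cortical activity); 1/f noise is independent per channel;
#' one to three ocular sources project blink transients dominantly onto
#' frontal channels. Fully deterministic given `config$seed`.
#'
#' The problem presentation order is pseudo-random but identical for all
#' participants; block order alternates A-B-C-D / C-D-A-B between
#' participants.
#'
#' @param config A [simulation_config()].
#' @param problems Stimulus set, see [read_problem_set()].
#' @return list of class `sim_dataset` with `recordings` (one per
#'   participant: `samples` channels x time matrix in microvolts,
#'   `channels`, `fs`, `bad`, `mask`, optionally `ground_truth`) and
#'   `events` (combined trial table: `participant`, `block`, `operand1`,
#'   `operation`, `operand2`, `size`, `onset`, `rt`, `correct`, `report`).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             problems = read_problem_set()) {
  validate_sim_config(config)
  recordings <- vector("list", config$n_participants)
  events <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    one <- simulate_participant(config, problems, p)
    recordings[[p]] <- one$recording
    events[[p]] <- one$events
  }
  structure(list(recordings = recordings,
                 events = do.call(rbind, events),
                 config = config),
            class = "sim_dataset")
}

# Fixed presentation order within blocks, shared by all participants.
problem_order <- function(config, problems) {
  set.seed(config$seed %% 2147483647L)
  lapply(split(seq_len(nrow(problems)), problems$block),
         function(ix) ix[sample.int(length(ix))])
}

#' Simulate one participant
#'
#' Generates the continuous recording and trial events of a single
#' participant; [simulate_dataset()] loops over this. Exposed separately
#' so that large runs can generate, process, and discard one participant
#' at a time instead of holding every recording in memory.
#'
#' @param config A [simulation_config()].
#' @param problems Stimulus set.
#' @param p Participant index (drives the participant-specific seed and
#'   the block-order counterbalancing).
#' @return list with `recording` and `events` (this participant's rows).
#' @export
simulate_participant <- function(config, problems, p) {
  validate_sim_config(config)
  if (is.null(problems) || nrow(problems) == 0L) stop("empty problem set")
  if (!"size" %in% names(problems)) problems$size <- classify_size(problems)
  fs <- config$fs
  bd <- band_definitions()
  roi_map <- roi_map_default()
  within_order <- problem_order(config, problems)
  {
    set.seed((config$seed + 7919L * p) %% 2147483647L)
    blocks <- names(within_order)
    if (p %% 2 == 0 && length(blocks) == 4L)
      blocks <- blocks[c(3, 4, 1, 2)]
    order_ix <- unlist(within_order[blocks], use.names = FALSE)
    probs <- problems[order_ix, , drop = FALSE]
    n_tr <- nrow(probs)

    strategy_design <- ifelse(probs$size == "small", "retrieve", "procedure")
    beh <- lapply(seq_len(n_tr), function(i)
      generate_behavior(strategy_design[i], probs$operation[i], config))
    rt <- vapply(beh, `[[`, numeric(1), "rt")
    report_dur <- stats::runif(n_tr, config$report_duration[1],
                               config$report_duration[2])
    onset <- config$lead_in + config$fixation +
      c(0, cumsum((config$fixation + rt + report_dur + config$blank)[-n_tr]))
    total <- onset[n_tr] + rt[n_tr] + report_dur[n_tr] + config$blank + 2
    n <- ceiling(total * fs)
    tvec <- seq_len(n) / fs

    # 1/f background, independent per channel
    samples <- t(vapply(seq_along(config$channels), function(ch)
      pink_noise(n, fs, config$noise_exponent, config$noise_sd),
      numeric(n)))

    # band-limited oscillations with condition-dependent activity amplitude;
    # each channel gets its own phase offset (rhythms are not perfectly
    # coherent across the scalp), which also keeps the oscillation nearly
    # invariant under common average referencing
    roi_chan_idx <- match(roi_map$channel, config$channels)
    for (b in seq_len(nrow(bd))) {
      band <- bd$band[b]
      carrier_s <- sin(2 * pi * config$carriers[[band]] * tvec)
      carrier_c <- cos(2 * pi * config$carriers[[band]] * tvec)
      phases <- stats::runif(length(roi_chan_idx), 0, 2 * pi)
      ramp_n <- round(0.1 * fs)
      ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      # group ROI channels by their target signature across conditions
      targ <- vapply(seq_len(nrow(roi_map)), function(j) {
        paste(vapply(seq_len(n_tr), function(i)
          effect_target(config$band_effects, band, strategy_design[i],
                        probs$operation[i], roi_map$roi[j],
                        roi_map$hemisphere[j]), numeric(1)), collapse = ",")
      }, character(1))
      for (sig in unique(targ)) {
        tgt <- as.numeric(strsplit(sig, ",")[[1]])
        env <- rep(config$osc_amplitude, n)
        for (i in seq_len(n_tr)) {
          aA <- config$osc_amplitude * sqrt(1 + tgt[i] / 100)
          a0 <- floor(onset[i] * fs) + 1L
          a1 <- min(n, ceiling((onset[i] + rt[i]) * fs))
          env[a0:a1] <- aA
          # short raised-cosine ramps at the window edges
          r0 <- max(1L, a0 - ramp_n)
          if (a0 > r0)
            env[r0:(a0 - 1L)] <- config$osc_amplitude +
              (aA - config$osc_amplitude) * ramp[seq_len(a0 - r0)]
          r1 <- min(n, a1 + ramp_n)
          if (r1 > a1)
            env[(a1 + 1L):r1] <- aA +
              (config$osc_amplitude - aA) * ramp[seq_len(r1 - a1)]
        }
        es <- env * carrier_s
        ec <- env * carrier_c
        for (jj in which(targ == sig)) {
          j <- roi_chan_idx[jj]
          samples[j, ] <- samples[j, ] +
            cos(phases[jj]) * es + sin(phases[jj]) * ec
        }
      }
    }

    ground_truth <- if (isTRUE(config$keep_ground_truth)) samples else NULL

    # ocular sources: 1-3 independent blink generators
    if (config$blink_rate > 0) {
      n_src <- if (is.null(config$n_ocular_sources)) sample.int(3L, 1L) else
        as.integer(config$n_ocular_sources)
      wav <- blink_waveform(fs)
      n_blinks <- stats::rpois(1, config$blink_rate * total / 60)
      if (n_blinks > 0) {
        src_of <- sample.int(n_src, n_blinks, replace = TRUE)
        t_blink <- sort(stats::runif(n_blinks, 1, total - 1))
        topo <- lapply(seq_len(n_src), function(s) {
          w <- blink_topography(config$channels)
          w * stats::runif(length(w), 0.95, 1.05)  # per-source jitter
        })
        for (k in seq_len(n_blinks)) {
          i0 <- floor(t_blink[k] * fs) + 1L
          idx <- i0:min(n, i0 + length(wav) - 1L)
          amp <- config$blink_amplitude * stats::runif(1, 0.7, 1.3)
          samples[, idx] <- samples[, idx] +
            outer(topo[[src_of[k]]], amp * wav[seq_along(idx)])
        }
      }
    }

    recording <- list(
      samples = samples, channels = config$channels, fs = fs,
      bad = character(0),
      mask = matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))),
      ground_truth = ground_truth)

    ev <- data.frame(
      participant = p, block = probs$block,
      operand1 = probs$operand1, operation = probs$operation,
      operand2 = probs$operand2, size = probs$size,
      onset = round(onset, 3), rt = round(rt, 3),
      correct = vapply(beh, `[[`, logical(1), "correct"),
      report = vapply(beh, `[[`, character(1), "report"),
      stringsAsFactors = FALSE)
  }
  list(recording = recording, events = ev)
}
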
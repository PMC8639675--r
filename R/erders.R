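# ERD/ERS computation: band-limited power, median horizontal averaging
# (over time within baseline and activity windows, per trial and channel),
# median vertical averaging (over trials within a condition), the
# (A - B) / B ratio, and ROI aggregation.

#' Frequency band definitions
#'
#' Theta (3-6 Hz), lower alpha (8-10 Hz), and upper alpha (10-13 Hz).
#' Theta synchronization indexes memory retrieval; alpha
#' desynchronization indexes task demands and attention. 10 Hz sits on the
#' shared edge of the two alpha bands; band-pass transitions are symmetric
#' about each printed edge, so a small overlap at 10 Hz is accepted.
#'
#' @return data.frame with columns `band`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(band = c("theta", "lower_alpha", "upper_alpha"),
             low = c(3, 8, 10), high = c(6, 10, 13),
             stringsAsFactors = FALSE)
}

#' Analysis window specification
#'
#' Baseline is the half-open interval \[-1.25, -0.25) s relative to problem
#' onset (one second inside the fixation period); the activity window is
#' \[0, rt) — problem onset until the verbal response. The sample at onset
#' belongs to the activity window.
#'
#' @return list with `baseline` (length-2 numeric) field.
#' @export
window_spec <- function() list(baseline = c(-1.25, -0.25))

#' 32-channel extended 10-20 montage
#'
#' Channel labels of the 32-electrode layout used by the paradigm
#' (BioSemi-style extended 10-20 arrangement).
#'
#' @return Character vector of 32 channel labels.
#' @export
montage32 <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
}

#' Default channel-to-ROI map
#'
#' Assigns each non-midline channel to one of four regions of interest
#' (frontal F, fronto-temporo-central FTC, centro-parietal CP,
#' parieto-occipital PO) per hemisphere. Midline channels Fz, Cz, Pz, Oz
#' belong to no ROI. The montage figure shows the regions only as colors,
#' so this mapping is a reconstruction; it is an argument everywhere it is
#' used and can be overridden.
#'
#' @return data.frame with columns `channel`, `roi`, `hemisphere`.
#' @export
roi_map_default <- function() {
  left <- list(F = c("Fp1", "AF3", "F7", "F3"),
               FTC = c("FC5", "FC1", "T7", "C3"),
               CP = c("CP5", "CP1", "P7", "P3"),
               PO = c("PO3", "O1"))
  right <- list(F = c("Fp2", "AF4", "F8", "F4"),
                FTC = c("FC6", "FC2", "T8", "C4"),
                CP = c("CP6", "CP2", "P8", "P4"),
                PO = c("PO4", "O2"))
  build <- function(side, lst) do.call(rbind, lapply(names(lst), function(r)
    data.frame(channel = lst[[r]], roi = r, hemisphere = side,
               stringsAsFactors = FALSE)))
  rbind(build("left", left), build("right", right))
}

validate_roi_map <- function(roi_map) {
  stopifnot(all(c("channel", "roi", "hemisphere") %in% names(roi_map)))
  dup <- roi_map$channel[duplicated(roi_map$channel)]
  if (length(dup))
    stop("channel assigned to more than one ROI: ", paste(dup, collapse = ", "))
  midline <- intersect(roi_map$channel, c("Fz", "Cz", "Pz", "Oz"))
  if (length(midline))
    stop("midline channel(s) in ROI map: ", paste(midline, collapse = ", "))
  invisible(roi_map)
}

#' Instantaneous band power of one channel
#'
#' Zero-phase Hamming-windowed FIR band-pass filtering followed by squaring
#' each sample. The output power series (in microvolts squared) is aligned
#' 1:1 with the input samples.
#'
#' @param x Numeric signal (microvolts).
#' @param band Either a band name from [band_definitions()] or a numeric
#'   `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @return Numeric vector of instantaneous power, same length as `x`.
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 4.5 * seq(0, 10, by = 1 / fs))
#' p <- bandpass_power(x, "theta", fs)
#' mean(p[500:700])  # ~ amplitude^2 / 2 = 0.5
#' @export
bandpass_power <- function(x, band, fs) {
  if (is.character(band)) {
    bd <- band_definitions()
    i <- match(band, bd$band)
    if (is.na(i)) stop("unknown band: ", band)
    band <- c(bd$low[i], bd$high[i])
  }
  h <- design_bandpass(band[1], band[2], fs)
  if (length(x) < length(h))
    stop("signal shorter than the band-pass filter (", length(h), " taps)")
  fir_filtfft(x, h)^2
}

#' Per-trial baseline and activity band power (horizontal averaging)
#'
#' Medians of the instantaneous power over the baseline window
#' \[-1.25, -0.25) s and the activity window \[0, rt) s relative to problem
#' onset, using unmasked samples only. A trial is unusable when less than
#' half of either window survives the artifact mask.
#'
#' @param power Instantaneous power series for one channel.
#' @param fs Sampling rate of `power`.
#' @param onset Problem onset in seconds from recording start.
#' @param rt Response time in seconds (> 0).
#' @param mask Artifact mask: matrix of half-open `(start, end)` intervals
#'   in seconds, or NULL.
#' @param window Window specification, see [window_spec()].
#' @return One-row data.frame: `B_trial`, `A_trial`, `frac_baseline`,
#'   `frac_activity`, `usable`.
#' @export
trial_band_power <- function(power, fs, onset, rt, mask = NULL,
                             window = window_spec()) {
  n <- length(power)
  bad <- if (NROW(mask)) mask_to_samples(merge_intervals(mask), n, fs) else
    logical(n)
  w <- trial_windows(fs, onset, rt, n, bad, window)
  data.frame(
    B_trial = if (length(w$bs)) stats::median(power[w$bs]) else NA_real_,
    A_trial = if (length(w$ac)) stats::median(power[w$ac]) else NA_real_,
    frac_baseline = w$frac_baseline, frac_activity = w$frac_activity,
    usable = w$usable)
}

# Shared window-index arithmetic: half-open [t0, t1) windows, the sample at
# t0 included, masked samples dropped, usability = >= 50% of each window left.
trial_windows <- function(fs, onset, rt, n, bad, window = window_spec()) {
  if (rt <= 0) stop("rt must be positive")
  win_idx <- function(t0, t1) {
    a <- floor(t0 * fs) + 1L          # sample at t0 included
    b <- ceiling(t1 * fs)             # half-open: sample at t1 excluded
    if (a < 1L || b > n) stop("analysis window outside the recording")
    a:b
  }
  bs <- win_idx(onset + window$baseline[1], onset + window$baseline[2])
  ac <- win_idx(onset, onset + rt)
  fb <- 1 - mean(bad[bs]); fa <- 1 - mean(bad[ac])
  list(bs = bs[!bad[bs]], ac = ac[!bad[ac]],
       frac_baseline = fb, frac_activity = fa,
       usable = fb >= 0.5 && fa >= 0.5)
}

#' Condition-level ERD/ERS (vertical averaging then ratio)
#'
#' Given per-trial baseline and activity powers of one condition (one
#' participant x strategy x operation cell, one channel, one band), takes
#' the median across trials of the baseline powers (B) and of the activity
#' powers (A) and forms `(A - B) / B * 100`. Negative values indicate
#' desynchronization (ERD), positive values synchronization (ERS). The
#' ratio is formed after the across-trial medians, never per trial.
#'
#' @param trial_powers data.frame with columns `B_trial`, `A_trial` and
#'   optionally `usable` (non-usable trials are dropped).
#' @return ERD/ERS value in percent, or NA (with a warning) when the
#'   condition is empty or its median baseline power is zero.
#' @examples
#' tp <- data.frame(B_trial = c(1, 2, 9), A_trial = c(2, 4, 18))
#' condition_erders(tp)  # B = 2, A = 4 -> +100
#' @export
condition_erders <- function(trial_powers) {
  tp <- trial_powers
  if ("usable" %in% names(tp)) tp <- tp[tp$usable, , drop = FALSE]
  tp <- tp[!is.na(tp$B_trial) & !is.na(tp$A_trial), , drop = FALSE]
  if (nrow(tp) == 0L) {
    warning("empty condition: ERD/ERS flagged missing")
    return(NA_real_)
  }
  B <- stats::median(tp$B_trial)
  A <- stats::median(tp$A_trial)
  if (B <= 0) {
    warning("non-positive median baseline power: ERD/ERS flagged missing")
    return(NA_real_)
  }
  (A - B) / B * 100
}

#' Aggregate per-channel ERD/ERS into ROI x hemisphere records
#'
#' Arithmetic mean of the per-channel values over the good channels of
#' each (ROI, hemisphere) cell. Midline channels are never part of any
#' ROI; bad channels are excluded. A cell whose channels are all bad (or
#' missing) yields a missing record with a warning.
#'
#' @param channel_values data.frame with columns `channel`, `value`
#'   (percent ERD/ERS), plus any grouping columns to carry through.
#' @param roi_map Channel-to-ROI map, see [roi_map_default()].
#' @param bad_channels Character vector of bad channel labels.
#' @return data.frame with columns `roi`, `hemisphere`, `value`,
#'   `n_channels`, plus carried grouping columns.
#' @export
roi_aggregate <- function(channel_values, roi_map = roi_map_default(),
                          bad_channels = character(0)) {
  validate_roi_map(roi_map)
  cells <- unique(roi_map[c("roi", "hemisphere")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    chans <- roi_map$channel[roi_map$roi == cells$roi[i] &
                             roi_map$hemisphere == cells$hemisphere[i]]
    chans <- setdiff(chans, bad_channels)
    vals <- channel_values$value[match(chans, channel_values$channel)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning("no good channels in ROI ", cells$roi[i], "/",
              cells$hemisphere[i], ": record missing")
      v <- NA_real_
    } else v <- mean(vals)
    data.frame(roi = cells$roi[i], hemisphere = cells$hemisphere[i],
               value = v, n_channels = length(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full ERD/ERS table for one participant
#'
#' Runs the complete per-participant chain: band-pass power per channel and
#' band (on a decimated copy of the cleaned recording; all analysis bands
#' lie well below the reduced Nyquist), per-trial window medians, grouping
#' of correct consistency-retained trials by strategy x operation, vertical
#' median averaging, the ERD/ERS ratio per channel, and ROI aggregation.
#'
#' @param recording Cleaned recording (see [simulate_dataset()] for the
#'   structure: `samples` channels x time, `channels`, `fs`, `bad`, `mask`).
#' @param trials data.frame of this participant's trials with columns
#'   `onset`, `rt`, `correct`, `retained`, `strategy`, `operation`.
#' @param bands Band table, see [band_definitions()].
#' @param roi_map Channel-to-ROI map.
#' @param fs_power Sampling rate for the band-power stage (must divide the
#'   recording rate); 64 Hz by default.
#' @param lowrate Optional pre-decimated cleaned copy of the good channels
#'   (as returned by [preprocess_recording()]), to avoid decimating twice.
#' @return data.frame of ERD/ERS records: `strategy`, `operation`, `band`,
#'   `roi`, `hemisphere`, `value`, `n_trials`, `n_channels`.
#' @export
participant_erders <- function(recording, trials, bands = band_definitions(),
                               roi_map = roi_map_default(), fs_power = 64,
                               lowrate = NULL) {
  validate_roi_map(roi_map)
  keep <- trials$retained & trials$correct
  trials <- trials[keep, , drop = FALSE]
  if (is.null(lowrate)) {
    dec <- decimate_channels(recording$samples, recording$fs, fs_power)
    dec_rows <- recording$channels
  } else {
    dec <- lowrate
    dec_rows <- setdiff(recording$channels, recording$bad)
  }
  n <- ncol(dec$samples)
  badv <- mask_to_samples(merge_intervals(recording$mask), n, dec$fs)
  tw <- lapply(seq_len(nrow(trials)), function(i)
    trial_windows(dec$fs, trials$onset[i], trials$rt[i], n, badv))
  usable <- vapply(tw, `[[`, logical(1), "usable")
  good <- setdiff(recording$channels, recording$bad)
  roi_chans <- intersect(roi_map$channel, good)
  combos <- unique(trials[c("strategy", "operation")])
  out <- list()
  for (b in seq_len(nrow(bands))) {
    band <- c(bands$low[b], bands$high[b])
    # per-channel per-trial window medians (horizontal averaging)
    BA <- lapply(roi_chans, function(ch) {
      p <- bandpass_power(dec$samples[match(ch, dec_rows), ],
                          band, dec$fs)
      cbind(B_trial = vapply(tw, function(w)
              if (length(w$bs)) stats::median(p[w$bs]) else NA_real_, 0),
            A_trial = vapply(tw, function(w)
              if (length(w$ac)) stats::median(p[w$ac]) else NA_real_, 0))
    })
    names(BA) <- roi_chans
    for (i in seq_len(nrow(combos))) {
      sel <- trials$strategy == combos$strategy[i] &
             trials$operation == combos$operation[i] & usable
      vals <- vapply(roi_chans, function(ch)
        condition_erders(as.data.frame(BA[[ch]])[sel, , drop = FALSE]),
        numeric(1))
      cv <- data.frame(channel = roi_chans, value = vals,
                       stringsAsFactors = FALSE)
      rec <- roi_aggregate(cv, roi_map, recording$bad)
      rec$strategy <- combos$strategy[i]
      rec$operation <- combos$operation[i]
      rec$band <- bands$band[b]
      rec$n_trials <- sum(sel)
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  res[c("strategy", "operation", "band", "roi", "hemisphere",
        "value", "n_trials", "n_channels")]
}
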
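# Orchestration: simulate (or accept) a dataset, clean every recording,
# compute ERD/ERS records, behavioral summaries, and the inferential
# layer, and write all outputs plus a machine-readable manifest.

#' Write a trial-events table to TSV
#'
#' BIDS-flavored events file: columns `onset`, `duration`, `trial_type`,
#' `response_time`, `correct`, `report`, plus any further columns present
#' (e.g. `participant`, `block`, operands, `size`). Timestamps are written
#' with millisecond precision.
#'
#' @param events Trial table with at least `onset`, `rt`, `correct`,
#'   `report` (plus `operation`/`size` for the trial_type label).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset", "rt", "correct", "report") %in% names(events)))
  out <- data.frame(
    onset = sprintf("%.3f", events$onset),
    duration = sprintf("%.3f", events$rt),
    trial_type = if (all(c("operation", "size") %in% names(events)))
      paste(events$size, events$operation, sep = "_") else "trial",
    response_time = sprintf("%.3f", events$rt),
    correct = as.integer(events$correct),
    report = events$report,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(events), c("onset", "rt", "correct", "report"))
  for (col in extra) out[[col]] <- events[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial-events table from TSV
#'
#' Validates the schema (every required column must be present, named in
#' the error when missing) and the event invariants: positive response
#' times and strictly increasing onsets within each participant.
#'
#' @param path Events TSV written by [write_events()].
#' @return data.frame with `onset`, `rt`, `correct` (logical), `report`,
#'   and all extra columns preserved.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "response_time", "correct",
            "report")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  out <- ev[setdiff(names(ev), c("duration", "trial_type", "response_time"))]
  out$rt <- as.numeric(ev$response_time)
  out$onset <- as.numeric(ev$onset)
  out$correct <- as.logical(ev$correct)
  if (any(out$rt <= 0)) stop("non-positive response_time in events file")
  split_by <- if ("participant" %in% names(out)) out$participant else
    rep(1L, nrow(out))
  for (s in split(out$onset, split_by))
    if (is.unsorted(s, strictly = TRUE))
      stop("onsets not strictly increasing within participant")
  out
}

#' Load a pipeline run configuration from YAML
#'
#' Reads a YAML file whose top-level keys are `simulation` (overrides for
#' [simulation_config()]), `preprocessing` (overrides for
#' [preproc_config()]), `fs_power`, and `out_dir`. Every paradigm constant
#' (trial timing, band edges, windows, ROI map) has its default surfaced
#' through those constructors.
#'
#' @param path YAML file path.
#' @return list with `sim`, `preproc`, `fs_power`, `out_dir`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, if (is.null(y$simulation)) list() else
    y$simulation)
  pp <- do.call(preproc_config, if (is.null(y$preprocessing)) list() else
    y$preprocessing)
  list(sim = sim, preproc = pp,
       fs_power = if (is.null(y$fs_power)) 64 else y$fs_power,
       out_dir = if (is.null(y$out_dir)) "results" else y$out_dir)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a multi-participant dataset, then runs the
#' complete chain: stimulus validation, per-recording cleaning, the
#' strategy-report consistency filter with Cohen's kappa, behavioral
#' summaries, ERD/ERS computation per participant, mixed-effects models
#' (response time, accuracy, and one ERD/ERS model per band), and Tukey
#' post-hoc contrasts. All tables are written as CSV/JSON under `out_dir`
#' together with a manifest of trial counts at every stage.
#'
#' @param sim_config [simulation_config()] for simulate mode.
#' @param preproc [preproc_config()].
#' @param out_dir Output directory (created if missing); NULL skips
#'   writing.
#' @param dataset Optional pre-built dataset (as from
#'   [simulate_dataset()]); when supplied, simulation is skipped.
#' @param fs_power Sampling rate of the band-power stage (Hz).
#' @param roi_map Channel-to-ROI map.
#' @param posthoc_specs Formula for the topographic post-hoc
#'   (`~ strategy * roi * hemisphere` by default, applied per band).
#' @param verbose Print stage progress.
#' @return list with `erders` (record table), `behavior` (kappa,
#'   consistency table, accuracy and RT summaries), `models` (effect
#'   tables and post-hocs), `cleaning` (per-participant reports), and
#'   `manifest` (stage counts).
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         preproc = preproc_config(),
                         out_dir = NULL, dataset = NULL, fs_power = 64,
                         roi_map = roi_map_default(),
                         posthoc_specs = ~ strategy * roi * hemisphere,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  problems <- read_problem_set()
  stopifnot(validate_problem_set(problems)$ok)

  simulate_mode <- is.null(dataset)
  n_participants <- if (simulate_mode) sim_config$n_participants else
    length(dataset$recordings)

  # one participant at a time: generate (or fetch), clean, reduce to
  # ERD/ERS records, then discard the raw recording
  say("cleaning + ERD/ERS, ", n_participants, " participants")
  cleaning <- vector("list", n_participants)
  erders <- vector("list", n_participants)
  events <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    say("  participant ", p, "/", n_participants)
    if (simulate_mode) {
      one <- simulate_participant(sim_config, problems, p)
      recording <- one$recording
      ev_p <- one$events
    } else {
      recording <- dataset$recordings[[p]]
      ev_p <- dataset$events[dataset$events$participant == p, , drop = FALSE]
    }
    pre <- preprocess_recording(recording, preproc)
    cleaning[[p]] <- pre$report
    ev_p$strategy <- ifelse(ev_p$size == "small", "retrieve", "procedure")
    ev_p$retained <- ev_p$report == ev_p$strategy   # consistency rule
    rec <- participant_erders(pre$recording, ev_p, roi_map = roi_map,
                              fs_power = fs_power, lowrate = pre$lowrate)
    rec$participant <- p
    erders[[p]] <- rec
    events[[p]] <- ev_p
  }
  erders <- do.call(rbind, erders)
  events <- do.call(rbind, events)

  say("consistency filter")
  cf <- consistency_filter(events)
  kap <- cohen_kappa(cf$table[, c("procedure", "retrieve")])
  retained <- cf$retained

  say("behavioral summaries")
  acc <- summarize_accuracy(retained)
  rts <- summarize_rt(retained[retained$correct, , drop = FALSE])

  say("mixed-effects models")
  rt_model <- fit_rt_model(retained[retained$correct, , drop = FALSE])
  acc_model <- fit_accuracy_model(retained)
  band_models <- lapply(split(erders, erders$band), fit_erders_model)
  posthocs <- lapply(band_models, function(m)
    pairwise_posthoc(m$model, posthoc_specs))
  rt_posthoc <- pairwise_posthoc(rt_model$model, ~ strategy * operation)

  manifest <- list(
    n_participants = n_participants,
    trials_total = nrow(events),
    trials_retained = nrow(retained),
    trials_excluded = nrow(cf$exclusions),
    trials_excluded_unknown = sum(cf$exclusions$reason == "unknown"),
    trials_correct_retained = sum(retained$correct),
    erders_records = nrow(erders),
    erders_missing = sum(is.na(erders$value)),
    posthoc_contrasts = vapply(posthocs, function(ph) nrow(ph$contrasts),
                               numeric(1)),
    stage_conservation = nrow(retained) + nrow(cf$exclusions) == nrow(events))

  out <- list(
    erders = erders,
    behavior = list(kappa = kap, consistency_table = cf$table,
                    accuracy = acc, rt = rts),
    models = list(rt = rt_model, accuracy = acc_model, erders = band_models,
                  posthoc = posthocs, rt_posthoc = rt_posthoc),
    cleaning = cleaning,
    events = events,
    manifest = manifest)

  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(run$erders, "erders.csv")
  w(as.data.frame(run$behavior$consistency_table), "consistency_table.csv")
  w(run$behavior$accuracy$summary, "accuracy_summary.csv")
  w(run$behavior$rt, "rt_summary.csv")
  effects <- rbind(run$models$rt$effects,
                   if (!is.null(run$models$accuracy$effects))
                     run$models$accuracy$effects)
  w(effects, "glmm_effects.csv")
  for (b in names(run$models$erders)) {
    w(run$models$erders[[b]]$effects, paste0("erders_effects_", b, ".csv"))
    w(run$models$posthoc[[b]]$contrasts, paste0("posthoc_", b, ".csv"))
    w(run$models$posthoc[[b]]$emmeans, paste0("emmeans_", b, ".csv"))
  }
  jsonlite::write_json(
    c(run$manifest, list(kappa = run$behavior$kappa$kappa,
                         agreement = run$behavior$kappa$agreement)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  cr <- lapply(run$cleaning, function(r)
    list(bad = r$bad, n_mask = NROW(r$mask), removed = r$removed,
         n_components = r$n_components))
  jsonlite::write_json(cr, file.path(out_dir, "cleaning_reports.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
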
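# Strategy-report handling and behavioral summaries.

#' Consistency filter for strategy reports
#'
#' Retains only trials whose verbal strategy report agrees with the
#' problem-size proxy: small problems reported as retrieved and large
#' problems reported as procedural. Trials with an "unknown" report are
#' always dropped. Retained trials carry their report as the final
#' strategy label.
#'
#' @param trials data.frame with at least columns `size`
#'   (`"small"`/`"large"`) and `report`
#'   (`"retrieve"`/`"procedure"`/`"unknown"`).
#' @return list with `retained` (subset of `trials` plus a `strategy`
#'   column), `table` (size x report contingency table of all input
#'   trials), and `exclusions` (data.frame of dropped trials with a
#'   `reason` column: `"unknown"` or `"inconsistent"`).
#' @export
consistency_filter <- function(trials) {
  stopifnot(all(c("size", "report") %in% names(trials)))
  size <- factor(trials$size, levels = c("large", "small"))
  report <- factor(trials$report, levels = c("procedure", "retrieve", "unknown"))
  if (anyNA(size) || anyNA(report))
    stop("size must be large/small and report procedure/retrieve/unknown")
  tab <- table(size = size, report = report)
  keep <- (size == "small" & report == "retrieve") |
          (size == "large" & report == "procedure")
  reason <- ifelse(report == "unknown", "unknown", "inconsistent")
  retained <- trials[keep, , drop = FALSE]
  retained$strategy <- as.character(report[keep])
  exclusions <- trials[!keep, , drop = FALSE]
  exclusions$reason <- reason[!keep]
  list(retained = retained, table = tab, exclusions = exclusions)
}

#' Agreement and Cohen's kappa for a 2x2 contingency table
#'
#' Chance-corrected agreement between the problem-size classification and
#' the dichotomous strategy report (after dropping unknown reports):
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' computed from the marginal products.
#'
#' @param tab 2x2 numeric matrix or table of agreement counts, categories
#'   in the same order on rows and columns (diagonal = agreement).
#' @return list with `agreement` (observed proportion `p_o`), `kappa`, and
#'   `n`. `kappa` is NA (with a warning) when the marginals are degenerate
#'   (`p_e = 1`).
#' @examples
#' cohen_kappa(matrix(c(1080, 148, 144, 1076), 2))
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L, all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty table")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps^0.5) {
    warning("degenerate marginals: expected agreement is 1, kappa undefined")
    k <- NA_real_
  } else k <- (po - pe) / (1 - pe)
  list(agreement = po, kappa = k, n = n)
}

#' Per-condition solution accuracy
#'
#' Per participant and strategy x operation cell, the proportion of correct
#' responses among retained trials; then the across-participant mean and
#' standard deviation per cell. Participant cells with no trials are
#' dropped from the mean/sd with a warning.
#'
#' @param trials Retained trials with columns `participant`, `strategy`,
#'   `operation`, `correct`.
#' @return list with `by_participant` (participant-level proportions) and
#'   `summary` (per-cell `n`, `mean`, `sd`).
#' @export
summarize_accuracy <- function(trials) {
  stopifnot(all(c("participant", "strategy", "operation", "correct") %in%
                names(trials)))
  agg <- stats::aggregate(correct ~ participant + strategy + operation,
                          data = trials, FUN = mean)
  names(agg)[names(agg) == "correct"] <- "accuracy"
  cells <- expand.grid(participant = unique(trials$participant),
                       strategy = unique(trials$strategy),
                       operation = unique(trials$operation),
                       stringsAsFactors = FALSE)
  if (nrow(agg) < nrow(cells))
    warning(nrow(cells) - nrow(agg),
            " participant-condition cell(s) without trials dropped")
  sm <- stats::aggregate(accuracy ~ strategy + operation, data = agg,
                         FUN = function(x) c(n = length(x), mean = mean(x),
                                             sd = stats::sd(x)))
  sm <- cbind(sm[c("strategy", "operation")], as.data.frame(sm$accuracy))
  list(by_participant = agg, summary = sm)
}

#' Response-time summary per condition
#'
#' Six-number summaries (min, first quartile, median, mean, third
#' quartile, max) of correct-trial response times pooled over participants
#' within each strategy x operation cell. Quartiles use linear
#' interpolation (the standard type-7 convention).
#'
#' @param trials Correct retained trials with columns `strategy`,
#'   `operation`, `rt` (seconds).
#' @return data.frame with one row per cell: `strategy`, `operation`, `n`,
#'   `min`, `q1`, `median`, `mean`, `q3`, `max`.
#' @export
summarize_rt <- function(trials) {
  stopifnot(all(c("strategy", "operation", "rt") %in% names(trials)))
  cells <- unique(trials[c("strategy", "operation")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    x <- trials$rt[trials$strategy == cells$strategy[i] &
                   trials$operation == cells$operation[i]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(strategy = cells$strategy[i], operation = cells$operation[i],
               n = length(x), min = min(x), q1 = q[1], median = q[2],
               mean = mean(x), q3 = q[3], max = max(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
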
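# Mixed-effects inference: inverse-Gaussian GLMM for response times,
# binomial GLMM for accuracy, Gaussian LMMs for ERD/ERS per band, plus
# estimated marginal means and Tukey-adjusted pairwise contrasts.
# Factors are coded sum-to-zero throughout so main effects remain
# interpretable in the presence of interactions (type-III-style tests).

sum_contrasts <- function(data, factors) {
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  data
}

# Per-term likelihood-ratio tests for a strategy x operation GLMM with a
# participant random intercept: the full model is compared against a model
# whose model-matrix columns for one term are removed (sum-to-zero coding,
# so lower-order terms keep their meaning).
glmm_term_lrt <- function(data, response, family, model_id) {
  data <- sum_contrasts(data, c("strategy", "operation"))
  X <- stats::model.matrix(~ strategy * operation, data)
  asn <- attr(X, "assign")
  labels <- c("strategy", "operation", "strategy:operation")
  fit_with <- function(Xm) {
    df <- data.frame(.y = data[[response]], participant = data$participant)
    df$X <- Xm
    lme4::glmer(.y ~ 0 + X + (1 | participant), data = df, family = family,
                nAGQ = 0L)
  }
  # the full model is fitted on the factor formula (same column space as X)
  # so that estimated marginal means can be derived from it downstream
  data$.y <- data[[response]]
  full <- lme4::glmer(.y ~ strategy * operation + (1 | participant),
                      data = data, family = family, nAGQ = 0L)
  eff <- do.call(rbind, lapply(seq_along(labels), function(t) {
    red <- fit_with(X[, asn != t, drop = FALSE])
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(red))))
    df <- sum(asn == t)
    data.frame(model = model_id, term = labels[t], statistic_kind = "chisq",
               statistic = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(effects = eff, model = full)
}

#' Fit the response-time model
#'
#' Generalized linear mixed-effects model for correct-trial response
#' times: inverse-Gaussian error distribution with identity link (the
#' canonical choice for right-skewed response times), fixed effects
#' strategy, operation, and their interaction, and a participant random
#' intercept. Each term is tested with a type-III-style likelihood-ratio
#' chi-squared test. If the inverse-Gaussian fit fails, the function falls
#' back — with a warning — to a linear mixed model on log response times
#' (a location-scale surrogate with the same fixed/random structure).
#'
#' @param trials Correct retained trials: columns `participant`,
#'   `strategy`, `operation`, `rt`.
#' @return list with `effects` (term table: statistic, df, p), `model`
#'   (the fitted model, for post-hocs), and `family` (`"inverse.gaussian"`
#'   or `"lognormal-fallback"`).
#' @export
fit_rt_model <- function(trials) {
  check_model_input(trials, "rt")
  res <- tryCatch(
    glmm_term_lrt(trials, "rt", stats::inverse.gaussian(link = "identity"),
                  "rt"),
    error = function(e) e, warning = function(w) w)
  if (inherits(res, "condition")) {
    warning("inverse-Gaussian RT model did not converge (",
            conditionMessage(res), "); falling back to log-RT linear model")
    trials$.logrt <- log(trials$rt)
    res <- lmm_term_lrt(trials, ".logrt", "rt")
    res$family <- "lognormal-fallback"
  } else res$family <- "inverse.gaussian"
  res
}

# LRT battery for the Gaussian fallback (ML fits on log RT).
lmm_term_lrt <- function(data, response, model_id) {
  data <- sum_contrasts(data, c("strategy", "operation"))
  X <- stats::model.matrix(~ strategy * operation, data)
  asn <- attr(X, "assign")
  labels <- c("strategy", "operation", "strategy:operation")
  fit_with <- function(Xm) {
    df <- data.frame(.y = data[[response]], participant = data$participant)
    df$X <- Xm
    lme4::lmer(.y ~ 0 + X + (1 | participant), data = df, REML = FALSE)
  }
  data$.y <- data[[response]]
  full <- lme4::lmer(.y ~ strategy * operation + (1 | participant),
                     data = data, REML = FALSE)
  eff <- do.call(rbind, lapply(seq_along(labels), function(t) {
    red <- fit_with(X[, asn != t, drop = FALSE])
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(red))))
    df <- sum(asn == t)
    data.frame(model = model_id, term = labels[t], statistic_kind = "chisq",
               statistic = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(effects = eff, model = full)
}

check_model_input <- function(trials, what) {
  need <- c("participant", "strategy", "operation", what)
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(trials$participant)) < 2)
    stop("need at least 2 participants")
  if (length(unique(trials$strategy)) < 2 ||
      length(unique(trials$operation)) < 2)
    stop("both strategies and both operations must be present")
  invisible(trials)
}

#' Fit the accuracy model
#'
#' Binomial GLMM with logit link on trial-level correctness: fixed effects
#' strategy, operation, and their interaction; participant random
#' intercept; type-III-style likelihood-ratio tests per term. Complete or
#' quasi-complete separation (constant outcome in a design cell, or
#' diverging coefficients) is flagged in the result rather than silently
#' dropped.
#'
#' @param trials Retained trials: columns `participant`, `strategy`,
#'   `operation`, `correct` (logical).
#' @return list with `effects`, `model`, and `separation` (logical flag).
#' @export
fit_accuracy_model <- function(trials) {
  check_model_input(trials, "correct")
  cellp <- stats::aggregate(correct ~ strategy + operation, data = trials,
                            FUN = mean)
  degenerate <- any(cellp$correct %in% c(0, 1))
  if (all(trials$correct) || all(!trials$correct)) {
    warning("constant outcome: complete separation, no model fitted")
    return(list(effects = NULL, model = NULL, separation = TRUE))
  }
  res <- glmm_term_lrt(trials, "correct", stats::binomial(link = "logit"),
                       "accuracy")
  sep <- degenerate || any(abs(lme4::fixef(res$model)) > 10)
  if (sep) warning("possible separation in the accuracy model")
  res$separation <- sep
  res
}

#' Fit the ERD/ERS model for one band
#'
#' Standard linear mixed-effects model on the ERD/ERS records of one
#' frequency band: full-factorial fixed effects operation x strategy x
#' ROI x hemisphere (all interactions up to the four-way term) and a
#' participant random intercept. Per-term F tests use Satterthwaite
#' denominator degrees of freedom with type-III sums of squares. A
#' singular fit triggers a logged refit without the four-way interaction.
#'
#' @param records ERD/ERS records of one band: columns `participant`,
#'   `strategy`, `operation`, `roi`, `hemisphere`, `value`.
#' @return list with `effects` (term, F, df1, df2, p), `model`,
#'   `n_rows`, and `residual_df` (structural residual degrees of freedom:
#'   rows minus fixed-effect parameters minus participant effects).
#' @export
fit_erders_model <- function(records) {
  need <- c("participant", "strategy", "operation", "roi", "hemisphere",
            "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- records[!is.na(records$value), , drop = FALSE]
  records <- sum_contrasts(records,
                           c("strategy", "operation", "roi", "hemisphere"))
  form <- value ~ operation * strategy * roi * hemisphere + (1 | participant)
  fit <- lmerTest::lmer(form, data = records)
  if (lme4::isSingular(fit)) {
    warning("singular fit: refitting without the four-way interaction")
    form <- value ~ (operation + strategy + roi + hemisphere)^3 +
      (1 | participant)
    fit <- lmerTest::lmer(form, data = records)
  }
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  eff <- data.frame(model = "erders", term = rownames(an),
                    statistic_kind = "F-test", statistic = an$`F value`,
                    df1 = an$NumDF, df2 = an$DenDF, p = an$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  p_fixed <- length(lme4::fixef(fit))
  n_part <- length(unique(records$participant))
  list(effects = eff, model = fit, n_rows = nrow(records),
       residual_df = nrow(records) - p_fixed - (n_part - 1))
}

#' Estimated marginal means and Tukey-adjusted pairwise contrasts
#'
#' Computes model-based cell means with 95% confidence intervals for a
#' factor combination and all pairwise contrasts between the cells with
#' Tukey-family adjustment. For k cells this yields choose(k, 2)
#' contrasts.
#'
#' @param model A fitted mixed model (from [fit_erders_model()] or the
#'   strategy x operation models; for the latter the design factors must
#'   be named in `specs` as in the fitting data).
#' @param specs Right-hand-side formula naming the factors, e.g.
#'   `~ strategy * roi * hemisphere`.
#' @return list with `emmeans` (cell means, SE, 95% CI) and `contrasts`
#'   (pair, estimate, adjusted p).
#' @export
pairwise_posthoc <- function(model, specs) {
  em <- emmeans::emmeans(model, specs)
  ct <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  list(emmeans = as.data.frame(em), contrasts = as.data.frame(ct))
}
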
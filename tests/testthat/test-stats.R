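# Model-level tests work on synthetic trial/record tables generated
# directly at the model interface, so they run fast and have known truth.

make_erders_records <- function(n_part, strategy_gap = 0, sd_noise = 8,
                                sd_part = 4, seed = 1) {
  set.seed(seed)
  re <- expand.grid(participant = factor(seq_len(n_part)),
                    strategy = c("retrieve", "procedure"),
                    operation = c("subtraction", "multiplication"),
                    roi = c("F", "FTC", "CP", "PO"),
                    hemisphere = c("left", "right"),
                    stringsAsFactors = FALSE)
  b <- rnorm(n_part, 0, sd_part)
  re$value <- rnorm(nrow(re), 0, sd_noise) + b[as.integer(re$participant)] +
    ifelse(re$strategy == "retrieve", strategy_gap / 2, -strategy_gap / 2)
  re
}

test_that("RT model recovers large configured condition differences", {
  cfg <- simulation_config()
  set.seed(30)
  tr <- expand.grid(participant = factor(1:8),
                    strategy = c("retrieve", "procedure"),
                    operation = c("subtraction", "multiplication"),
                    rep = 1:20, stringsAsFactors = FALSE)
  tr$rt <- mapply(function(s, o) generate_behavior(s, o, cfg)$rt,
                  tr$strategy, tr$operation)
  fit <- suppressWarnings(fit_rt_model(tr))
  eff <- fit$effects
  expect_equal(eff$term,
               c("strategy", "operation", "strategy:operation"))
  expect_lt(eff$p[eff$term == "strategy"], 0.001)
  expect_lt(eff$p[eff$term == "strategy:operation"], 0.001)
  expect_true(all(eff$p >= 0 & eff$p <= 1))

  # estimated marginal means order matches the configured means
  ph <- pairwise_posthoc(fit$model, ~ strategy * operation)
  expect_equal(nrow(ph$contrasts), 6)   # C(4, 2)
  em <- ph$emmeans
  expect_gt(em$emmean[em$strategy == "procedure" &
                      em$operation == "multiplication"],
            em$emmean[em$strategy == "retrieve" &
                      em$operation == "subtraction"])
})

test_that("model preconditions and degenerate inputs are caught", {
  tr <- data.frame(participant = factor(rep(1:4, each = 10)),
                   strategy = "retrieve", operation = "subtraction",
                   rt = rexp(40) + 1, correct = TRUE)
  expect_error(fit_rt_model(tr), "strategies")
  expect_error(fit_rt_model(tr[, -4]), "missing column")

  both <- expand.grid(participant = factor(1:4),
                      strategy = c("retrieve", "procedure"),
                      operation = c("subtraction", "multiplication"),
                      rep = 1:5)
  both$correct <- TRUE
  expect_warning(res <- fit_accuracy_model(both), "separation")
  expect_true(res$separation)
})

test_that("accuracy model detects a configured strategy gap", {
  set.seed(31)
  tr <- expand.grid(participant = factor(1:10),
                    strategy = c("retrieve", "procedure"),
                    operation = c("subtraction", "multiplication"),
                    rep = 1:20, stringsAsFactors = FALSE)
  tr$correct <- runif(nrow(tr)) <
    ifelse(tr$strategy == "retrieve", 0.98, 0.90)
  res <- suppressWarnings(fit_accuracy_model(tr))
  expect_lt(res$effects$p[res$effects$term == "strategy"], 0.01)
})

test_that("ERD/ERS model structure matches the balanced design", {
  re <- make_erders_records(31, strategy_gap = 0, seed = 7)
  fit <- fit_erders_model(re)
  expect_equal(fit$n_rows, 992)
  expect_equal(fit$residual_df, 930)
  expect_equal(nrow(fit$effects), 15)   # 4 mains + 6 + 4 + 1 interactions
  main <- fit$effects[fit$effects$term %in%
                      c("strategy", "operation", "hemisphere"), ]
  expect_true(all(main$df1 == 1))
  expect_true(all(abs(main$df2 - 930) < 1))
  expect_equal(fit$effects$df1[fit$effects$term == "roi"], 3)
})

test_that("ERD/ERS model detects an injected strategy effect with the right sign", {
  re <- make_erders_records(31, strategy_gap = 10, seed = 8)
  fit <- fit_erders_model(re)
  expect_lt(fit$effects$p[fit$effects$term == "strategy"], 0.001)
  ph <- pairwise_posthoc(fit$model, ~ strategy * roi * hemisphere)
  expect_equal(nrow(ph$contrasts), choose(16, 2))   # 120
  em <- ph$emmeans
  expect_gt(mean(em$emmean[em$strategy == "retrieve"]),
            mean(em$emmean[em$strategy == "procedure"]))
  expect_true(all(c("lower.CL", "upper.CL") %in% names(em)))
})

test_that("Tukey adjustment never reports smaller p than unadjusted", {
  re <- make_erders_records(10, strategy_gap = 3, seed = 9)
  fit <- fit_erders_model(re)
  em <- emmeans::emmeans(fit$model, ~ strategy * roi)
  tukey <- as.data.frame(emmeans::contrast(em, "pairwise",
                                           adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_true(all(tukey$p.value >= raw$p.value - 1e-12))
})
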
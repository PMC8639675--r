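#!/usr/bin/env Rscript
# Stage 2 — behavior without EEG.
#
# Draws trial-level behavior (inverse-Gaussian response times, binomial
# correctness, noisy verbal strategy reports) for a 31-child cohort on
# the full problem set, then applies the strategy-report consistency
# filter and summarizes agreement (Cohen's kappa), accuracy, and response
# times per strategy x operation cell. This is the behavioral half of the
# analysis; the EEG half follows in stage 3.

library(oscarith)

dir.create("results", showWarnings = FALSE)
set.seed(20211202)

cfg <- simulation_config()
problems <- read_problem_set()
strategy_design <- ifelse(classify_size(problems) == "small",
                          "retrieve", "procedure")

events <- do.call(rbind, lapply(seq_len(cfg$n_participants), function(p) {
  beh <- lapply(seq_len(nrow(problems)), function(i)
    generate_behavior(strategy_design[i], problems$operation[i], cfg))
  data.frame(participant = p, operation = problems$operation,
             size = classify_size(problems),
             rt = vapply(beh, `[[`, numeric(1), "rt"),
             correct = vapply(beh, `[[`, logical(1), "correct"),
             report = vapply(beh, `[[`, character(1), "report"))
}))

cf <- consistency_filter(events)
k <- cohen_kappa(cf$table[, c("procedure", "retrieve")])

cat("Trials:", nrow(events), " retained:", nrow(cf$retained),
    " excluded:", nrow(cf$exclusions),
    "(", sum(cf$exclusions$reason == "unknown"), "unknown )\n")
cat("Agreement:", round(k$agreement, 3), " Cohen's kappa:",
    round(k$kappa, 3), "\n\n")

acc <- summarize_accuracy(cf$retained)
print(acc$summary, digits = 3)
rts <- summarize_rt(cf$retained[cf$retained$correct, ])
print(rts, digits = 3)

utils::write.csv(as.data.frame(cf$table), "results/consistency_table.csv",
                 row.names = FALSE)
utils::write.csv(acc$summary, "results/accuracy_summary.csv",
                 row.names = FALSE)
utils::write.csv(rts, "results/rt_summary.csv", row.names = FALSE)
cat("\nWrote results/consistency_table.csv, accuracy_summary.csv,",
    "rt_summary.csv\n")
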
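#!/usr/bin/env Rscript
# Stage 4 — inferential summary.
#
# Reads the tables written by stage 3 and prints the effect structure:
# chi-squared tests for the response-time and accuracy GLMMs, F tests per
# term for the three band-wise ERD/ERS linear mixed models, and the sizes
# of the Tukey-adjusted post-hoc families.

stopifnot(dir.exists("results/run"))

glmm <- utils::read.csv("results/run/glmm_effects.csv")
cat("Generalized linear mixed models (chi-squared tests):\n")
print(glmm, digits = 3)

for (band in c("theta", "lower_alpha", "upper_alpha")) {
  eff <- utils::read.csv(sprintf("results/run/erders_effects_%s.csv", band))
  cat("\n", band, " band (F tests):\n", sep = "")
  print(eff[eff$p < 0.1, ], digits = 3)
  ph <- utils::read.csv(sprintf("results/run/posthoc_%s.csv", band))
  cat(" post-hoc family:", nrow(ph), "contrasts,",
      sum(ph$p.value < 0.05), "significant at 0.05\n")
}
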
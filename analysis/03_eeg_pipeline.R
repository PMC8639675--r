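#!/usr/bin/env Rscript
# Stage 3 — the full EEG pipeline at study scale.
#
# Simulates 31 participants (continuous 32-channel recordings at 512 Hz
# with condition-dependent oscillatory modulation and blink artifacts),
# cleans each recording (bad channels, common average reference, artifact
# masking, ICA ocular removal), computes per-condition ERD/ERS values for
# theta, lower alpha, and upper alpha in four ROIs per hemisphere, and
# fits the mixed-effects models with Tukey post-hocs. Expect roughly ten
# minutes of runtime on one core; every output lands in results/run/.

library(oscarith)

run <- run_pipeline(simulation_config(), out_dir = "results/run")

m <- run$manifest
cat("\nParticipants:", m$n_participants,
    "\nTrials:", m$trials_total, "retained:", m$trials_retained,
    "\nERD/ERS records:", m$erders_records,
    "( missing:", m$erders_missing, ")\n")
cat("Cohen's kappa:", round(run$behavior$kappa$kappa, 3), "\n")

cat("\nCondition means (percent ERD/ERS) by band and strategy:\n")
print(aggregate(value ~ band + strategy, run$erders,
                function(v) round(mean(v), 1)))
cat("\nOutputs in results/run/\n")
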
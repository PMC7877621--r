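#!/usr/bin/env Rscript
# Stage 3: platform preferences from the discrete choice experiment.
# Builds a randomized balanced design (2 blocks x 16 sets x 3 alternatives),
# simulates 48 participants' choices from the published part-worths, refits
# the conditional logit, and reports validity diagnostics. The published
# coefficients remain the default for the downstream valuation; the refit
# shows what a 48-participant survey can and cannot pin down.

library(vaxpda)

seed <- 1L
lv <- default_attribute_levels()
design <- build_design(lv, seed = seed)
cfg <- synthetic_config(seed = seed)
choices <- generate_choice_responses(cfg, design)
fit <- fit_conditional_logit(choices, lv)

dir.create("results", showWarnings = FALSE)
write.csv(choices, "results/data/choices.csv", row.names = FALSE)
write.csv(fit$coefficients, "results/part_worths_fit.csv", row.names = FALSE)
write.csv(default_part_worths()$coefficients,
          "results/part_worths_published.csv", row.names = FALSE)

cat("Design: ", length(unique(design$sets$set_id)), "choice sets;",
    "level balance within +/-1 per platform;",
    length(design$dominant_sets), "dominance probe(s),",
    length(design$repeated_sets), "repeat probe(s)\n\n")
cat("Conditional logit refit from 48 simulated participants:\n")
print(fit)
truth <- default_part_worths()$coefficients
cat(sprintf("\nMax |refit - published| = %.3f (published SEs ~0.07-0.08;\n",
            max(abs(c(fit$coefficients$beta_b - truth$beta_b,
                      fit$coefficients$beta_c - truth$beta_c)))))
cat("48 participants bound precision; the valuation uses the published table)\n")
val <- validity_checks(choices, design)
cat("Dominance pass rate:",
    ifelse(val$applicable$dominance,
           sprintf("%.2f", val$summary$dominance_rate), "n/a (no probe)"),
    "| consistency:",
    ifelse(val$applicable$consistency,
           sprintf("%.2f", val$summary$consistency_rate), "n/a (no probe)"),
    "\n")
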
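#!/usr/bin/env Rscript
# Stage 2: project probability-of-success distributions.
# Reviewer-mixture Monte Carlo (10,000 iterations): each iteration picks one
# assigned reviewer per project, draws the seven factors from that reviewer's
# triangular three-point estimates and multiplies them into project PoS.

library(vaxpda)

seed <- 1L
cfg <- synthetic_config(seed = seed)
roster <- read_roster_csv("results/data/roster.csv")
assignment <- with(read.csv("results/data/assignment.csv"),
                   split(reviewer_id, project_id)[roster$project_id])
assessments <- read.csv("results/data/assessments.csv")

summaries <- list()
for (stage in c("initial", "final")) {
  pos <- simulate_project_pos(assessments, assignment, roster,
                              n_iter = 10000, seed = seed, stage = stage)
  s <- summarize_draws(unclass(pos))
  names(s)[1] <- "project_id"
  summaries[[stage]] <- cbind(stage = stage, s)
}
out <- do.call(rbind, summaries)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/pos_summary.csv", row.names = FALSE)

cat("Project PoS (mean of 10,000 iterations), final assessments:\n")
fin <- out[out$stage == "final", ]
print(fin[order(-fin$mean), c("project_id", "mean", "ci_low", "ci_high")],
      row.names = FALSE, digits = 3)
cat(sprintf("\nPoS shrinks from the initial to the final stage by %.0f%% on average;\n",
            100 * (1 - mean(fin$mean) /
                     mean(out$mean[out$stage == "initial"]))))
cat("estimates are low and heavily overlapping across projects, as expected\n")
cat("for seven multiplied factor probabilities.\n")
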
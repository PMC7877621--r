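#!/usr/bin/env Rscript
# Stage 1: synthetic elicitation study.
# Generates the project roster (16 projects, 5 platform types, budgets
# US$6-65m), the reviewer assignment (pool of 27, 4-5 reviewers per project,
# at most 4 projects each), and three-point factor assessments for both the
# initial and the downward-revised final stage.

library(vaxpda)

seed <- 1L
cfg <- synthetic_config(seed = seed)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

roster <- generate_roster(cfg)
assignment <- assign_reviewers(cfg, roster)
assessments <- generate_assessments(cfg, assignment)

write.csv(roster, "results/data/roster.csv", row.names = FALSE)
write.csv(data.frame(project_id = rep(names(assignment),
                                      lengths(assignment)),
                     reviewer_id = unlist(assignment)),
          "results/data/assignment.csv", row.names = FALSE)
write.csv(assessments, "results/data/assessments.csv", row.names = FALSE)

cat("Roster:", nrow(roster), "projects,",
    length(unique(roster$platform_type)), "platform types, total budget",
    sprintf("US$%.1fm", sum(roster$budget_musd)), "\n")
cat("Reviewers per project:",
    paste(range(lengths(assignment)), collapse = "-"),
    "| projects per reviewer:",
    paste(range(table(unlist(assignment))), collapse = "-"), "\n")
ini <- assessments[assessments$stage == "initial", ]
fin <- assessments[assessments$stage == "final", ]
cat(sprintf("Mean most-likely factor estimate: %.3f initial vs %.3f final\n",
            mean(ini$most_likely), mean(fin$most_likely)))
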
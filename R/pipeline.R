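#' Read a project roster from an XLSX workbook
#'
#' Supports deposited roster workbooks whose column names differ from the
#' package schema via an explicit mapping.
#'
#' @param path Path to the workbook.
#' @param sheet Sheet name or index (default 1).
#' @param mapping Named list mapping schema names (`project_id`,
#'   `platform_type`, `budget_musd`) to workbook column names.
#' @return Roster tibble.
#' @export
read_roster_xlsx <- function(path, sheet = 1,
                             mapping = list(project_id = "project_id",
                                            platform_type = "platform_type",
                                            budget_musd = "budget_musd")) {
  raw <- readxl::read_excel(path, sheet = sheet)
  missing <- setdiff(unlist(mapping), names(raw))
  if (length(missing)) {
    stop("workbook lacks column(s) ", paste(missing, collapse = ", "),
         "; expected mapping: ",
         paste(names(mapping), unlist(mapping), sep = " <- ",
               collapse = ", "), call. = FALSE)
  }
  budget <- suppressWarnings(as.numeric(raw[[mapping$budget_musd]]))
  if (anyNA(budget)) {
    stop("non-numeric budget value in row(s) ",
         paste(which(is.na(budget)), collapse = ", "), call. = FALSE)
  }
  roster <- tibble::tibble(project_id = as.character(raw[[mapping$project_id]]),
                           platform_type =
                             as.character(raw[[mapping$platform_type]]),
                           budget_musd = budget)
  validate_roster(roster)
  roster
}

#' Read a project roster from CSV
#' @param path CSV with columns `project_id`, `platform_type`, `budget_musd`.
#' @export
read_roster_csv <- function(path) {
  roster <- tibble::as_tibble(utils::read.csv(path,
                                              stringsAsFactors = FALSE))
  validate_roster(roster)
  roster
}

validate_roster <- function(roster) {
  need <- c("project_id", "platform_type", "budget_musd")
  missing <- setdiff(need, names(roster))
  if (length(missing)) stop("roster lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(roster$project_id)) stop("duplicate project ids",
                                             call. = FALSE)
  if (any(roster$budget_musd <= 0)) stop("budgets must be positive",
                                         call. = FALSE)
  invisible(roster)
}

#' Run the full portfolio decision analysis
#'
#' Executes the staged analysis end to end on synthetic elicitation data:
#' roster and reviewer-assessment generation, PoS Monte Carlo for both
#' assessment stages, preference coefficients (fitted from simulated DCE
#' choices, or the published fixture), portfolio valuation, optimization
#' (enumeration plus evolutionary cross-check), the efficiency frontier, and
#' the uncertainty/rank-probability analysis. Writes stage outputs as
#' CSV/JSON under `output_dir` along with a reproducibility manifest.
#'
#' @param config A [synthetic_config()]; its `seed` governs every stage.
#' @param budget Budget constraint, US$ million (default 140).
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param objective,q Passed to [optimization_spec()].
#' @param fit_dce If `FALSE`, skip DCE simulation/fitting and use
#'   [default_part_worths()].
#' @param output_dir Directory for outputs; `NULL` (default) writes nothing.
#' @param frontier_points Number of budget grid points for the frontier
#'   summary (subset-cost breakpoints are thinned to this count).
#' @return List of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = synthetic_config(), budget = 140,
                         n_iter = 10000L, objective = "quantile", q = 0.95,
                         fit_dce = TRUE, output_dir = NULL,
                         frontier_points = 25L) {
  stopifnot(inherits(config, "synthetic_config"))
  levels <- default_attribute_levels()
  roster <- generate_roster(config)
  assignment <- assign_reviewers(config, roster)
  assessments <- generate_assessments(config, assignment)
  pos_final <- simulate_project_pos(assessments, assignment, roster,
                                    n_iter = n_iter, seed = config$seed,
                                    stage = "final")
  pos_initial <- simulate_project_pos(assessments, assignment, roster,
                                      n_iter = n_iter, seed = config$seed,
                                      stage = "initial")
  if (fit_dce) {
    design <- build_design(levels, blocks = config$dce$blocks,
                           sets_per_block = config$dce$sets_per_block,
                           alts = config$dce$alternatives_per_set,
                           n_participants = config$dce$participants,
                           seed = config$seed)
    choices <- generate_choice_responses(config, design)
    pw <- fit_conditional_logit(choices, levels)
    validity <- validity_checks(choices, design)
  } else {
    design <- NULL; choices <- NULL; validity <- NULL
    pw <- default_part_worths()
  }
  pw_draws <- sample_part_worths(pw, n = n_iter, seed = config$seed)
  spec <- optimization_spec(budget = budget, objective = objective, q = q,
                            seed = config$seed)
  sol_enum <- enumerate_optimal(roster, pos_final, pw_draws, levels, spec)
  sol_ga <- evolve_optimal(roster, pos_final, pw_draws, levels, spec)
  breakpoints <- build_frontier_grid(roster, frontier_points)
  frontier <- build_frontier(roster, pos_final, pw_draws, levels,
                             budgets = breakpoints, spec = spec)
  comparator <- pos_to_cost_ranking(roster, pos_final, budget)
  alternatives <- enumerate_feasible(roster, budget)
  n_alternatives <- length(alternatives)
  # rank the optimum against genuine rivals, not against itself
  alternatives <- Filter(function(p) {
    !identical(p$selection, sol_enum$portfolio$selection)
  }, alternatives)
  report <- outranking_report(sol_enum$portfolio, alternatives, pos_final,
                              pw_draws, levels, roster)
  results <- list(config = config, roster = roster, assignment = assignment,
                  assessments = assessments,
                  pos = list(final = pos_final, initial = pos_initial),
                  design = design, choices = choices, part_worths = pw,
                  validity = validity, pw_draws = pw_draws,
                  optimal = sol_enum, evolved = sol_ga,
                  frontier = frontier, comparator = comparator,
                  n_alternatives = n_alternatives,
                  outranking = report)
  results$manifest <- build_manifest(config, budget, n_iter, objective, q,
                                     fit_dce, results)
  if (!is.null(output_dir)) write_pipeline_outputs(results, output_dir)
  results
}

build_frontier_grid <- function(roster, frontier_points) {
  lo <- min(roster$budget_musd)
  hi <- sum(roster$budget_musd)
  unique(round(seq(lo, hi, length.out = frontier_points), 1))
}

build_manifest <- function(config, budget, n_iter, objective, q, fit_dce,
                           results) {
  list(tool = "vaxpda",
       version = as.character(utils::packageVersion("vaxpda")),
       seed = config$seed,
       budget_musd = budget,
       n_iter = n_iter,
       objective = objective,
       q = q,
       part_worths_source = if (fit_dce) "fitted" else "published fixture",
       roster_hash = sum(results$roster$budget_musd),
       n_projects = nrow(results$roster),
       optimal_projects = results$optimal$portfolio$project_ids,
       optimal_objective = results$optimal$objective,
       n_alternatives = results$n_alternatives,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_pipeline_outputs <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(output_dir, name), row.names = FALSE)
  }
  wcsv(results$roster, "roster.csv")
  wcsv(results$assessments, "assessments.csv")
  pos_sum <- cbind(stage = "final",
                   summarize_draws(unclass(results$pos$final)))
  pos_sum_i <- cbind(stage = "initial",
                     summarize_draws(unclass(results$pos$initial)))
  names(pos_sum)[2] <- names(pos_sum_i)[2] <- "project_id"
  wcsv(rbind(pos_sum, pos_sum_i), "pos_summary.csv")
  wcsv(results$part_worths$coefficients, "part_worths.csv")
  front <- results$frontier
  front$project_ids <- vapply(front$project_ids, paste, character(1),
                              collapse = "+")
  wcsv(front, "frontier.csv")
  rank_tab <- results$outranking$table
  rank_tab$added <- vapply(rank_tab$added, paste, character(1),
                           collapse = "+")
  rank_tab$removed <- vapply(rank_tab$removed, paste, character(1),
                             collapse = "+")
  wcsv(rank_tab, "outranking.csv")
  jsonlite::write_json(results$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
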
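# Shared fixtures: tiny rosters and point-mass assessments built in code.

toy_roster <- function(budgets, platforms = NULL) {
  n <- length(budgets)
  if (is.null(platforms)) platforms <- rep("RNA", n)
  tibble::tibble(project_id = sprintf("T%02d", seq_len(n)),
                 platform_type = platforms,
                 budget_musd = budgets)
}

# one reviewer per project, all seven factor triples at a point mass
point_assessments <- function(roster, value, reviewer = "R01") {
  grid <- expand.grid(project_id = roster$project_id,
                      factor = pos_factors(),
                      stringsAsFactors = FALSE)
  v <- rep_len(value, nrow(roster))[match(grid$project_id, roster$project_id)]
  tibble::tibble(reviewer_id = reviewer, project_id = grid$project_id,
                 factor = grid$factor, worst = v, most_likely = v, best = v,
                 stage = "final")
}

point_assignment <- function(roster, reviewer = "R01") {
  a <- lapply(roster$project_id, function(p) reviewer)
  names(a) <- roster$project_id
  a
}

# pos_draws matrix with every draw fixed at `values` (per project)
constant_pos <- function(roster, values, n_iter = 50L) {
  m <- matrix(rep(values, each = n_iter), n_iter, nrow(roster),
              dimnames = list(NULL, roster$project_id))
  structure(m, class = c("pos_draws", "matrix", "array"),
            seed = NA_integer_, stage = "final")
}

# attribute levels restricted to the platforms present in a roster
levels_for <- function(roster) {
  lv <- default_attribute_levels()
  lv[lv$platform_type %in% unique(roster$platform_type), ]
}

# full default synthetic instance used across solver tests
synthetic_instance <- function(seed, n_iter = 500L) {
  cfg <- synthetic_config(seed = seed)
  roster <- generate_roster(cfg)
  assignment <- assign_reviewers(cfg, roster)
  assessments <- generate_assessments(cfg, assignment)
  pos <- simulate_project_pos(assessments, assignment, roster,
                              n_iter = n_iter, seed = seed)
  pw_draws <- sample_part_worths(default_part_worths(), n = n_iter,
                                 seed = seed)
  list(roster = roster, pos = pos, pw_draws = pw_draws,
       levels = default_attribute_levels())
}
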
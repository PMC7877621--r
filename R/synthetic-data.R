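#' PoS factor labels
#'
#' Seven consequentially independent factors (applicant competency, project
#' feasibility, clinical benefit, safety potential, manufacturing scalability
#' and speed, operational suitability, operational sustainability) whose
#' product defines a project's probability of success.
#' @export
pos_factors <- function() paste0("C", 1:7)

#' Default platform type names
#' @export
platform_types <- function() c("RNA", "ViralVector", "DNA", "Protein", "mAb")

#' Configuration for the synthetic elicitation study
#'
#' Defaults emulate the study conditions of the motivating funding call:
#' 16 preclinical platform projects across five platform technology types
#' (4 RNA, 4 viral vector, 3 DNA, 3 protein subunit, 2 gene-encoded mAb),
#' project budgets between US$6m and US$65m, a pool of 27 expert reviewers
#' with 4-5 reviewers per project and 3-4 projects per reviewer, and a
#' discrete choice experiment with 48 participants answering 2 blocks of
#' 16 choice sets of 3 portfolio alternatives.
#'
#' @param seed Master seed for all synthetic stages.
#' @param n_projects Number of projects.
#' @param platform_sizes Named integer vector of projects per platform type;
#'   must sum to `n_projects`.
#' @param budget_range Budget bounds in US$ million (uniform draw, rounded to
#'   0.1).
#' @param n_reviewers_pool Size of the reviewer pool.
#' @param reviewers_per_project Length-2 range of reviewers per project.
#' @param projects_per_reviewer Length-2 range of projects per reviewer (the
#'   upper bound is a hard cap; the lower bound is honoured for reviewers
#'   actually used, as far as the margins allow).
#' @param factor_prior Per-factor generator for (worst, most-likely, best)
#'   triples: a list with either `shape1`/`shape2` (Beta prior for the
#'   most-likely value) or a degenerate `mode`, plus `spread` (maximum
#'   half-width of the worst/best interval, uniform).
#' @param optimism_shift Scalar in `[0, 1)`; "final" assessments shrink all
#'   three triple points multiplicatively by `1 - optimism_shift`, emulating
#'   the downward revision of estimates after panel discussion.
#' @param dce List with `participants`, `blocks`, `sets_per_block`,
#'   `alternatives_per_set`, and `true_part_worths` (a part-worths object used
#'   as the data-generating truth; defaults to [default_part_worths()]).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_projects = 16L,
                             platform_sizes = c(RNA = 4L, ViralVector = 4L,
                                                DNA = 3L, Protein = 3L,
                                                mAb = 2L),
                             budget_range = c(6, 65),
                             n_reviewers_pool = 27L,
                             reviewers_per_project = c(4L, 5L),
                             projects_per_reviewer = c(3L, 4L),
                             factor_prior = list(shape1 = 6, shape2 = 2,
                                                 spread = 0.15),
                             optimism_shift = 0.2,
                             dce = list()) {
  if (sum(platform_sizes) != n_projects) {
    stop("`platform_sizes` must sum to `n_projects` (",
         sum(platform_sizes), " != ", n_projects, ")", call. = FALSE)
  }
  if (budget_range[1] <= 0 || budget_range[2] < budget_range[1]) {
    stop("`budget_range` must be positive and non-decreasing", call. = FALSE)
  }
  stopifnot(n_reviewers_pool >= 1,
            length(reviewers_per_project) == 2,
            length(projects_per_reviewer) == 2,
            optimism_shift >= 0, optimism_shift < 1)
  dce_defaults <- list(participants = 48L, blocks = 2L, sets_per_block = 16L,
                       alternatives_per_set = 3L,
                       true_part_worths = default_part_worths())
  dce <- utils::modifyList(dce_defaults, dce)
  structure(list(seed = as.integer(seed),
                 n_projects = as.integer(n_projects),
                 platform_sizes = platform_sizes,
                 budget_range = budget_range,
                 n_reviewers_pool = as.integer(n_reviewers_pool),
                 reviewers_per_project = as.integer(reviewers_per_project),
                 projects_per_reviewer = as.integer(projects_per_reviewer),
                 factor_prior = factor_prior,
                 optimism_shift = optimism_shift,
                 dce = dce),
            class = "synthetic_config")
}

#' Generate a synthetic project roster
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `project_id`, `platform_type`, `budget_musd`; platform
#'   group sizes follow `config$platform_sizes` and budgets are uniform on
#'   `config$budget_range`, rounded to US$0.1m.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, "roster"), {
    n <- config$n_projects
    platform <- rep(names(config$platform_sizes), config$platform_sizes)
    budget <- round(stats::runif(n, config$budget_range[1],
                                 config$budget_range[2]), 1)
    tibble::tibble(project_id = sprintf("P%02d", seq_len(n)),
                   platform_type = platform,
                   budget_musd = budget)
  })
}

#' Assign reviewers to projects
#'
#' Randomized, load-balanced greedy assignment: each project receives a number
#' of reviewers drawn from `reviewers_per_project`, chosen among the
#' least-loaded pool members with spare capacity (ties broken at random), so
#' per-reviewer loads stay within `projects_per_reviewer` caps and as uniform
#' as the margins allow.
#'
#' @param config A [synthetic_config()].
#' @param roster Roster tibble from [generate_roster()].
#' @return Named list: `project_id` -> character vector of reviewer ids.
#' @export
assign_reviewers <- function(config, roster) {
  stopifnot(inherits(config, "synthetic_config"))
  n_proj <- nrow(roster)
  rp <- config$reviewers_per_project
  pr <- config$projects_per_reviewer
  pool_n <- config$n_reviewers_pool
  if (rp[1] > pool_n) {
    stop("infeasible assignment: per-project minimum of ", rp[1],
         " reviewers exceeds pool size ", pool_n, call. = FALSE)
  }
  if (n_proj * rp[1] > pool_n * pr[2]) {
    stop("infeasible assignment: projects require at least ", n_proj * rp[1],
         " reviewer slots but the pool supplies at most ", pool_n * pr[2],
         " (per-reviewer cap)", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "assignment"), {
    pool <- sprintf("R%02d", seq_len(pool_n))
    load <- stats::setNames(integer(pool_n), pool)
    out <- vector("list", n_proj)
    names(out) <- roster$project_id
    for (p in sample(seq_len(n_proj))) {
      k <- if (rp[1] == rp[2]) rp[1] else sample(seq(rp[1], rp[2]), 1)
      open <- pool[load < pr[2]]
      if (length(open) < rp[1]) {
        stop("infeasible assignment: per-reviewer cap exhausted while ",
             "projects still need reviewers", call. = FALSE)
      }
      k <- min(k, length(open))
      # fill least-loaded reviewers first; random order within equal loads
      open <- open[order(load[open], stats::runif(length(open)))]
      chosen <- open[seq_len(k)]
      load[chosen] <- load[chosen] + 1L
      out[[roster$project_id[p]]] <- sort(chosen)
    }
    out
  })
}

#' Generate three-point factor assessments
#'
#' For every reviewer x assigned project x factor, draws a (worst,
#' most-likely, best) triple in `[0,1]` with `worst <= most_likely <= best`.
#' The most-likely value comes from the configured factor prior (Beta by
#' default); worst/best are symmetric uniform half-widths around it, clipped
#' to `[0,1]`. Two stages are emitted: `initial`, and `final` with all three
#' points shrunk multiplicatively by `1 - optimism_shift` (the downward
#' revision observed after face-to-face panel review).
#'
#' @param config A [synthetic_config()].
#' @param assignment Assignment map from [assign_reviewers()].
#' @return Long tibble: `reviewer_id`, `project_id`, `factor`, `worst`,
#'   `most_likely`, `best`, `stage`.
#' @export
generate_assessments <- function(config, assignment) {
  stopifnot(inherits(config, "synthetic_config"))
  prior <- config$factor_prior
  with_seed(derive_seed(config$seed, "assessments"), {
    rows <- lapply(names(assignment), function(pid) {
      revs <- assignment[[pid]]
      expand.grid(reviewer_id = revs, project_id = pid,
                  factor = pos_factors(), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    n <- nrow(tab)
    mode <- if (!is.null(prior$mode)) {
      rep_len(prior$mode, n)
    } else {
      stats::rbeta(n, prior$shape1, prior$shape2)
    }
    spread <- if (is.null(prior$spread)) 0.15 else prior$spread
    worst <- pmax(0, mode - stats::runif(n, 0, spread))
    best <- pmin(1, mode + stats::runif(n, 0, spread))
    initial <- tibble::tibble(reviewer_id = tab$reviewer_id,
                              project_id = tab$project_id,
                              factor = tab$factor,
                              worst = worst, most_likely = mode, best = best,
                              stage = "initial")
    shrink <- 1 - config$optimism_shift
    final <- initial
    final$worst <- final$worst * shrink
    final$most_likely <- final$most_likely * shrink
    final$best <- final$best * shrink
    final$stage <- "final"
    out <- rbind(initial, final)
    out[order(out$stage, out$project_id, out$reviewer_id, out$factor), ]
  })
}

#' Simulate choice responses from a conditional logit
#'
#' Given a choice design and true part-worths, each participant chooses one
#' alternative per choice set with probability proportional to `exp(U_j)`,
#' where `U_j` sums the cumulative-coded part-worths of the alternative's
#' POS>=1 levels. Participants are split evenly across design blocks.
#'
#' @param config A [synthetic_config()] (supplies seed and participant count).
#' @param design A choice design from [build_design()].
#' @param truth Part-worths object acting as the data-generating truth.
#' @return Tibble: `participant_id`, `block`, `set_id`, `alternative_id`, one
#'   level column per platform type, `chosen` (0/1; exactly one per
#'   participant x set).
#' @export
generate_choice_responses <- function(config, design, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(design, "choice_design"))
  if (is.null(truth)) truth <- config$dce$true_part_worths
  stopifnot(inherits(truth, "part_worths"))
  missing <- setdiff(design$platforms, truth$coefficients$platform_type)
  if (length(missing)) {
    stop("truth part-worths missing platform(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- design$sets
  util <- alternative_utilities(sets, truth, design$levels)
  n_part <- config$dce$participants
  with_seed(derive_seed(config$seed, "choices"), {
    blocks <- sort(unique(sets$block))
    part_block <- rep_len(blocks, n_part)
    res <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      sub <- sets[sets$block == b, , drop = FALSE]
      u <- util[sets$block == b]
      pb <- which(part_block == b)
      chosen <- matrix(0L, nrow(sub), length(pb))
      for (s in unique(sub$set_id)) {
        idx <- which(sub$set_id == s)
        pr <- exp(u[idx] - max(u[idx]))
        picks <- sample.int(length(idx), length(pb), replace = TRUE,
                            prob = pr / sum(pr))
        chosen[cbind(idx[picks], seq_along(pb))] <- 1L
      }
      rep_idx <- rep(seq_len(nrow(sub)), times = length(pb))
      res[[bi]] <- tibble::tibble(
        participant_id = rep(sprintf("S%04d", pb), each = nrow(sub)),
        block = sub$block[rep_idx], set_id = sub$set_id[rep_idx],
        alternative_id = sub$alternative_id[rep_idx],
        sub[rep_idx, design$platforms, drop = FALSE],
        chosen = as.vector(chosen))
    }
    out <- do.call(rbind, res)
    out[order(out$participant_id), ]
  })
}

# Utility of each design row under cumulative (level-threshold) coding.
alternative_utilities <- function(sets, pw, levels) {
  co <- pw$coefficients
  u <- numeric(nrow(sets))
  for (k in co$platform_type) {
    lv <- levels[levels$platform_type == k, ]
    x <- sets[[k]]
    bb <- co$beta_b[co$platform_type == k]
    bc <- co$beta_c[co$platform_type == k]
    u <- u + bb * (x >= lv$b - 1e-9) + bc * (x >= lv$c - 1e-9)
  }
  u
}
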
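#' Value-to-budget efficiency frontier
#'
#' Solves the selection problem at each budget on a grid, under one fixed set
#' of Monte Carlo draws (common random numbers), so frontier differences
#' reflect the budget alone. With enumeration active, all subsets are scored
#' once and each grid point is an argmax over the feasible prefix, so the
#' exact frontier costs little more than a single optimization.
#'
#' @param roster,pos,pw_draws,levels Analysis inputs.
#' @param budgets Increasing budget grid (US$ million); defaults to every
#'   distinct subset-cost breakpoint between the cheapest project and the
#'   total roster cost (exact frontier) when the roster permits enumeration.
#' @param spec An [optimization_spec()]; its `budget` field is ignored in
#'   favour of the grid.
#' @return Tibble: `budget`, `cost`, `objective`, `mean`, `ci_low`,
#'   `ci_high`, `project_ids` (list column), plus attribute `solutions`.
#' @export
build_frontier <- function(roster, pos, pw_draws, levels, budgets = NULL,
                           spec = optimization_spec()) {
  n <- nrow(roster)
  if (n > 24) stop("frontier enumeration limited to 24 projects",
                   call. = FALSE)
  ev <- value_evaluator(pos, pw_draws, levels, roster)
  masks <- 0:(2^n - 1)
  cost <- numeric(length(masks))
  for (j in seq_len(n)) {
    cost <- cost + roster$budget_musd[j] * (bitwAnd(masks, 2^(j - 1)) > 0)
  }
  if (is.null(budgets)) {
    budgets <- sort(unique(round(cost[cost > 0], 6)))
  }
  if (!length(budgets)) stop("empty budget grid", call. = FALSE)
  if (is.unsorted(budgets, strictly = TRUE)) {
    stop("budget grid must be strictly increasing", call. = FALSE)
  }
  obj <- evaluate_masks(masks, ev, roster, spec)
  rows <- vector("list", length(budgets))
  sols <- vector("list", length(budgets))
  for (i in seq_along(budgets)) {
    feas <- which(cost <= budgets[i] + 1e-9)
    best <- feas[select_best(masks[feas], obj[feas], cost[feas], n)]
    sel <- mask_to_selection(masks[best], n)
    pf <- portfolio(sel, roster)
    v <- ev(sel)
    s <- value_summary(v)
    sols[[i]] <- new_solution(pf, obj[best], v,
                              trace = list(solver = "enumerate",
                                           budget = budgets[i]))
    rows[[i]] <- tibble::tibble(budget = budgets[i], cost = pf$cost,
                                objective = obj[best], mean = s$mean,
                                ci_low = s$ci[1], ci_high = s$ci[2],
                                project_ids = list(pf$project_ids))
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  out
}

#' Greedy PoS-to-cost ranking comparator
#'
#' The naive benchmark the frontier is compared against: rank projects by
#' mean PoS divided by budget (descending) and add them greedily, skipping
#' any project that would break the budget and continuing down the list.
#'
#' @param roster Roster tibble.
#' @param pos `pos_draws` matrix (means taken per project).
#' @param budget Budget, US$ million.
#' @return A [portfolio()] labelled `"PoS-to-cost ranking"`.
#' @export
pos_to_cost_ranking <- function(roster, pos, budget) {
  mean_pos <- colMeans(pos)
  ratio <- mean_pos / roster$budget_musd
  ord <- order(ratio, decreasing = TRUE)
  sel <- rep(FALSE, nrow(roster))
  spent <- 0
  for (j in ord) {
    if (spent + roster$budget_musd[j] <= budget + 1e-9) {
      sel[j] <- TRUE
      spent <- spent + roster$budget_musd[j]
    }
  }
  portfolio(sel, roster, label = "PoS-to-cost ranking")
}

#' Cumulative value curve of a single platform type
#'
#' For each subset size `m = 1..s_k` of platform `k`'s projects, finds the
#' best `m`-subset by mean portfolio value (other platforms excluded) and
#' reports its mean POS>=1 and mean value -- the per-platform diminishing
#' returns view: increments shrink once POS>=1 passes the middle preference
#' level when the upper part-worth is smaller.
#'
#' @param roster,pos,pw_draws,levels Analysis inputs.
#' @param platform Platform type name.
#' @return Tibble: `n_projects`, `project_ids` (list), `pos_geq1_mean`,
#'   `value_mean`.
#' @export
platform_value_curve <- function(roster, pos, pw_draws, levels, platform) {
  members <- which(roster$platform_type == platform)
  if (!length(members)) stop("unknown or empty platform: ", platform,
                             call. = FALSE)
  ev <- value_evaluator(pos, pw_draws, levels, roster)
  rows <- lapply(seq_along(members), function(m) {
    combs <- utils::combn(members, m)
    best_val <- -Inf; best_sel <- NULL
    for (ci in seq_len(ncol(combs))) {
      sel <- rep(FALSE, nrow(roster))
      sel[combs[, ci]] <- TRUE
      val <- mean(ev(sel))
      if (val > best_val) { best_val <- val; best_sel <- sel }
    }
    ps <- platform_success_draws(pos, roster, best_sel)
    tibble::tibble(n_projects = m,
                   project_ids = list(roster$project_id[best_sel]),
                   pos_geq1_mean = mean(ps[, platform]),
                   value_mean = best_val)
  })
  do.call(rbind, rows)
}
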
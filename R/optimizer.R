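#' Specification of the portfolio selection problem
#'
#' The selection problem maximizes a statistic of the simulated portfolio
#' value distribution subject to a budget constraint on the sum of selected
#' project budgets. The default objective is the chance-constrained one: the
#' empirical 95th-percentile (VaR-style) of the value draws; the
#' expected-value objective is retained for comparison runs, and levels
#' 0.50-0.90 are available through `q`.
#'
#' @param budget Budget constraint, US$ million (default 140).
#' @param objective `"quantile"` (default) or `"expected"`.
#' @param q Quantile level for the chance-constrained objective (default
#'   0.95).
#' @param seed Seed used by the evolutionary solver.
#' @param ga List of evolutionary-algorithm settings: `population`,
#'   `generations`, `crossover`, `mutation` (per-bit; default `1.5/n`),
#'   `tournament`, `patience` (stop after this many stale generations), and
#'   `stall_reset` (re-randomize the non-elite population after this many
#'   stale generations, reintroducing diversity).
#' @return An `optimization_spec` list.
#' @export
optimization_spec <- function(budget = 140, objective = c("quantile",
                                                          "expected"),
                              q = 0.95, seed = 1L, ga = list()) {
  objective <- match.arg(objective)
  if (budget <= 0) stop("budget must be positive", call. = FALSE)
  if (q <= 0 || q >= 1) stop("quantile level q must lie in (0, 1)",
                             call. = FALSE)
  ga_defaults <- list(population = 100L, generations = 250L, crossover = 0.9,
                      mutation = NULL, tournament = 3L, patience = 80L,
                      stall_reset = 20L)
  ga <- utils::modifyList(ga_defaults, ga)
  structure(list(budget = budget, objective = objective, q = q,
                 seed = as.integer(seed), ga = ga),
            class = "optimization_spec")
}

#' Objective statistic of value draws
#'
#' @param v Value draws.
#' @param spec An [optimization_spec()].
#' @return Mean of the draws (`"expected"`) or their inverted-CDF type-1
#'   `q`-quantile (`"quantile"`).
#' @export
objective_value <- function(v, spec) {
  if (spec$objective == "expected") mean(v) else quantile_type1(v, spec$q)
}

#' Cached portfolio-value evaluator under common random numbers
#'
#' Portfolio value separates across platform types: the value draw vector of
#' any portfolio is the sum over platforms of that platform's contribution
#' vector, which depends only on which of the platform's own members are
#' selected. With at most a handful of projects per platform, all per-platform
#' member-subset contribution vectors are precomputed once, making every
#' subsequent portfolio evaluation a few vector additions on identical draws.
#'
#' @param pos `pos_draws` matrix.
#' @param pw_draws `part_worth_draws` aligned with `pos`.
#' @param levels Attribute-level tibble.
#' @param roster Roster tibble.
#' @return A function `(selection) -> value draws` with attribute
#'   `platform_info` (member indices per platform) for internal reuse.
#' @export
value_evaluator <- function(pos, pw_draws, levels, roster) {
  n_iter <- nrow(pos)
  if (pw_draws$n == 1L && n_iter > 1L) {
    pw_draws <- list(beta_b = pw_draws$beta_b[rep(1, n_iter), , drop = FALSE],
                     beta_c = pw_draws$beta_c[rep(1, n_iter), , drop = FALSE],
                     platforms = pw_draws$platforms, n = n_iter)
  } else if (pw_draws$n != n_iter) {
    stop("iteration mismatch between pos draws (", n_iter,
         ") and part-worth draws (", pw_draws$n, ")", call. = FALSE)
  }
  platforms <- unique(roster$platform_type)
  info <- lapply(platforms, function(k) which(roster$platform_type == k))
  names(info) <- platforms
  contrib <- lapply(platforms, function(k) {
    members <- info[[k]]
    s <- length(members)
    lv <- levels[levels$platform_type == k, ]
    if (!nrow(lv)) stop("no attribute levels for platform ", k, call. = FALSE)
    lvk <- c(lv$a, lv$b, lv$c)
    bb <- pw_draws$beta_b[, k]; bc <- pw_draws$beta_c[, k]
    mat <- matrix(0, n_iter, 2^s)
    fail_cache <- vector("list", 2^s)
    fail_cache[[1]] <- rep(1, n_iter)
    for (m in seq_len(2^s - 1)) {
      lowbit <- bitwAnd(m, -m)
      prev <- bitwXor(m, lowbit)
      j <- members[1L + as.integer(round(log2(lowbit)))]
      fail_cache[[m + 1]] <- fail_cache[[prev + 1]] * (1 - pos[, j])
      mat[, m + 1] <- preference_value(bb, bc, lvk, 1 - fail_cache[[m + 1]])
    }
    mat
  })
  names(contrib) <- platforms
  f <- function(selection) {
    selection <- as.logical(selection)
    v <- numeric(n_iter)
    for (k in platforms) {
      members <- info[[k]]
      m <- sum(2^(seq_along(members) - 1) * selection[members])
      v <- v + contrib[[k]][, m + 1]
    }
    v
  }
  attr(f, "platform_info") <- info
  attr(f, "contrib") <- contrib
  attr(f, "n_iter") <- n_iter
  f
}

#' Exhaustive enumeration of the optimal portfolio
#'
#' Evaluates every budget-feasible subset of the roster under common random
#' numbers and returns the argmax of the objective. Ties are broken by lower
#' cost, then by the lexicographically smallest selection vector, making the
#' result fully deterministic.
#'
#' @param roster Roster tibble (at most 24 projects).
#' @param pos,pw_draws,levels Inputs to [value_evaluator()].
#' @param spec An [optimization_spec()].
#' @return A `solution` list: `portfolio`, `objective`, `summary`, `trace`
#'   (`n_feasible`, `n_subsets`).
#' @export
enumerate_optimal <- function(roster, pos, pw_draws, levels, spec) {
  n <- nrow(roster)
  if (n > 24) {
    stop("roster of ", n, " projects exceeds the 2^24 enumeration guard; ",
         "use evolve_optimal()", call. = FALSE)
  }
  ev <- value_evaluator(pos, pw_draws, levels, roster)
  masks <- 0:(2^n - 1)
  cost <- numeric(length(masks))
  for (j in seq_len(n)) {
    cost <- cost + roster$budget_musd[j] * (bitwAnd(masks, 2^(j - 1)) > 0)
  }
  feas <- which(cost <= spec$budget + 1e-9)
  obj <- evaluate_masks(masks[feas], ev, roster, spec)
  best <- feas[select_best(masks[feas], obj, cost[feas], n)]
  sel <- mask_to_selection(masks[best], n)
  pf <- portfolio(sel, roster, label = "enumerated optimum")
  v <- ev(sel)
  new_solution(pf, objective_value(v, spec), v,
               trace = list(solver = "enumerate",
                            n_feasible = length(feas),
                            n_subsets = length(masks)))
}

# Objective for a vector of subset masks, using the platform decomposition.
evaluate_masks <- function(masks, ev, roster, spec) {
  info <- attr(ev, "platform_info")
  contrib <- attr(ev, "contrib")
  n_iter <- attr(ev, "n_iter")
  sub <- lapply(info, function(members) {
    s <- 0
    for (m in seq_along(members)) {
      s <- s + 2^(m - 1) * (bitwAnd(masks, 2^(members[m] - 1)) > 0)
    }
    s + 1  # column index
  })
  if (spec$objective == "expected") {
    means <- lapply(contrib, colMeans)
    obj <- numeric(length(masks))
    for (k in names(info)) obj <- obj + means[[k]][sub[[k]]]
    return(obj)
  }
  jq <- max(1L, as.integer(ceiling(n_iter * spec$q)))
  obj <- numeric(length(masks))
  ks <- names(info)
  for (i in seq_along(masks)) {
    v <- contrib[[ks[1]]][, sub[[ks[1]]][i]]
    for (k in ks[-1]) v <- v + contrib[[k]][, sub[[k]][i]]
    obj[i] <- sort(v, partial = jq)[jq]
  }
  obj
}

select_best <- function(masks, obj, cost, n) {
  top <- which(obj >= max(obj) - 1e-12)
  if (length(top) > 1L) top <- top[order(cost[top])]
  top <- top[cost[top] <= min(cost[top]) + 1e-9]
  if (length(top) > 1L) {
    # lexicographically smallest selection vector: project 1 most significant
    key <- vapply(masks[top], function(m) {
      sum(mask_to_selection(m, n) * 2^(n - seq_len(n)))
    }, numeric(1))
    top <- top[order(key)]
  }
  top[1]
}

mask_to_selection <- function(mask, n) {
  (bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
}

new_solution <- function(pf, objective, v, trace) {
  structure(list(portfolio = pf, objective = objective,
                 summary = value_summary(v), trace = trace),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf("Solution (%s): objective %.4f | mean %.4f [%.4f, %.4f]\n",
              x$trace$solver, x$objective, x$summary$mean,
              x$summary$ci[1], x$summary$ci[2]))
  print(x$portfolio)
  invisible(x)
}

#' Evolutionary search for the optimal portfolio
#'
#' Binary-chromosome genetic algorithm over project selections: tournament
#' selection, uniform crossover, independent per-bit mutation, elitism of one,
#' and a death penalty (objective `-Inf`) for budget-infeasible chromosomes.
#' Portfolio evaluations are memoised, and all chromosomes are scored on the
#' same Monte Carlo draws (common random numbers), so the search is
#' deterministic given the seed. Stops after `generations` or after
#' `patience` generations without improvement.
#'
#' @inheritParams enumerate_optimal
#' @return A `solution`; `trace` records evaluations and the generation of
#'   convergence. If no feasible chromosome is ever seen (budget below the
#'   cheapest project and the empty set never generated), the empty portfolio
#'   is returned with a warning.
#' @export
evolve_optimal <- function(roster, pos, pw_draws, levels, spec) {
  n <- nrow(roster)
  ev <- value_evaluator(pos, pw_draws, levels, roster)
  ga <- spec$ga
  mut <- ga$mutation %||% (1.5 / n)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(sel) {
    key <- paste(as.integer(sel), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    val <- if (sum(roster$budget_musd[sel]) > spec$budget + 1e-9) -Inf
           else objective_value(ev(sel), spec)
    cache[[key]] <- val
    val
  }
  with_seed(derive_seed(spec$seed, "ga"), {
    popn <- ga$population
    pop <- lapply(seq_len(popn), function(i) stats::runif(n) < 0.5)
    pop[[1]] <- rep(FALSE, n)  # empty portfolio: always feasible anchor
    fit <- vapply(pop, score, numeric(1))
    best_i <- which.max(fit)
    best <- pop[[best_i]]; best_fit <- fit[best_i]
    best_gen <- 0L; stale <- 0L
    for (gen in seq_len(ga$generations)) {
      newpop <- vector("list", popn)
      newpop[[1]] <- best  # elitism
      for (i in seq_len(popn - 1L) + 1L) {
        p1 <- tournament_pick(fit, ga$tournament)
        p2 <- tournament_pick(fit, ga$tournament)
        child <- if (stats::runif(1) < ga$crossover) {
          mask <- stats::runif(n) < 0.5
          ifelse(mask, pop[[p1]], pop[[p2]])
        } else pop[[p1]]
        flip <- stats::runif(n) < mut
        child[flip] <- !child[flip]
        newpop[[i]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, score, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]; best <- pop[[gi]]; best_gen <- gen; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= ga$patience) break
        # diversity reintroduction against premature convergence: on a long
        # stall, re-randomize everything but the elite and continue
        if (stale %% ga$stall_reset == 0L) {
          pop <- lapply(seq_len(popn), function(i) stats::runif(n) < 0.5)
          pop[[1]] <- best
          fit <- vapply(pop, score, numeric(1))
        }
      }
    }
    if (!is.finite(best_fit)) {
      warning("no feasible portfolio found; returning the empty portfolio")
      best <- rep(FALSE, n)
      best_fit <- objective_value(ev(best), spec)
    }
    pf <- portfolio(best, roster, label = "GA optimum")
    v <- ev(best)
    new_solution(pf, best_fit, v,
                 trace = list(solver = "evolve", evaluations = n_eval,
                              converged_generation = best_gen))
  })
}

tournament_pick <- function(fit, k) {
  idx <- sample.int(length(fit), min(k, length(fit)))
  idx[which.max(fit[idx])]
}
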
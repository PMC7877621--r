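#' Enumerate budget-feasible portfolio alternatives
#'
#' All non-empty project subsets whose cost satisfies the budget constraint
#' (`<=` by default; `strict = TRUE` for a strict `<` reading of "under" the
#' budget), sorted by cost. Exact enumeration of alternatives, in place of
#' perturbed-budget re-optimization sweeps.
#'
#' @param roster Roster tibble (at most 24 projects).
#' @param budget Budget, US$ million.
#' @param strict Use strict inequality.
#' @return List of [portfolio()] objects sorted by increasing cost.
#' @export
enumerate_feasible <- function(roster, budget, strict = FALSE) {
  n <- nrow(roster)
  if (n > 24) stop("feasible-set enumeration limited to 24 projects",
                   call. = FALSE)
  masks <- 1:(2^n - 1)
  cost <- numeric(length(masks))
  for (j in seq_len(n)) {
    cost <- cost + roster$budget_musd[j] * (bitwAnd(masks, 2^(j - 1)) > 0)
  }
  keep <- if (strict) cost < budget - 1e-9 else cost <= budget + 1e-9
  masks <- masks[keep]; cost <- cost[keep]
  ord <- order(cost)
  lapply(ord, function(i) portfolio(mask_to_selection(masks[i], n), roster))
}

#' Dispersion and Gini statistics of a value distribution
#'
#' Mean-risk summaries used for stochastic dominance screening: variance
#' (population form), below-mean semivariance `E[min(0, X - mu)^2]`, standard
#' deviation, mean absolute deviation `E|X - mu|`, the Gini mean difference
#' `Gamma = E|X - X'| / 2` (computed by the rank-covariance identity
#' `Gamma = 2 cov(X, F(X))` with the empirical CDF, O(n log n)), and the
#' mean-Gini criterion `mu - Gamma`.
#'
#' @param v Value draws.
#' @return Tibble with `mean`, `variance`, `semivariance`, `sd`, `mad`,
#'   `gini`, `mean_minus_gini`.
#' @export
dominance_stats <- function(v) {
  if (!length(v)) stop("empty draws", call. = FALSE)
  n <- length(v)
  mu <- mean(v)
  dev <- v - mu
  variance <- mean(dev^2)
  tibble::tibble(
    mean = mu,
    variance = variance,
    semivariance = mean(pmin(0, dev)^2),
    sd = sqrt(variance),
    mad = mean(abs(dev)),
    gini = gini_mean_difference(v) / 2,
    mean_minus_gini = mu - gini_mean_difference(v) / 2
  )
}

#' Gini mean difference `E|X - X'|`
#'
#' Rank-based identity: with average ranks `r_i`,
#' `E|X - X'| = (2 / n^2) * sum_i (2 r_i - n - 1) x_i`, equal to the naive
#' double-loop average over all ordered pairs (ties included).
#'
#' @param x Numeric draws.
#' @export
gini_mean_difference <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  2 * sum((2 * r - n - 1) * x) / n^2
}

#' Mean-risk stochastic dominance relation
#'
#' `a` dominates `b` iff `mean_a >= mean_b` and `risk_a <= risk_b`, with at
#' least one inequality strict, for the chosen risk measure.
#'
#' @param a,b Rows from [dominance_stats()].
#' @param risk One of `"variance"`, `"semivariance"`, `"sd"`, `"mad"`.
#' @return `"dominates"`, `"dominated"`, or `"non-comparable"`.
#' @export
mv_dominates <- function(a, b, risk = c("variance", "semivariance", "sd",
                                        "mad")) {
  risk <- match.arg(risk)
  mean_risk_relation(a$mean, a[[risk]], b$mean, b[[risk]])
}

#' Mean-Gini stochastic dominance relation
#'
#' `a` dominates `b` iff `mean_a >= mean_b` and
#' `mean_a - Gamma_a >= mean_b - Gamma_b`, at least one strict; the
#' necessary condition for second-order dominance under risk aversion.
#'
#' @param a,b Rows from [dominance_stats()].
#' @return `"dominates"`, `"dominated"`, or `"non-comparable"`.
#' @export
mean_gini_dominates <- function(a, b) {
  rel_fwd <- (a$mean >= b$mean) && (a$mean_minus_gini >= b$mean_minus_gini) &&
    ((a$mean > b$mean) || (a$mean_minus_gini > b$mean_minus_gini))
  rel_bwd <- (b$mean >= a$mean) && (b$mean_minus_gini >= a$mean_minus_gini) &&
    ((b$mean > a$mean) || (b$mean_minus_gini > a$mean_minus_gini))
  if (rel_fwd) "dominates" else if (rel_bwd) "dominated" else "non-comparable"
}

mean_risk_relation <- function(mu_a, risk_a, mu_b, risk_b) {
  fwd <- (mu_a >= mu_b) && (risk_a <= risk_b) &&
    ((mu_a > mu_b) || (risk_a < risk_b))
  bwd <- (mu_b >= mu_a) && (risk_b <= risk_a) &&
    ((mu_b > mu_a) || (risk_b < risk_a))
  if (fwd) "dominates" else if (bwd) "dominated" else "non-comparable"
}

#' Pairwise rank probability of two portfolios
#'
#' The fraction of Monte Carlo iterations in which the reference portfolio's
#' value exceeds the alternative's, ties counted as half-wins, both evaluated
#' on the same draws (common random numbers). By construction
#' `rank_probability(a, b) + rank_probability(b, a) = 1`.
#'
#' @param reference,alternative [portfolio()] objects.
#' @param pos,pw_draws,levels,roster Analysis inputs.
#' @param evaluator Optional prebuilt [value_evaluator()] to reuse.
#' @return Probability in `[0, 1]`.
#' @export
rank_probability <- function(reference, alternative, pos, pw_draws, levels,
                             roster, evaluator = NULL) {
  ev <- evaluator %||% value_evaluator(pos, pw_draws, levels, roster)
  va <- ev(reference$selection)
  vb <- ev(alternative$selection)
  mean((va > vb) + 0.5 * (va == vb))
}

#' Outranking report of a reference portfolio against alternatives
#'
#' For each alternative, the probability that the reference outranks it by
#' value across iterations; a banded summary over configurable probability
#' bands; and, per band, the inclusion frequency of every project among the
#' alternatives in that band together with the composition difference from
#' the reference.
#'
#' @param reference A [portfolio()] (typically the enumerated optimum).
#' @param alternatives List of portfolios ([enumerate_feasible()]).
#' @param pos,pw_draws,levels,roster Analysis inputs.
#' @param bands Increasing probability band edges; defaults to
#'   `c(0.5, 0.75, 0.9, 1)` giving bands (0.5, 0.75], (0.75, 0.9], (0.9, 1].
#' @return List: `table` (tibble with `alternative`, `cost`, `probability`,
#'   `band`, `added`, `removed`), `band_inclusion` (per band x project
#'   inclusion frequency), `min_probability`, `second_best` (highest-
#'   probability... i.e. the closest rival and its probability).
#' @export
outranking_report <- function(reference, alternatives, pos, pw_draws, levels,
                              roster, bands = c(0.5, 0.75, 0.9, 1)) {
  if (!length(alternatives)) stop("no alternatives supplied", call. = FALSE)
  ev <- value_evaluator(pos, pw_draws, levels, roster)
  vref <- ev(reference$selection)
  prob <- vapply(alternatives, function(p) {
    vb <- ev(p$selection)
    mean((vref > vb) + 0.5 * (vref == vb))
  }, numeric(1))
  lab <- vapply(alternatives, function(p) p$label, character(1))
  cost <- vapply(alternatives, function(p) p$cost, numeric(1))
  band <- cut(prob, breaks = c(-Inf, bands), include.lowest = TRUE,
              labels = c(paste0("<=", bands[1]),
                         paste0("(", utils::head(bands, -1), ",",
                                bands[-1], "]")))
  added <- lapply(alternatives, function(p)
    setdiff(p$project_ids, reference$project_ids))
  removed <- lapply(alternatives, function(p)
    setdiff(reference$project_ids, p$project_ids))
  tab <- tibble::tibble(alternative = lab, cost = cost, probability = prob,
                        band = as.character(band), added = added,
                        removed = removed)
  incl <- lapply(split(seq_along(alternatives), tab$band), function(idx) {
    sel <- vapply(alternatives[idx], function(p) p$selection,
                  logical(nrow(roster)))
    tibble::tibble(project_id = roster$project_id,
                   inclusion_rate = rowMeans(matrix(sel, nrow(roster))))
  })
  rival <- which.min(prob)  # the alternative hardest to outrank
  list(table = tab,
       band_inclusion = incl,
       min_probability = min(prob),
       closest_rival = list(alternative = lab[rival],
                            probability = prob[rival]))
}
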
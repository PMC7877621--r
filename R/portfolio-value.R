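#' Construct a portfolio
#'
#' @param selection Logical or 0/1 vector over roster rows.
#' @param roster Roster tibble.
#' @param label Optional label.
#' @return A `portfolio` list: `selection` (logical), `project_ids`, `cost`
#'   (US$ million), `label`.
#' @export
portfolio <- function(selection, roster, label = NULL) {
  selection <- as.logical(selection)
  stopifnot(length(selection) == nrow(roster), !anyNA(selection))
  structure(list(selection = selection,
                 project_ids = roster$project_id[selection],
                 cost = sum(roster$budget_musd[selection]),
                 label = label %||% paste(roster$project_id[selection],
                                          collapse = "+")),
            class = "portfolio")
}

#' Portfolio from project ids
#' @param ids Character project ids.
#' @param roster Roster tibble.
#' @param label Optional label.
#' @export
portfolio_from_ids <- function(ids, roster, label = NULL) {
  bad <- setdiff(ids, roster$project_id)
  if (length(bad)) stop("unknown project id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  portfolio(roster$project_id %in% ids, roster, label = label)
}

#' @export
print.portfolio <- function(x, ...) {
  cat("Portfolio", if (!is.null(x$label)) paste0("'", x$label, "'"), ":",
      if (length(x$project_ids)) paste(x$project_ids, collapse = ", ")
      else "(empty)",
      sprintf("| cost US$%.1fm\n", x$cost))
  invisible(x)
}

#' Monte Carlo draws of portfolio value
#'
#' Composes the stochastic portfolio value iteration-by-iteration under
#' common random numbers: per iteration, the platform-level POS>=1 is formed
#' from the selected members' PoS draws, the piecewise preference weight is
#' evaluated at that realized POS>=1 using the same iteration's coefficient
#' draws, and the weighted contributions are summed across platform types.
#'
#' @param pos `pos_draws` matrix ([simulate_project_pos()]).
#' @param pw_draws `part_worth_draws` ([sample_part_worths()] or
#'   [fixed_part_worths()]); must share the iteration count with `pos`
#'   (a single-row draw is recycled as fixed coefficients).
#' @param portfolio A [portfolio()].
#' @param levels Attribute-level tibble.
#' @param roster Roster tibble.
#' @return Numeric vector of value draws, one per iteration.
#' @export
portfolio_value_draws <- function(pos, pw_draws, portfolio, levels, roster) {
  stopifnot(inherits(portfolio, "portfolio"),
            inherits(pw_draws, "part_worth_draws"))
  n_iter <- nrow(pos)
  if (pw_draws$n == 1L && n_iter > 1L) {
    pw_draws <- list(beta_b = pw_draws$beta_b[rep(1, n_iter), , drop = FALSE],
                     beta_c = pw_draws$beta_c[rep(1, n_iter), , drop = FALSE],
                     platforms = pw_draws$platforms, n = n_iter)
  } else if (pw_draws$n != n_iter) {
    stop("iteration mismatch: pos has ", n_iter, " draws, part-worths ",
         pw_draws$n, " (common random numbers require equal counts)",
         call. = FALSE)
  }
  ps <- platform_success_draws(pos, roster, portfolio$selection)
  v <- numeric(n_iter)
  for (k in colnames(ps)) {
    lv <- levels[levels$platform_type == k, ]
    if (!nrow(lv)) stop("no attribute levels for platform ", k, call. = FALSE)
    v <- v + preference_value(pw_draws$beta_b[, k], pw_draws$beta_c[, k],
                              c(lv$a, lv$b, lv$c), ps[, k])
  }
  v
}

#' Summary of portfolio value draws
#'
#' @param v Value draws.
#' @param ci Percentile-interval coverage.
#' @return List with `mean`, `sd`, `ci` (equal-tailed), and `quantile(q)`, an
#'   inverted-CDF (type-1) quantile accessor used by the optimizer's VaR
#'   objective.
#' @export
value_summary <- function(v, ci = 0.95) {
  if (!length(v)) stop("empty value draws", call. = FALSE)
  alpha <- (1 - ci) / 2
  sorted <- sort(v)
  qfun <- function(q) quantile_type1(sorted, q, presorted = TRUE)
  list(mean = mean(v), sd = stats::sd(v),
       ci = c(qfun(alpha), qfun(1 - alpha)),
       quantile = qfun)
}

#' Inverted-CDF (type-1) empirical quantile
#'
#' The smallest order statistic `x_(j)` with `j = ceiling(n * q)`; exactly
#' reproducible, no interpolation.
#'
#' @param x Numeric draws.
#' @param q Quantile level(s) in (0, 1].
#' @param presorted Set `TRUE` when `x` is already sorted ascending.
#' @export
quantile_type1 <- function(x, q, presorted = FALSE) {
  stopifnot(all(q > 0), all(q <= 1))
  n <- length(x)
  j <- pmax(1L, as.integer(ceiling(n * q)))
  if (presorted) return(x[j])
  if (length(j) == 1L) sort(x, partial = j)[j] else sort(x)[j]
}
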
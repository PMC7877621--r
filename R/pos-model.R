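#' Simulate project probability-of-success distributions
#'
#' Reviewer-mixture Monte Carlo: in each iteration, independently for every
#' project, one assigned reviewer is selected uniformly at random, each of the
#' seven PoS factors is drawn from that reviewer's triangular three-point
#' distribution, and the factor draws are multiplied into the project PoS.
#' Factors are treated as consequentially independent, so their product is the
#' joint success probability.
#'
#' @param assessments Long assessment tibble (one stage; filter by `stage`
#'   first or pass `stage`).
#' @param assignment Assignment map (project -> reviewer ids).
#' @param roster Roster tibble; its row order fixes the draw-matrix columns.
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed Seed for the PoS substream.
#' @param stage Which assessment stage to use when `assessments` carries both.
#' @return `pos_draws`: an `n_iter x n_projects` matrix of PoS samples in
#'   `[0,1]`, with project ids as column names and attributes `seed`, `stage`.
#' @export
simulate_project_pos <- function(assessments, assignment, roster,
                                 n_iter = 10000L, seed = 1L,
                                 stage = "final") {
  if (!is.null(assessments$stage)) {
    assessments <- assessments[assessments$stage == stage, , drop = FALSE]
  }
  if (!nrow(assessments)) stop("no assessments for stage '", stage, "'",
                               call. = FALSE)
  projects <- roster$project_id
  factors <- pos_factors()
  # pre-index triples: per project, reviewer-major arrays [reviewer, factor]
  tri <- lapply(projects, function(pid) {
    revs <- assignment[[pid]]
    if (is.null(revs) || !length(revs)) {
      stop("project ", pid, " has no assigned reviewers", call. = FALSE)
    }
    sub <- assessments[assessments$project_id == pid, , drop = FALSE]
    idx <- function(col) {
      m <- matrix(NA_real_, length(revs), length(factors),
                  dimnames = list(revs, factors))
      m[cbind(match(sub$reviewer_id, revs), match(sub$factor, factors))] <-
        sub[[col]]
      m
    }
    lo <- idx("worst"); mo <- idx("most_likely"); hi <- idx("best")
    if (anyNA(lo) || anyNA(mo) || anyNA(hi)) {
      stop("incomplete factor triples for project ", pid,
           ": every assigned reviewer needs all 7 factors", call. = FALSE)
    }
    list(lo = lo, mo = mo, hi = hi, n_rev = length(revs))
  })
  names(tri) <- projects
  out <- matrix(NA_real_, n_iter, length(projects),
                dimnames = list(NULL, projects))
  with_seed(derive_seed(seed, paste0("pos-", stage)), {
    for (j in seq_along(projects)) {
      tt <- tri[[j]]
      rev_pick <- sample.int(tt$n_rev, n_iter, replace = TRUE)
      p <- rep(1, n_iter)
      for (f in seq_along(factors)) {
        p <- p * sample_triangular(n_iter,
                                   low = tt$lo[rev_pick, f],
                                   mode = tt$mo[rev_pick, f],
                                   high = tt$hi[rev_pick, f])
      }
      out[, j] <- p
    }
  })
  structure(out, class = c("pos_draws", "matrix", "array"),
            seed = seed, stage = stage)
}

#' Platform-level probability of at least one success, per iteration
#'
#' For each Monte Carlo iteration and platform type `k`,
#' `POS>=1(k) = 1 - prod(1 - p_i)` over the selected member projects `i` of
#' that platform -- computed iteration-wise on the draws (never on means), so
#' platform draws inherit the project draws' uncertainty. A platform with no
#' selected member contributes 0.
#'
#' @param pos `pos_draws` matrix from [simulate_project_pos()].
#' @param roster Roster tibble (maps projects to platform types).
#' @param selection Logical or 0/1 vector over roster rows; defaults to all.
#' @return `n_iter x n_platforms` matrix with platform types as columns.
#' @export
platform_success_draws <- function(pos, roster, selection = NULL) {
  if (is.null(selection)) selection <- rep(TRUE, nrow(roster))
  selection <- as.logical(selection)
  stopifnot(length(selection) == nrow(roster))
  platforms <- unique(roster$platform_type)
  out <- matrix(0, nrow(pos), length(platforms),
                dimnames = list(NULL, platforms))
  for (k in platforms) {
    members <- which(roster$platform_type == k & selection)
    if (!length(members)) next
    fail <- rep(1, nrow(pos))
    for (j in members) fail <- fail * (1 - pos[, j])
    out[, k] <- 1 - fail
  }
  out
}

#' Summarize Monte Carlo draws
#'
#' @param samples Numeric vector or matrix (columns summarized separately).
#' @param ci Equal-tailed percentile interval coverage (default 0.95).
#' @return Tibble with `mean`, `sd`, `ci_low`, `ci_high` (one row per column).
#' @export
summarize_draws <- function(samples, ci = 0.95) {
  if (is.matrix(samples)) {
    rows <- lapply(seq_len(ncol(samples)),
                   function(j) summarize_draws(samples[, j], ci = ci))
    out <- do.call(rbind, rows)
    out$name <- colnames(samples) %||% as.character(seq_len(ncol(samples)))
    return(out[, c("name", "mean", "sd", "ci_low", "ci_high")])
  }
  if (!length(samples)) stop("cannot summarize empty draws", call. = FALSE)
  alpha <- (1 - ci) / 2
  q <- stats::quantile(samples, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(mean = mean(samples), sd = stats::sd(samples),
                 ci_low = q[1], ci_high = q[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
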
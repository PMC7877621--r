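#' Attribute levels of the discrete choice experiment
#'
#' Each platform type is an attribute whose levels are probabilities of at
#' least one successful project (POS>=1): a lower level `a` (always 0), a
#' middle level `b`, and an upper level `c = 2b`. Defaults are the published
#' study levels: RNA and viral vector (0, 0.30, 0.60), DNA (0, 0.28, 0.56),
#' protein (0, 0.20, 0.40), gene-encoded mAb (0, 0.06, 0.12).
#'
#' @return Tibble with `platform_type`, `a`, `b`, `c`.
#' @export
default_attribute_levels <- function() {
  tibble::tibble(
    platform_type = platform_types(),
    a = 0,
    b = c(0.30, 0.30, 0.28, 0.20, 0.06),
    c = c(0.60, 0.60, 0.56, 0.40, 0.12)
  )
}

#' Published part-worth coefficients
#'
#' The conditional-logit coefficients and standard errors estimated from the
#' study's 48-participant DCE: for each platform type, `beta_b` is the utility
#' of moving POS>=1 from the lower to the middle level and `beta_c` the
#' further increment from middle to upper. The negative mAb `beta_c` is
#' retained as published.
#'
#' @return A `part_worths` object usable wherever a fitted model is expected.
#' @export
default_part_worths <- function() {
  co <- tibble::tibble(
    platform_type = platform_types(),
    beta_b = c(1.313, 1.167, 0.833, 0.710, 0.133),
    se_b   = c(0.081, 0.082, 0.076, 0.077, 0.073),
    beta_c = c(0.360, 0.463, 0.118, 0.266, -0.043),
    se_c   = c(0.070, 0.070, 0.073, 0.075, 0.076)
  )
  new_part_worths(co, diagnostics = list(source = "published fixture"))
}

new_part_worths <- function(coefficients, diagnostics = list(), vcov = NULL) {
  stopifnot(all(c("platform_type", "beta_b", "se_b", "beta_c", "se_c") %in%
                  names(coefficients)))
  structure(list(coefficients = coefficients, diagnostics = diagnostics,
                 vcov = vcov),
            class = "part_worths")
}

#' @export
print.part_worths <- function(x, ...) {
  cat("Part-worth coefficients (conditional logit):\n")
  print(x$coefficients)
  if (length(x$diagnostics)) {
    d <- x$diagnostics
    if (!is.null(d$logLik)) {
      cat(sprintf("logLik %.2f | AICc %.2f | BIC %.2f\n",
                  d$logLik, d$AICc, d$BIC))
    }
  }
  invisible(x)
}

#' Build a randomized balanced choice design
#'
#' Generates `blocks x sets_per_block` choice sets of `alts` portfolio
#' alternatives. Each alternative assigns every platform type one of its
#' three POS>=1 levels. Level frequencies per platform are balanced within
#' +/-1 across the whole design (balanced replication of a/b/c, randomly
#' permuted per platform). Per-participant attribute-order and set-order
#' permutations are drawn for survey presentation, and sets containing a
#' level-wise dominant alternative or duplicating another set are flagged as
#' validity probes.
#'
#' @param levels Attribute-level tibble ([default_attribute_levels()]).
#' @param blocks,sets_per_block,alts Design dimensions (defaults 2, 16, 3).
#' @param n_participants Number of participants to randomize orders for.
#' @param seed Seed for the randomized design.
#' @return A `choice_design` list: `sets` (tibble with `block`, `set_id`,
#'   `alternative_id` and one level column per platform), `levels`,
#'   `platforms`, `participant_orders`, `dominant_sets`, `repeated_sets`,
#'   `diagnostics` (level frequencies and pairwise co-occurrence counts).
#' @export
build_design <- function(levels = default_attribute_levels(), blocks = 2L,
                         sets_per_block = 16L, alts = 3L,
                         n_participants = 48L, seed = 1L) {
  if (alts < 2) stop("a choice set needs at least 2 alternatives",
                     call. = FALSE)
  stopifnot(all(levels$a < levels$b), all(levels$b < levels$c))
  platforms <- levels$platform_type
  n_rows <- blocks * sets_per_block * alts
  with_seed(derive_seed(seed, "dce-design"), {
    cols <- lapply(platforms, function(k) {
      lv <- unlist(levels[levels$platform_type == k, c("a", "b", "c")])
      base <- rep(lv, length.out = n_rows)  # frequencies balanced within +/-1
      sample(base)
    })
    names(cols) <- platforms
    sets <- tibble::tibble(
      block = rep(seq_len(blocks), each = sets_per_block * alts),
      set_id = rep(seq_len(blocks * sets_per_block), each = alts),
      alternative_id = rep(seq_len(alts), blocks * sets_per_block)
    )
    sets <- tibble::as_tibble(cbind(sets, tibble::as_tibble(cols)))
    participant_orders <- lapply(seq_len(n_participants), function(p) {
      list(attribute_order = sample(platforms),
           set_order = sample(seq_len(sets_per_block)))
    })
    names(participant_orders) <- sprintf("S%03d", seq_len(n_participants))
    structure(list(sets = sets, levels = levels, platforms = platforms,
                   participant_orders = participant_orders,
                   dominant_sets = find_dominant_sets(sets, platforms),
                   repeated_sets = find_repeated_sets(sets, platforms),
                   diagnostics = design_diagnostics(sets, levels)),
              class = "choice_design")
  })
}

# Sets where one alternative is level-wise >= every other (>= on all
# platforms, > on at least one): a rational respondent must choose it.
find_dominant_sets <- function(sets, platforms) {
  out <- integer(0)
  for (s in unique(sets$set_id)) {
    m <- as.matrix(sets[sets$set_id == s, platforms, drop = FALSE])
    for (j in seq_len(nrow(m))) {
      others <- m[-j, , drop = FALSE]
      ge <- apply(others, 1, function(o) all(m[j, ] >= o) && any(m[j, ] > o))
      if (all(ge)) { out <- c(out, s); break }
    }
  }
  out
}

# Pairs of sets within a block showing identical alternative-level matrices
# (consistency probes: a careful respondent answers both the same way).
find_repeated_sets <- function(sets, platforms) {
  keys <- vapply(unique(sets$set_id), function(s) {
    m <- sets[sets$set_id == s, platforms, drop = FALSE]
    paste(unlist(m), collapse = ",")
  }, character(1))
  ids <- unique(sets$set_id)
  dup <- split(ids, keys)
  dup <- dup[vapply(dup, length, 1L) > 1]
  unname(lapply(dup, identity))
}

design_diagnostics <- function(sets, levels) {
  platforms <- levels$platform_type
  freq <- lapply(platforms, function(k) table(sets[[k]]))
  names(freq) <- platforms
  co <- matrix(0L, length(platforms), length(platforms),
               dimnames = list(platforms, platforms))
  for (i in seq_along(platforms)) {
    for (j in seq_along(platforms)) {
      bi <- levels$b[i]; bj <- levels$b[j]
      co[i, j] <- sum(sets[[platforms[i]]] >= bi - 1e-9 &
                        sets[[platforms[j]]] >= bj - 1e-9)
    }
  }
  list(level_frequencies = freq, nonzero_co_occurrence = co)
}

#' Fit the conditional logit choice model
#'
#' Maximum-likelihood conditional logistic regression of chosen alternatives
#' on cumulative-coded POS>=1 levels: for platform `k`, `X_b(k) = 1` when an
#' alternative shows level b or c, and `X_c(k) = 1` only at level c, so
#' `beta_c(k)` is the utility increment from the middle to the upper level.
#' Estimation uses exact conditional likelihood per choice set
#' (`survival::clogit`); standard errors come from the inverse observed
#' information.
#'
#' @param data Choice data ([generate_choice_responses()] schema).
#' @param levels Attribute-level tibble.
#' @return A `part_worths` object with coefficient table, covariance matrix,
#'   and diagnostics (`logLik`, `AICc`, `BIC`, `n_sets`).
#' @export
fit_conditional_logit <- function(data, levels = default_attribute_levels()) {
  platforms <- levels$platform_type
  X <- choice_model_matrix(data, levels)
  strata_id <- interaction(data$participant_id, data$set_id, drop = TRUE)
  if (any(tapply(data$chosen, strata_id, sum) != 1)) {
    stop("every participant x set stratum needs exactly one chosen alternative",
         call. = FALSE)
  }
  # columns with no variation carry no information in a conditional logit;
  # drop them and report NA for their coefficients
  varying <- apply(X, 2, function(col) stats::var(col) > 0)
  X <- X[, varying, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design coding; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(chosen = data$chosen, X, strata_id = strata_id)
  df$surv <- survival::Surv(rep(1, nrow(df)), df$chosen)
  fml <- stats::as.formula(paste(
    "surv ~", paste(colnames(X), collapse = " + "),
    "+ survival::strata(strata_id)"))
  # conditional logit as stratified Cox partial likelihood (the clogit trick);
  # with exactly one chosen alternative per stratum the partial likelihood
  # equals the exact conditional (multinomial) logit likelihood
  fit <- survival::coxph(fml, data = df,
                         control = survival::coxph.control(iter.max = 50,
                                                           eps = 1e-10))
  est <- stats::coef(fit)
  if (any(!is.finite(est)) || any(abs(est) > 15)) {
    stop("conditional logit did not converge to finite estimates ",
         "(likely complete separation in the choice data)", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  ll <- fit$loglik[2]
  p <- length(est)
  n_sets <- length(unique(strata_id))
  aicc <- -2 * ll + 2 * p + 2 * p * (p + 1) / max(n_sets - p - 1, 1)
  bic <- -2 * ll + p * log(n_sets)
  pick <- function(v, nm) {
    out <- v[match(nm, names(v))]
    unname(out)
  }
  co <- tibble::tibble(
    platform_type = platforms,
    beta_b = pick(est, paste0("Xb_", platforms)),
    se_b = pick(se, paste0("Xb_", platforms)),
    beta_c = pick(est, paste0("Xc_", platforms)),
    se_c = pick(se, paste0("Xc_", platforms))
  )
  new_part_worths(co,
                  diagnostics = list(logLik = ll, AICc = aicc, BIC = bic,
                                     n_sets = n_sets),
                  vcov = stats::vcov(fit))
}

# Cumulative (level-threshold) coding matrix with columns Xb_<k>, Xc_<k>.
choice_model_matrix <- function(data, levels) {
  platforms <- levels$platform_type
  cols <- list()
  for (k in platforms) {
    lv <- levels[levels$platform_type == k, ]
    x <- data[[k]]
    if (is.null(x)) stop("choice data lacks level column for platform ", k,
                         call. = FALSE)
    cols[[paste0("Xb_", k)]] <- as.numeric(x >= lv$b - 1e-9)
    cols[[paste0("Xc_", k)]] <- as.numeric(x >= lv$c - 1e-9)
  }
  do.call(cbind, cols)
}

#' Internal-validity checks of choice responses
#'
#' Dominance: on sets flagged as containing a level-wise dominant
#' alternative, did the participant choose it? Consistency: on repeated
#' (identical) sets, did the participant answer the same way?
#'
#' @param data Choice data.
#' @param design The `choice_design` the data were collected on.
#' @return List with `applicable` flags, per-participant pass tibble, and
#'   summary pass rates (`NA` when no probe sets exist).
#' @export
validity_checks <- function(data, design) {
  stopifnot(inherits(design, "choice_design"))
  platforms <- design$platforms
  participants <- unique(data$participant_id)
  dom_sets <- design$dominant_sets
  rep_sets <- design$repeated_sets

  dom_pass <- rep(NA_real_, length(participants))
  if (length(dom_sets)) {
    for (i in seq_along(participants)) {
      rows <- data[data$participant_id == participants[i] &
                     data$set_id %in% dom_sets, , drop = FALSE]
      if (!nrow(rows)) next
      ok <- vapply(unique(rows$set_id), function(s) {
        sub <- rows[rows$set_id == s, , drop = FALSE]
        m <- as.matrix(sub[, platforms, drop = FALSE])
        j <- which(sub$chosen == 1)
        others <- m[-j, , drop = FALSE]
        all(apply(others, 1, function(o) all(m[j, ] >= o)))
      }, logical(1))
      dom_pass[i] <- mean(ok)
    }
  }
  con_pass <- rep(NA_real_, length(participants))
  if (length(rep_sets)) {
    for (i in seq_along(participants)) {
      ok <- vapply(rep_sets, function(pair) {
        picks <- vapply(pair, function(s) {
          sub <- data[data$participant_id == participants[i] &
                        data$set_id == s, , drop = FALSE]
          if (!nrow(sub)) return(NA_integer_)
          sub$alternative_id[sub$chosen == 1]
        }, integer(1))
        picks <- picks[!is.na(picks)]
        if (length(picks) < 2) NA else length(unique(picks)) == 1
      }, logical(1))
      con_pass[i] <- mean(ok, na.rm = TRUE)
    }
  }
  per <- tibble::tibble(participant_id = participants,
                        dominance_pass = dom_pass,
                        consistency_pass = con_pass)
  list(applicable = list(dominance = length(dom_sets) > 0,
                         consistency = length(rep_sets) > 0),
       per_participant = per,
       summary = list(
         dominance_rate = if (length(dom_sets)) mean(dom_pass, na.rm = TRUE)
                          else NA_real_,
         consistency_rate = if (length(rep_sets)) mean(con_pass, na.rm = TRUE)
                            else NA_real_))
}

#' Piecewise preference weight for a platform's POS>=1
#'
#' The preference function maps an achieved POS>=1 value to a weight `w` such
#' that `w * pos` interpolates the fitted utilities linearly through the
#' anchor points (0, 0), (b, beta_b) and (c, beta_b + beta_c):
#' `w = beta_b / (b - a)` for `pos <= b`, and
#' `w = (beta_b + beta_c * (pos - b) / (c - b)) / pos` for `pos > b`.
#' At `pos = 0` the lower-branch constant is returned. Values above `c`
#' continue the upper linear segment (extrapolation, flagged via attribute
#' `extrapolated`).
#'
#' @param beta_b,beta_c Part-worth coefficients (scalars or vectors recycled
#'   against `pos`).
#' @param levels_k Numeric `(a, b, c)` levels for the platform.
#' @param pos POS>=1 value(s) in `[0, 1]`.
#' @return Weight(s) `w`; multiply by `pos` for the value contribution.
#' @export
preference_weight <- function(beta_b, beta_c, levels_k, pos) {
  a <- levels_k[[1]]; b <- levels_k[[2]]; cc <- levels_k[[3]]
  if (b <= a) stop("levels must satisfy b > a", call. = FALSE)
  if (cc <= b) stop("levels must satisfy c > b", call. = FALSE)
  if (any(pos < 0 | pos > 1)) stop("pos must lie in [0, 1]", call. = FALSE)
  k <- max(length(pos), length(beta_b), length(beta_c))
  pos <- rep_len(pos, k); beta_b <- rep_len(beta_b, k)
  beta_c <- rep_len(beta_c, k)
  lower <- pos <= b
  w <- numeric(k)
  w[lower] <- beta_b[lower] / (b - a)
  up <- !lower
  w[up] <- (beta_b[up] + beta_c[up] * (pos[up] - b) / (cc - b)) / pos[up]
  structure(w, extrapolated = any(pos > cc + 1e-12))
}

# Value contribution w * pos, vectorised; numerically safe at pos = 0.
preference_value <- function(beta_b, beta_c, levels_k, pos) {
  a <- levels_k[[1]]; b <- levels_k[[2]]; cc <- levels_k[[3]]
  lower <- pos <= b
  v <- numeric(length(pos))
  bb <- rep_len(beta_b, length(pos)); bc <- rep_len(beta_c, length(pos))
  v[lower] <- bb[lower] * pos[lower] / (b - a)
  v[!lower] <- bb[!lower] + bc[!lower] * (pos[!lower] - b) / (cc - b)
  v
}

#' Sample stochastic part-worth coefficients
#'
#' Draws coefficient vectors for the Monte Carlo valuation: by default each
#' coefficient is an independent Normal(estimate, SE); with
#' `use_covariance = TRUE` and a covariance matrix present, a multivariate
#' Normal preserving estimation correlations is used instead.
#'
#' @param pw A `part_worths` object (SEs required).
#' @param n Number of draws (default 10000).
#' @param seed Seed for the coefficient substream.
#' @param use_covariance Draw jointly from the fitted covariance when
#'   available.
#' @return A `part_worth_draws` list with `beta_b` and `beta_c` matrices
#'   (`n` x platforms) and the platform order.
#' @export
sample_part_worths <- function(pw, n = 10000L, seed = 1L,
                               use_covariance = FALSE) {
  stopifnot(inherits(pw, "part_worths"))
  co <- pw$coefficients
  if (any(!is.finite(co$se_b)) || any(!is.finite(co$se_c))) {
    stop("part-worths lack standard errors; cannot sample", call. = FALSE)
  }
  platforms <- co$platform_type
  t_k <- length(platforms)
  with_seed(derive_seed(seed, "part-worths"), {
    if (use_covariance && !is.null(pw$vcov)) {
      mu <- c(rbind(co$beta_b, co$beta_c))
      ord <- c(rbind(paste0("Xb_", platforms), paste0("Xc_", platforms)))
      V <- pw$vcov[ord, ord]
      draws <- MASS::mvrnorm(n, mu = mu, Sigma = V)
      beta_b <- draws[, seq(1, 2 * t_k, by = 2), drop = FALSE]
      beta_c <- draws[, seq(2, 2 * t_k, by = 2), drop = FALSE]
    } else {
      beta_b <- vapply(seq_len(t_k),
                       function(j) stats::rnorm(n, co$beta_b[j], co$se_b[j]),
                       numeric(n))
      beta_c <- vapply(seq_len(t_k),
                       function(j) stats::rnorm(n, co$beta_c[j], co$se_c[j]),
                       numeric(n))
    }
    colnames(beta_b) <- platforms
    colnames(beta_c) <- platforms
    structure(list(beta_b = beta_b, beta_c = beta_c, platforms = platforms,
                   n = as.integer(n), seed = seed),
              class = "part_worth_draws")
  })
}

#' Freeze part-worths at their point estimates
#'
#' Convenience for deterministic analyses: a `part_worth_draws` object whose
#' every draw equals the point estimate (equivalent to SEs of zero).
#'
#' @param pw A `part_worths` object.
#' @param n Number of (identical) rows.
#' @return A `part_worth_draws` object.
#' @export
fixed_part_worths <- function(pw, n = 1L) {
  co <- pw$coefficients
  platforms <- co$platform_type
  structure(list(
    beta_b = matrix(co$beta_b, n, length(platforms), byrow = TRUE,
                    dimnames = list(NULL, platforms)),
    beta_c = matrix(co$beta_c, n, length(platforms), byrow = TRUE,
                    dimnames = list(NULL, platforms)),
    platforms = platforms, n = as.integer(n), seed = NA_integer_),
    class = "part_worth_draws")
}
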
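test_that("feasible-portfolio enumeration matches brute force", {
  roster <- toy_roster(c(1, 2, 4))
  got <- enumerate_feasible(roster, budget = 3)
  costs <- vapply(got, function(p) p$cost, numeric(1))
  expect_length(got, 3)  # {1}, {2}, {1,2}
  expect_equal(costs, c(1, 2, 3))

  expect_length(enumerate_feasible(roster, budget = 0.5), 0)
  expect_length(enumerate_feasible(roster, budget = 100), 2^3 - 1)
  # strict reading of "under the budget"
  expect_length(enumerate_feasible(roster, budget = 3, strict = TRUE), 2)
})

test_that("dispersion and Gini statistics match closed forms", {
  d0 <- dominance_stats(rep(1.5, 100))
  expect_equal(unlist(d0[c("variance", "semivariance", "mad", "gini")]),
               c(variance = 0, semivariance = 0, mad = 0, gini = 0))

  d01 <- dominance_stats(rep(c(0, 1), 500))
  expect_equal(d01$gini, 0.25)
  expect_equal(d01$variance, 0.25)
  expect_equal(d01$semivariance, 0.125)
  expect_equal(d01$mean_minus_gini, 0.25)

  set.seed(42)
  u <- runif(100000)
  du <- dominance_stats(u)
  expect_lt(abs(du$gini - 1 / 6), 0.005)
  expect_lte(du$semivariance, du$variance)

  expect_error(dominance_stats(numeric(0)), "empty")
})

test_that("fast Gini identity agrees with the naive double loop", {
  set.seed(7)
  for (x in list(runif(2000), rnorm(500), c(rep(0.2, 300), rep(0.7, 200)))) {
    naive <- mean(abs(outer(x, x, "-")))
    expect_lt(abs(gini_mean_difference(x) - naive), 1e-10)
  }
})

test_that("mean-risk and mean-Gini dominance relations are definitional", {
  a <- dominance_stats(rep(c(0.9, 1.1), 50))
  b <- dominance_stats(rep(c(0.5, 1.3), 50))
  expect_equal(mv_dominates(a, a), "non-comparable")
  expect_equal(mv_dominates(a, b), "dominates")  # higher mean, lower var
  expect_equal(mv_dominates(b, a), "dominated")

  hi_var <- dominance_stats(rep(c(0, 2.4), 50))
  expect_equal(mv_dominates(hi_var, a), "non-comparable")

  # degenerate 1.0 vs fair {0,2} coin: equal means, Gamma 0 vs 0.5
  deg <- dominance_stats(rep(1, 100))
  coin <- dominance_stats(rep(c(0, 2), 50))
  expect_equal(coin$gini, 0.5)
  expect_equal(mean_gini_dominates(deg, coin), "dominates")
  expect_equal(mean_gini_dominates(coin, deg), "dominated")
  expect_equal(mean_gini_dominates(deg, deg), "non-comparable")
})

test_that("rank probabilities are tie-aware and exactly symmetric", {
  inst <- synthetic_instance(seed = 17, n_iter = 400)
  roster <- inst$roster
  ref <- portfolio(roster$platform_type == "RNA", roster)
  expect_equal(rank_probability(ref, ref, inst$pos, inst$pw_draws,
                                inst$levels, roster), 0.5)

  # exact complement rule over several random pairs
  set.seed(1)
  for (i in 1:5) {
    a <- portfolio(runif(16) < 0.4, roster)
    b <- portfolio(runif(16) < 0.4, roster)
    pab <- rank_probability(a, b, inst$pos, inst$pw_draws, inst$levels,
                            roster)
    pba <- rank_probability(b, a, inst$pos, inst$pw_draws, inst$levels,
                            roster)
    expect_equal(pab + pba, 1, tolerance = 1e-15)
  }

  # degenerate distributions: value 2 always beats value 1
  lv <- default_attribute_levels()
  pwf <- fixed_part_worths(default_part_worths())
  r2 <- toy_roster(c(5, 5), platforms = c("RNA", "ViralVector"))
  posA <- constant_pos(r2, c(0.3, 0.3), n_iter = 30)
  strong <- portfolio(c(TRUE, TRUE), r2)
  weak <- portfolio(c(TRUE, FALSE), r2)
  expect_equal(rank_probability(strong, weak, posA, pwf, lv, r2), 1)

  # identical marginal value distributions from symmetric platforms
  rsym <- toy_roster(c(5, 5), platforms = c("RNA", "ViralVector"))
  levsym <- default_attribute_levels()
  pw_sym <- default_part_worths()
  pw_sym$coefficients$beta_b[2] <- 1.313
  pw_sym$coefficients$beta_c[2] <- 0.360
  pw_sym$coefficients$se_b[1:2] <- 0.2
  pw_sym$coefficients$se_c[1:2] <- 0.2
  pwd_sym <- sample_part_worths(pw_sym, n = 4000, seed = 3)
  possym <- constant_pos(rsym, c(0.35, 0.35), n_iter = 4000)
  pa <- rank_probability(portfolio(c(TRUE, FALSE), rsym),
                         portfolio(c(FALSE, TRUE), rsym),
                         possym, pwd_sym, levsym, rsym)
  expect_lt(abs(pa - 0.5), 0.02)
})

test_that("the outranking report bands alternatives and profiles composition", {
  inst <- synthetic_instance(seed = 19, n_iter = 400)
  roster <- inst$roster
  ref <- portfolio(roster$platform_type %in% c("RNA", "Protein"), roster)

  same <- outranking_report(ref, list(ref), inst$pos, inst$pw_draws,
                            inst$levels, roster)
  expect_equal(same$table$probability, 0.5)
  band_incl <- same$band_inclusion[[1]]
  expect_equal(band_incl$inclusion_rate[match(ref$project_ids,
                                              band_incl$project_id)],
               rep(1, length(ref$project_ids)))

  expect_error(outranking_report(ref, list(), inst$pos, inst$pw_draws,
                                 inst$levels, roster), "no alternatives")

  # strictly dominated point-mass alternatives are outranked with certainty
  lv <- default_attribute_levels()
  pwf <- fixed_part_worths(default_part_worths())
  r2 <- toy_roster(c(5, 5), platforms = c("RNA", "ViralVector"))
  posA <- constant_pos(r2, c(0.3, 0.3), n_iter = 30)
  rep2 <- outranking_report(portfolio(c(TRUE, TRUE), r2),
                            list(portfolio(c(TRUE, FALSE), r2),
                                 portfolio(c(FALSE, TRUE), r2)),
                            posA, pwf, lv, r2)
  expect_equal(rep2$table$probability, c(1, 1))
  expect_equal(rep2$min_probability, 1)
  expect_equal(rep2$table$removed, list("T02", "T01"))
})
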
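test_that("roster generation honours seed, grouping and budget range", {
  cfg <- synthetic_config(seed = 1)
  r1 <- generate_roster(cfg)
  r2 <- generate_roster(cfg)
  expect_identical(r1, r2)

  expect_equal(nrow(r1), 16)
  expect_equal(as.vector(table(r1$platform_type)[platform_types()]),
               c(4, 4, 3, 3, 2))
  expect_true(all(r1$budget_musd >= 6 & r1$budget_musd <= 65))
  expect_equal(r1$budget_musd, round(r1$budget_musd, 1))

  degenerate <- synthetic_config(seed = 3, budget_range = c(10, 10))
  expect_true(all(generate_roster(degenerate)$budget_musd == 10))

  expect_error(synthetic_config(platform_sizes = c(RNA = 3, DNA = 3)),
               "sum")
})

test_that("reviewer assignment satisfies both margins and is seeded", {
  cfg <- synthetic_config(seed = 2)
  roster <- generate_roster(cfg)
  a1 <- assign_reviewers(cfg, roster)
  a2 <- assign_reviewers(cfg, roster)
  expect_identical(a1, a2)

  per_project <- lengths(a1)
  expect_true(all(per_project >= 4 & per_project <= 5))
  per_reviewer <- table(unlist(a1))
  expect_true(all(per_reviewer <= 4))
  expect_true(all(vapply(a1, anyDuplicated, 1L) == 0))

  tiny <- synthetic_config(seed = 1, n_projects = 1,
                           platform_sizes = c(RNA = 1),
                           n_reviewers_pool = 5,
                           reviewers_per_project = c(1, 1),
                           projects_per_reviewer = c(1, 1))
  single <- assign_reviewers(tiny, generate_roster(tiny))
  expect_length(single[[1]], 1)
})

test_that("infeasible assignment margins raise a counting error", {
  cfg <- synthetic_config(seed = 1, n_reviewers_pool = 3)
  roster <- generate_roster(cfg)
  # 16 projects x 4 minimum slots = 64 > 3 reviewers x 4 cap = 12 (the
  # per-project minimum also already exceeds the pool)
  expect_error(assign_reviewers(cfg, roster), "infeasible")
  wide <- synthetic_config(seed = 1, n_reviewers_pool = 6,
                           projects_per_reviewer = c(1, 4))
  # pool of 6 x cap 4 = 24 slots < 64 required
  expect_error(assign_reviewers(wide, roster), "at least 64.*at most 24")
})

test_that("assessment triples are ordered, bounded, and shrink with optimism", {
  cfg <- synthetic_config(seed = 4, optimism_shift = 0.3)
  roster <- generate_roster(cfg)
  a <- assign_reviewers(cfg, roster)
  tab <- generate_assessments(cfg, a)
  expect_true(all(tab$worst >= 0 & tab$best <= 1))
  expect_true(all(tab$worst <= tab$most_likely + 1e-12))
  expect_true(all(tab$most_likely <= tab$best + 1e-12))
  # each assigned reviewer-project pair carries all 7 factors, both stages
  n_pairs <- sum(lengths(a))
  expect_equal(nrow(tab), n_pairs * 7 * 2)

  ini <- tab[tab$stage == "initial", ]
  fin <- tab[tab$stage == "final", ]
  expect_true(all(fin$most_likely <= ini$most_likely + 1e-12))
  expect_equal(fin$most_likely, ini$most_likely * 0.7)

  no_shift <- synthetic_config(seed = 4, optimism_shift = 0)
  tab0 <- generate_assessments(no_shift, a)
  ini0 <- tab0[tab0$stage == "initial", ]
  fin0 <- tab0[tab0$stage == "final", ]
  expect_equal(fin0$most_likely, ini0$most_likely)
  expect_equal(fin0$worst, ini0$worst)

  fixed <- synthetic_config(seed = 4,
                            factor_prior = list(mode = 0.9, spread = 0),
                            optimism_shift = 0)
  tabf <- generate_assessments(fixed, a)
  expect_true(all(tabf$worst == 0.9 & tabf$most_likely == 0.9 &
                    tabf$best == 0.9))
})

test_that("different seeds give different assessments", {
  roster <- generate_roster(synthetic_config(seed = 1))
  a <- assign_reviewers(synthetic_config(seed = 1), roster)
  t1 <- generate_assessments(synthetic_config(seed = 1), a)
  t2 <- generate_assessments(synthetic_config(seed = 2), a)
  expect_false(identical(t1$most_likely, t2$most_likely))
})

test_that("simulated choices follow the conditional logit", {
  lv <- default_attribute_levels()
  design <- build_design(lv, seed = 5)
  # all-zero truth: every alternative equally likely, shares ~ 1/3
  null_truth <- default_part_worths()
  null_truth$coefficients$beta_b[] <- 0
  null_truth$coefficients$beta_c[] <- 0
  cfg <- synthetic_config(seed = 5, dce = list(participants = 1500L))
  ch <- generate_choice_responses(cfg, design, truth = null_truth)
  shares <- tapply(ch$chosen, ch$alternative_id, mean)
  expect_true(all(abs(shares - 1 / 3) < 0.02))
  expect_true(all(tapply(ch$chosen,
                         interaction(ch$participant_id, ch$set_id,
                                     drop = TRUE), sum) == 1))

  # a huge uniform positive truth makes the level-wise largest alternative
  # (when one exists) all but certain to be chosen
  big <- default_part_worths()
  big$coefficients$beta_b[] <- 8
  big$coefficients$beta_c[] <- 8
  chb <- generate_choice_responses(cfg, design, truth = big)
  val <- validity_checks(chb, design)
  if (val$applicable$dominance) {
    expect_gt(val$summary$dominance_rate, 0.95)
  }

  # determinism and seed sensitivity
  ch2 <- generate_choice_responses(cfg, design, truth = null_truth)
  expect_identical(ch, ch2)
  cfg2 <- synthetic_config(seed = 6, dce = list(participants = 1500L))
  ch3 <- generate_choice_responses(cfg2, design, truth = null_truth)
  expect_false(identical(ch$chosen, ch3$chosen))

  bad_truth <- default_part_worths()
  bad_truth$coefficients <- bad_truth$coefficients[-1, ]
  expect_error(generate_choice_responses(cfg, design, truth = bad_truth),
               "missing platform")
})
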
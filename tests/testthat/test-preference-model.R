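test_that("choice design is balanced, complete and seeded", {
  lv <- default_attribute_levels()
  d <- build_design(lv, blocks = 2, sets_per_block = 16, alts = 3, seed = 1)
  expect_s3_class(d$sets, "tbl_df")
  expect_equal(length(unique(d$sets$set_id)), 32)
  expect_equal(nrow(d$sets), 32 * 3)
  expect_true(all(platform_types() %in% names(d$sets)))

  # every alternative shows one of the platform's three levels, frequencies
  # balanced within +/-1 across the design
  for (k in platform_types()) {
    lvk <- unlist(lv[lv$platform_type == k, c("a", "b", "c")])
    expect_true(all(d$sets[[k]] %in% lvk))
    freq <- table(d$sets[[k]])
    expect_lte(diff(range(freq)), 1)
  }

  d2 <- build_design(lv, seed = 1)
  expect_identical(d$sets, d2$sets)
  d3 <- build_design(lv, seed = 2)
  expect_false(identical(d$sets, d3$sets))

  expect_length(d$participant_orders, 48)
  expect_setequal(d$participant_orders[[1]]$attribute_order, platform_types())
  expect_error(build_design(lv, alts = 1), "at least 2")
})

test_that("preference weight reproduces the piecewise interpolation", {
  lv <- default_attribute_levels()
  pw <- default_part_worths()$coefficients

  # published worked values: RNA at the middle and upper levels
  w_mid <- preference_weight(1.313, 0.360, c(0, 0.30, 0.60), 0.30)
  expect_equal(as.numeric(w_mid), 4.376667, tolerance = 1e-6)
  expect_equal(as.numeric(w_mid) * 0.30, 1.313, tolerance = 1e-9)
  w_up <- preference_weight(1.313, 0.360, c(0, 0.30, 0.60), 0.60)
  expect_equal(as.numeric(w_up) * 0.60, 1.673, tolerance = 1e-9)

  expect_equal(as.numeric(preference_weight(0, 0, c(0, 0.3, 0.6),
                                            c(0, 0.2, 0.5))), rep(0, 3))
  expect_error(preference_weight(1, 1, c(0, 0.3, 0.2), 0.5), "c > b")
  expect_error(preference_weight(1, 1, c(0.3, 0.3, 0.6), 0.5), "b > a")

  # interpolation identity on a grid, for all five platform parameterizations
  for (i in seq_len(nrow(lv))) {
    a <- lv$a[i]; b <- lv$b[i]; cc <- lv$c[i]
    bb <- pw$beta_b[i]; bc <- pw$beta_c[i]
    grid <- seq(0, cc, length.out = 41)
    got <- as.numeric(preference_weight(bb, bc, c(a, b, cc), grid)) * grid
    want <- stats::approx(x = c(0, b, cc), y = c(0, bb, bb + bc),
                          xout = grid)$y
    expect_equal(got, want, tolerance = 1e-12)
  }

  # pos = 0 returns the lower-branch constant, extrapolation is flagged
  expect_equal(as.numeric(preference_weight(1.2, 0.3, c(0, 0.3, 0.6), 0)),
               1.2 / 0.3)
  expect_true(attr(preference_weight(1.2, 0.3, c(0, 0.3, 0.6), 0.7),
                   "extrapolated"))
})

test_that("conditional logit MLE matches a grid-search likelihood oracle", {
  # 2-alternative sets differing on one platform only: a single coefficient
  lv <- tibble::tibble(platform_type = "RNA", a = 0, b = 0.3, c = 0.6)
  n_sets <- 40
  chosen_hi <- 28  # fixed outcome counts, enumerable likelihood
  data <- tibble::tibble(
    participant_id = rep(sprintf("S%02d", seq_len(n_sets)), each = 2),
    set_id = rep(seq_len(n_sets), each = 2),
    alternative_id = rep(1:2, n_sets),
    RNA = rep(c(0.3, 0), n_sets),
    chosen = as.vector(vapply(seq_len(n_sets),
                              function(s) if (s <= chosen_hi) c(1L, 0L)
                                          else c(0L, 1L),
                              integer(2)))
  )
  fit <- fit_conditional_logit(data, lv)
  # independent oracle: log-likelihood of the one-parameter conditional logit
  # maximized by grid search (X_c never varies here and is dropped)
  ll <- function(beta) {
    chosen_hi * (beta - log(exp(beta) + 1)) -
      (n_sets - chosen_hi) * log(exp(beta) + 1)
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_hat <- grid[which.max(ll(grid))]
  expect_equal(fit$coefficients$beta_b, beta_hat, tolerance = 1e-4)
  expect_equal(beta_hat, log(chosen_hi / (n_sets - chosen_hi)),
               tolerance = 1e-3)
})

test_that("rank-deficient coding is reported with the collinear column", {
  lv <- tibble::tibble(platform_type = "RNA", a = 0, b = 0.3, c = 0.6)
  data <- tibble::tibble(
    participant_id = rep("S01", 4), set_id = rep(1:2, each = 2),
    alternative_id = rep(1:2, 2),
    RNA = c(0.6, 0, 0.6, 0),  # Xb and Xc identical -> collinear
    chosen = c(1L, 0L, 0L, 1L)
  )
  expect_error(fit_conditional_logit(data, lv), "collinear")
})

test_that("simulated truth is recovered and the null shows no signal", {
  lv <- default_attribute_levels()
  design <- build_design(lv, seed = 7)
  cfg <- synthetic_config(seed = 7, dce = list(participants = 2000L))
  ch <- generate_choice_responses(cfg, design)
  fit <- fit_conditional_logit(ch, lv)
  truth <- default_part_worths()$coefficients
  expect_true(all(abs(fit$coefficients$beta_b - truth$beta_b) < 0.1))
  expect_true(all(abs(fit$coefficients$beta_c - truth$beta_c) < 0.1))
  expect_true(all(c(fit$coefficients$se_b, fit$coefficients$se_c) > 0))
  expect_lt(fit$diagnostics$AICc, fit$diagnostics$BIC)

  null_truth <- default_part_worths()
  null_truth$coefficients$beta_b[] <- 0
  null_truth$coefficients$beta_c[] <- 0
  chn <- generate_choice_responses(cfg, design, truth = null_truth)
  fitn <- fit_conditional_logit(chn, lv)
  z <- c(fitn$coefficients$beta_b / fitn$coefficients$se_b,
         fitn$coefficients$beta_c / fitn$coefficients$se_c)
  expect_true(all(abs(z) < 4))
})

test_that("validity checks score dominance and consistency probes", {
  lv <- tibble::tibble(platform_type = c("RNA", "DNA"), a = 0,
                       b = c(0.3, 0.28), c = c(0.6, 0.56))
  sets <- tibble::tibble(
    block = 1L, set_id = rep(1:3, each = 2), alternative_id = rep(1:2, 3),
    RNA = c(0.6, 0, 0.3, 0.6, 0.3, 0.6),
    DNA = c(0.56, 0, 0.28, 0, 0.28, 0)  # set 1 dominant; sets 2,3 repeats
  )
  design <- structure(list(sets = sets, levels = lv,
                           platforms = c("RNA", "DNA"),
                           participant_orders = list(),
                           dominant_sets = vaxpda:::find_dominant_sets(
                             sets, c("RNA", "DNA")),
                           repeated_sets = vaxpda:::find_repeated_sets(
                             sets, c("RNA", "DNA")),
                           diagnostics = list()),
                      class = "choice_design")
  expect_equal(design$dominant_sets, 1L)
  expect_equal(design$repeated_sets, list(c(2L, 3L)))

  good <- tibble::tibble(participant_id = "S001", block = 1L,
                         set_id = rep(1:3, each = 2),
                         alternative_id = rep(1:2, 3),
                         RNA = sets$RNA, DNA = sets$DNA,
                         chosen = c(1L, 0L, 0L, 1L, 0L, 1L))
  v <- validity_checks(good, design)
  expect_equal(v$summary$dominance_rate, 1)
  expect_equal(v$summary$consistency_rate, 1)

  bad <- good
  bad$chosen <- c(0L, 1L, 1L, 0L, 0L, 1L)  # misses dominant, flips repeat
  vb <- validity_checks(bad, design)
  expect_equal(vb$summary$dominance_rate, 0)
  expect_equal(vb$summary$consistency_rate, 0)

  no_probe <- design
  no_probe$dominant_sets <- integer(0)
  no_probe$repeated_sets <- list()
  vn <- validity_checks(good, no_probe)
  expect_false(vn$applicable$dominance)
  expect_true(is.na(vn$summary$dominance_rate))
})

test_that("part-worth sampling follows Normal(estimate, SE)", {
  pw <- default_part_worths()
  frozen <- pw
  frozen$coefficients$se_b[] <- 0
  frozen$coefficients$se_c[] <- 0
  d0 <- sample_part_worths(frozen, n = 50, seed = 1)
  expect_true(all(d0$beta_b[, "RNA"] == 1.313))
  expect_true(all(d0$beta_c[, "mAb"] == -0.043))

  d <- sample_part_worths(pw, n = 100000, seed = 1)
  expect_lt(abs(mean(d$beta_b[, "RNA"]) - 1.313), 0.002)
  q <- stats::quantile(d$beta_b[, "RNA"], c(0.025, 0.975), names = FALSE)
  expect_equal(q, 1.313 + c(-1.96, 1.96) * 0.081, tolerance = 0.01)

  broken <- pw
  broken$coefficients$se_b[1] <- NA
  expect_error(sample_part_worths(broken, 10, seed = 1), "standard errors")
})

test_that("the published coefficient fixture is complete", {
  pw <- default_part_worths()
  co <- pw$coefficients
  expect_equal(nrow(co), 5)
  expect_equal(co$beta_b[co$platform_type == "RNA"], 1.313)
  expect_equal(co$beta_c[co$platform_type == "mAb"], -0.043)
  expect_equal(length(c(co$beta_b, co$beta_c)), 10)
  expect_true(all(c(co$se_b, co$se_c) > 0))
})
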
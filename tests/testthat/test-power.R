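test_that("power outcomes wire truth to detection correctly", {
  model <- builtin_community_model()
  oc <- run_power_simulation(model, n_taxa = 150L, n_per_group = 20L,
                             n_sims = 3L, seed = 33L)
  expect_s3_class(oc, "power_outcomes")
  expect_identical(nrow(oc), 450L)                  # unconditional: all taxa
  expect_true(all(oc$y %in% 0:1))
  expect_true(all(is.finite(oc$x1) & is.finite(oc$x2) & oc$x2 >= 0))
  # y = 1 iff q < alpha among tested taxa
  tested <- !is.na(oc$q_value)
  expect_identical(oc$y[tested], as.integer(oc$q_value[tested] < 0.1))
  # filtered-out taxa are retained as undetectable
  expect_true(all(oc$y[!tested] == 0L))

  occ <- run_power_simulation(model, n_taxa = 150L, n_per_group = 20L,
                              n_sims = 3L, seed = 33L, conditional = TRUE)
  expect_lt(nrow(occ), nrow(oc))
  expect_true(all(!is.na(occ$q_value)))

  # the default design mirrors the standard experiment
  fm <- formals(run_power_simulation)
  expect_identical(eval(fm$n_taxa), 1000L)
  expect_identical(eval(fm$n_per_group), 100L)
  expect_identical(eval(fm$n_sims), 100L)
})

test_that("the fitted surface tracks a known monotone detection probability", {
  oc <- synthetic_outcomes(50000L, seed = 35L)
  surf <- fit_power_surface(oc)
  g <- expand.grid(x1 = seq(0.5, 11.5, length.out = 10),
                   x2 = seq(0.2, 3.8, length.out = 10))
  ph <- predict(surf, g$x1, g$x2)
  pt <- plogis(-3 + 0.3 * g$x1 + 1.5 * g$x2)
  expect_lt(mean(abs(ph - pt)), 0.05)
  expect_true(all(ph >= 0 & ph <= 1))
  expect_identical(count_monotonicity_violations(surf), 0L)
})

test_that("signal-free outcomes give a nearly flat surface", {
  oc <- synthetic_outcomes(20000L, seed = 37L)
  set.seed(38)
  oc$y <- sample(oc$y)
  surf <- fit_power_surface(oc)
  g1 <- seq(0, 12, length.out = 20); g2 <- seq(0, 4, length.out = 20)
  pr <- predict(surf, rep(g1, 20), rep(g2, each = 20))
  expect_lt(max(pr) - min(pr), 0.1)
})

test_that("degenerate outcomes are rejected", {
  oc <- synthetic_outcomes(500L, seed = 39L)
  oc$y <- 1L
  expect_error(fit_power_surface(oc), "all-detected")
})

test_that("predictions outside the training box clamp to the boundary", {
  oc <- synthetic_outcomes(20000L, seed = 41L)
  surf <- fit_power_surface(oc)
  inside <- predict(surf, surf$box$x1[2L], surf$box$x2[2L])
  outside <- predict(surf, surf$box$x1[2L] + 5, surf$box$x2[2L] + 5)
  expect_equal(as.numeric(outside), as.numeric(inside), tolerance = 1e-12)
  expect_identical(attr(outside, "n_clamped"), 1L)
})

test_that("power summaries satisfy the expected-count identity exactly", {
  # a flat half-power surface: all coefficient increments zero
  oc <- synthetic_outcomes(2000L, seed = 43L)
  surf <- fit_power_surface(oc)
  flat <- surf
  flat$coef <- matrix(0, surf$df[1L], surf$df[2L])
  taxa <- data.frame(x1 = runif(1000, 1, 11), x2 = runif(1000, 0.1, 3.9))
  s_flat <- power_summary(flat, taxa)
  expect_equal(s_flat$power, rep(0.5, 1000))
  expect_equal(s_flat$expected_significant, 500)

  s <- power_summary(surf, taxa)
  expect_identical(s$expected_significant, s$n * s$average_power)
  expect_lt(abs(s$expected_significant - sum(s$power)), 1e-9)
  expect_true(all(s$power >= 0 & s$power <= 1))
  expect_identical(length(s$quantiles), 9L)
  expect_error(power_summary(surf, data.frame(x1 = numeric(), x2 = numeric())),
               "empty")
})

test_that("right-skewed per-taxon powers push the mean above the median", {
  oc <- synthetic_outcomes(20000L, seed = 45L)
  surf <- fit_power_surface(oc)
  # mostly weak taxa, a few strong: right-skewed power distribution
  taxa <- data.frame(x1 = c(rep(1, 900), rep(11, 100)),
                     x2 = c(rep(0.2, 900), rep(3.8, 100)))
  s <- power_summary(surf, taxa)
  expect_gt(s$average_power, unname(s$quantiles["50%"]))
})

test_that("a small sample-size sweep has the documented layout and defaults", {
  model <- builtin_community_model()
  sw <- sample_size_sweep(model, sizes = c(15L, 30L), lfc_values = c(1, 2),
                          n_taxa = 120L, n_sims = 3L, seed = 47L)
  expect_s3_class(sw, "power_sweep")
  expect_identical(nrow(sw), 4L)
  expect_identical(sort(unique(sw$size)), c(15L, 30L))
  expect_true(all(sw$power >= 0 & sw$power <= 1))
  expect_true(all(sw$expected_significant >= 0))
  # defaults reproduce the standard sweep grid
  fm <- formals(sample_size_sweep)
  expect_identical(eval(fm$sizes), seq(30L, 190L, by = 20L))
  expect_identical(eval(fm$lfc_values), c(2, 3, 4))
  expect_identical(eval(fm$x1_ref), 5)
})
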
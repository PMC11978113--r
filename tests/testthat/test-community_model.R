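test_that("taxon summaries are log2 means of normalised counts", {
  est <- data.frame(taxon_id = c("a", "b", "c"), base_mean = c(32, 0, 8),
                    lfc_raw = c(1, 0, -2), lfc_shrunk = c(0.8, 0, -1.5),
                    se_lfc = 0.1, dispersion = 0.1, p_value = 0.5,
                    q_value = 0.5, tested = TRUE)
  xy <- compute_taxon_summaries(est)
  expect_equal(xy$x[xy$taxon_id == "a"], 5)
  expect_equal(xy$y, c(0.8, -1.5))
  expect_identical(attr(xy, "n_excluded"), 1L)
  est$lfc_shrunk <- NA_real_
  expect_error(compute_taxon_summaries(est), "shrink_lfc")
})

test_that("single-component EM equals the closed-form Gaussian fit", {
  set.seed(21)
  x <- rnorm(200, 3, 2)
  f <- fit_gmm(x, 1L)
  expect_equal(f$means, mean(x))
  expect_equal(f$sds, sqrt(mean((x - mean(x))^2)))
})

test_that("two-component EM recovers a well-separated mixture", {
  set.seed(22)
  x <- c(rnorm(1000, 0, 1), rnorm(1000, 6, 1))
  f <- fit_gmm(x, 2L, seed = 5L)
  o <- order(f$means)
  expect_equal(f$means[o], c(0, 6), tolerance = 0.2)
  expect_equal(f$weights[o], c(0.5, 0.5), tolerance = 0.05)
  expect_trace_nondecreasing(f$ll_trace)
  # nesting: richer model never fits worse
  expect_gte(f$loglik, fit_gmm(x, 1L)$loglik)
})

test_that("mixture densities integrate to one", {
  set.seed(23)
  f <- fit_gmm(c(rnorm(300), rnorm(300, 4)), 2L, seed = 2L)
  grid <- seq(-10, 14, length.out = 4001)
  dens <- rowSums(vapply(1:2, function(k)
    f$weights[k] * dnorm(grid, f$means[k], f$sds[k]), numeric(length(grid))))
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 1e-4)
})

test_that("bootstrap order selection is reproducible and respects K_max", {
  set.seed(24)
  x <- rnorm(400, 2, 1)
  s1 <- select_components_bootstrap(x, K_max = 2L, B = 20L, seed = 7L)
  s2 <- select_components_bootstrap(x, K_max = 2L, B = 20L, seed = 7L)
  expect_identical(s1, s2)   # bit-reproducible under a fixed seed
  expect_true(all(s1$selection$p_value > 0 & s1$selection$p_value <= 1))

  s0 <- select_components_bootstrap(x, K_max = 1L, B = 20L, seed = 7L)
  expect_identical(s0$K, 1L)
  expect_identical(nrow(s0$selection), 0L)
})

test_that("GMM loglik agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(25)
  x <- c(rnorm(500, 0, 1), rnorm(500, 5, 2))
  f <- fit_gmm(x, 2L, seed = 3L)
  mc <- mclust::Mclust(x, G = 2L, modelNames = "V", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("LFC mixture weights sum to one and trace is monotone for all candidates", {
  set.seed(26)
  n <- 400
  x <- rnorm(n, 5, 2)
  y <- ifelse(runif(n) < 0.6, rnorm(n, 0, 0.3), rnorm(n, 0, 1.5))
  f <- fit_lfc_mixture(x, y, K_range = 1:3, seed = 4L)
  expect_equal(sum(f$weights), 1, tolerance = 1e-10)
  expect_equal(f$lambda[1L], 0)
  expect_trace_nondecreasing(f$ll_trace)
  expect_true(all(c("K", "variance_form", "aic") %in% names(f$candidates)))
})

test_that("homoscedastic data yield a near-flat fitted variance function", {
  set.seed(27)
  n <- 2000
  x <- rnorm(n, 5, 2)
  y <- 0.1 * x + rnorm(n, 0, 0.8)
  f <- fit_lfc_mixture(x, y, K_range = 1:2, seed = 6L)
  xr <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 20)
  # mixture sd at each x (weighted component sds)
  sds <- vapply(xr, function(xx) {
    Xs <- cbind(1, xx, if (f$degree == 2L) xx^2)
    sqrt(sum(f$weights * exp(2 * rowSums(f$sd_coef * matrix(Xs, f$K,
                                                            f$degree + 1L,
                                                            byrow = TRUE)))))
  }, numeric(1))
  expect_lt((max(sds) - min(sds)) / min(sds), 0.2)
})

test_that("conditional LFC density integrates to one at fixed abundance", {
  set.seed(28)
  x <- rnorm(500, 5, 2)
  y <- 0.2 + 0.1 * x + rnorm(500, 0, 0.7)
  f <- fit_lfc_mixture(x, y, K_range = 1:2, seed = 8L)
  for (xx in c(2, 5, 8)) {
    grid <- seq(-15, 15, length.out = 3001)
    expect_equal(sum(dlfc(grid, xx, f)) * diff(grid[1:2]), 1, tolerance = 1e-3)
  }
})

test_that("dispersion trend recovers noiseless coefficients exactly", {
  m <- exp(seq(log(2), log(2000), length.out = 60))
  d <- 0.2 + 5 / m
  tr <- fit_dispersion_trend(m, d)
  expect_equal(tr$c0, 0.2, tolerance = 1e-6)
  expect_equal(tr$c1, 5, tolerance = 1e-6)
  expect_equal(tr$scale, 0.3)
  expect_equal(predict_dispersion(tr, 10), 0.3 * (0.2 + 0.5), tolerance = 1e-6)
  # monotone non-increasing prediction
  mm <- seq(1, 100, length.out = 50)
  expect_true(all(diff(predict_dispersion(tr, mm)) <= 1e-12))
})

test_that("dispersion trend handles degenerate and contaminated inputs", {
  expect_error(fit_dispersion_trend(1:5, rep(0.3, 5)), "at least 10")
  tr <- fit_dispersion_trend(seq(10, 500, length.out = 30), rep(0.3, 30))
  expect_equal(tr$c0, 0.3, tolerance = 1e-6)
  expect_equal(tr$c1, 0, tolerance = 1e-4)
  # gross outliers are trimmed on the second pass
  m <- exp(seq(log(2), log(2000), length.out = 60))
  d <- 0.2 + 5 / m
  d[1:3] <- d[1:3] * 100
  tr2 <- fit_dispersion_trend(m, d)
  expect_gt(tr2$n_trimmed, 0)
  expect_equal(tr2$c0, 0.2, tolerance = 0.05)
  expect_equal(tr2$c1, 5, tolerance = 0.5)
})

test_that("community model YAML serialization round-trips", {
  model <- builtin_community_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_community_model(model, path)
  back <- read_community_model(path)
  expect_equal(back$mean_mixture$weights, model$mean_mixture$weights, tolerance = 1e-9)
  expect_equal(back$mean_mixture$means, model$mean_mixture$means, tolerance = 1e-9)
  expect_equal(back$lfc_mixture$mean_coef, model$lfc_mixture$mean_coef, tolerance = 1e-9)
  expect_equal(back$lfc_mixture$sd_coef, model$lfc_mixture$sd_coef, tolerance = 1e-9)
  expect_equal(back$dispersion_trend$c0, model$dispersion_trend$c0)
  expect_identical(back$log_base, 2)

  other <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema = "something/else"), other)
  expect_error(read_community_model(other), "not a dapower")
})

test_that("a community model refit on its own simulation recovers parameters", {
  model <- builtin_community_model()
  sim <- simulate_community(model, 5000L, 60L, 60L, seed = 31L)
  fcm <- filter_low_abundance(sim$counts)
  est <- da_test(fcm)
  xy <- compute_taxon_summaries(est)
  mm <- fit_gmm(xy$x, 3L, seed = 9L)
  expect_equal(sort(mm$means), c(3, 6, 9), tolerance = 0.35)
  use <- est$tested & !est$at_boundary
  tr <- fit_dispersion_trend(est$base_mean[use], est$dispersion[use])
  # effective simulated curve is scale * (c0 + c1/m)
  expect_equal(tr$c0, 0.3 * 0.2, tolerance = 0.2 * 0.3 * 0.2 + 0.02)
  expect_equal(tr$c1, 0.3 * 5, tolerance = 0.2 * 0.3 * 5)
})
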
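test_that("size factors follow the median-of-ratios oracle", {
  # identical columns: all factors 1
  m <- matrix(rep(c(10L, 30L), 4), 2,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm <- count_matrix(m, rep(c("control", "treatment"), 2))
  expect_equal(unname(estimate_size_factors(cm)), rep(1, 4))

  # exact doubling: factors proportional to (1, 2)
  m2 <- matrix(c(10L, 20L, 10L, 20L, 30L, 60L, 30L, 60L), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm2 <- count_matrix(m2, rep(c("control", "treatment"), each = 2))
  s <- estimate_size_factors(cm2)
  expect_equal(unname(s[2] / s[1]), 2, tolerance = 1e-12)

  # hand-computed oracle: columns (10,30) and (20,60) give 1/sqrt(2), sqrt(2)
  m3 <- matrix(c(10L, 20L, 10L, 20L, 30L, 60L, 30L, 60L), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm3 <- count_matrix(m3, c("control", "treatment", "control", "treatment"))
  s3 <- estimate_size_factors(cm3)
  expect_equal(unname(s3), c(1 / sqrt(2), sqrt(2), 1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(exp(mean(log(s3))), 1, tolerance = 1e-12)

  # all-zero sample is an error
  m4 <- matrix(c(0L, 5L, 5L, 5L, 0L, 6L, 7L, 8L), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm4 <- count_matrix(m4, rep(c("control", "treatment"), 2))
  expect_error(estimate_size_factors(cm4), "all-zero")
})

test_that("dispersion MLE hits the Poisson boundary for constant and Poisson taxa", {
  cm <- one_taxon_cm(rep(7L, 8))
  d <- estimate_dispersions(cm, rep(1, 8))
  expect_equal(d$dispersion, 0)
  expect_true(d$at_boundary)

  set.seed(41)
  hits <- vapply(1:5, function(r) {
    cmp <- one_taxon_cm(rpois(400, 100))
    estimate_dispersions(cmp, rep(1, 400))$dispersion
  }, numeric(1))
  expect_true(all(hits < 0.05))
})

test_that("dispersion MLE recovers a genuine negative binomial dispersion", {
  set.seed(42)
  a_hat <- vapply(1:5, function(r) {
    cmn <- one_taxon_cm(rnbinom(1000, size = 2, mu = 100))  # alpha = 0.5
    estimate_dispersions(cmn, rep(1, 1000))$dispersion
  }, numeric(1))
  expect_true(all(a_hat > 0.35 & a_hat < 0.65))
})

test_that("Wald test respects group-relabel symmetry and flags untestable taxa", {
  cm <- tiny_cm(n_taxa = 20L, n_per_group = 10L, seed = 7L)
  cm$counts[3L, ] <- 0L  # all-zero taxon
  cm <- count_matrix(cm$counts, as.character(cm$group))
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf)
  res <- wald_test(cm, sf, disp)
  expect_false(res$tested[3L])
  expect_true(is.na(res$p_value[3L]) && is.na(res$q_value[3L]))
  # BH denominator excludes the flagged taxon
  expect_equal(res$q_value[res$tested],
               bh_adjust(res$p_value[res$tested]))

  flipped <- c("control" = "treatment", "treatment" = "control")
  cm2 <- count_matrix(cm$counts, unname(flipped[as.character(cm$group)]))
  res2 <- wald_test(cm2, sf, disp)
  expect_equal(res2$lfc_raw, -res$lfc_raw, tolerance = 1e-6)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-6)
})

test_that("null p-values are approximately uniform and strong effects are found", {
  # global null: rejection rate at p < 0.05 close to nominal
  set.seed(8)
  n <- 1000L
  m <- matrix(rnbinom(n * 60L, size = 5, mu = 80), n,
              dimnames = list(sprintf("t%04d", 1:n), sprintf("s%02d", 1:60)))
  cm <- count_matrix(m, rep(c("control", "treatment"), each = 30L))
  est <- da_test(cm)
  expect_lt(abs(mean(est$p_value < 0.05) - 0.05), 0.02)

  # 4-fold change at healthy abundance is essentially always detected
  set.seed(9)
  hits <- vapply(1:10, function(r) {
    k <- c(rnbinom(100, size = 10, mu = 100), rnbinom(100, size = 10, mu = 400))
    km <- rbind(k, matrix(rnbinom(5 * 200, size = 10, mu = 50), 5))
    rownames(km) <- c("fx", paste0("bg", 1:5)); colnames(km) <- paste0("s", 1:200)
    cmx <- count_matrix(km, rep(c("control", "treatment"), each = 100))
    ex <- da_test(cmx)
    ex$q_value[ex$taxon_id == "fx"] < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("LFC shrinkage pulls noisy estimates toward zero and keeps limits", {
  est <- data.frame(
    taxon_id = paste0("t", 1:5),
    base_mean = c(100, 50, 2, 80, 60),
    lfc_raw = c(2, 0, 8, -1.5, 0.6),
    lfc_shrunk = NA_real_,
    se_lfc = c(1e-8, 0.2, 6, 0.3, 0.1),
    dispersion = 0.1, p_value = 0.5, q_value = 0.5, tested = TRUE)
  sh <- shrink_lfc(est)
  expect_equal(sh$lfc_shrunk[1L], sh$lfc_raw[1L], tolerance = 1e-6)  # se -> 0
  expect_equal(sh$lfc_shrunk[2L], 0)                                 # zero raw
  expect_true(all(abs(sh$lfc_shrunk) <= abs(sh$lfc_raw) + 1e-12))
  expect_true(is.finite(sh$lfc_shrunk[3L]))                          # huge se
  expect_lt(abs(sh$lfc_shrunk[3L]), abs(sh$lfc_raw[3L]))
  expect_gte(attr(sh, "tau2"), 0.01)
})

test_that("a taxon observed in one group only stays finite after the pipeline", {
  set.seed(10)
  k <- c(rep(0L, 50), rnbinom(50, size = 5, mu = 60))
  km <- rbind(onegrp = k, matrix(rnbinom(6 * 100, size = 5, mu = 40), 6))
  rownames(km) <- c("onegrp", paste0("bg", 1:6)); colnames(km) <- paste0("s", 1:100)
  cm <- count_matrix(km, rep(c("control", "treatment"), each = 50))
  est <- da_test(cm)
  row <- est[est$taxon_id == "onegrp", ]
  expect_true(is.finite(row$lfc_raw) && is.finite(row$lfc_shrunk))
  expect_lt(abs(row$lfc_shrunk), abs(row$lfc_raw))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))  # n counts non-NA
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (r in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_identical(bh_adjust(p), bh_brute(p))
  }
  # q-values never below p-values
  set.seed(12)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})
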
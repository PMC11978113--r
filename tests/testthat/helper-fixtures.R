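# Shared fixtures, all built in code.

# small valid count matrix with both groups
tiny_cm <- function(n_taxa = 6L, n_per_group = 4L, seed = 1L, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * 2L * n_per_group, lambda), nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(2L * n_per_group))))
  count_matrix(m, rep(c("control", "treatment"), each = n_per_group))
}

# single-taxon count matrix from given per-sample counts (split half/half)
one_taxon_cm <- function(k) {
  n <- length(k)
  m <- matrix(k, nrow = 1L,
              dimnames = list("t1", paste0("s", seq_len(n))))
  count_matrix(m, rep(c("control", "treatment"), c(ceiling(n / 2), floor(n / 2))))
}

# independent brute-force BH oracle: for each p_i, the minimum over all
# observed p_j >= p_i of n * p_j / rank(p_j), capped at 1 (O(n^2) definition,
# no cummin shortcut)
bh_brute <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(n), function(i) {
    cand <- n * p[p >= p[i]] / r[p >= p[i]]
    min(c(cand, 1))
  }, numeric(1))
}

# a simple hand-built community model for simulator tests (single component
# everywhere so moments are easy to reason about)
point_model <- function(log2_mean = log2(50), lfc_mean = 0, lfc_sd = 0.3,
                        c0 = 1, c1 = 0, scale = 0.3) {
  mm <- structure(list(weights = 1, means = log2_mean, sds = 1e-9, K = 1L),
                  class = "mean_mixture")
  lf <- structure(list(K = 1L, weights = 1, lambda = 0,
                       variance_form = "linear", degree = 1L,
                       mean_coef = rbind(c(lfc_mean, 0)),
                       sd_coef = rbind(c(log(lfc_sd), 0))),
                  class = "lfc_mixture")
  dt <- structure(list(c0 = c0, c1 = c1, scale = scale,
                       n_used = NA_integer_, n_trimmed = NA_integer_),
                  class = "dispersion_trend")
  community_model(mm, lf, dt)
}

# power_outcomes table drawn from a known logistic detection surface
synthetic_outcomes <- function(n, beta0 = -3, b1 = 0.3, b2 = 1.5, seed = 1L) {
  set.seed(seed)
  x1 <- runif(n, 0, 12)
  x2 <- runif(n, 0, 4)
  p <- plogis(beta0 + b1 * x1 + b2 * x2)
  oc <- data.frame(sim = 1L, taxon_id = as.character(seq_len(n)),
                   x1 = x1, x2 = x2, y = rbinom(n, 1L, p), q_value = NA_real_)
  attr(oc, "alpha_sig") <- 0.1
  class(oc) <- c("power_outcomes", "data.frame")
  oc
}

# grid monotonicity violations of a fitted surface (negative steps beyond
# floating-point slack)
count_monotonicity_violations <- function(surface, grid_n = 20L, tol = 1e-8) {
  g1 <- seq(surface$box$x1[1L], surface$box$x1[2L], length.out = grid_n)
  g2 <- seq(surface$box$x2[1L], surface$box$x2[2L], length.out = grid_n)
  Z <- matrix(predict(surface, rep(g1, grid_n), rep(g2, each = grid_n)), grid_n)
  sum(apply(Z, 2L, diff) < -tol) + sum(apply(t(Z), 2L, diff) < -tol)
}

expect_trace_nondecreasing <- function(trace, tol = 1e-8) {
  expect_true(all(diff(trace) >= -tol * (abs(trace[-length(trace)]) + 1)))
}
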
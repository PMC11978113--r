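# Simulation of case-control count matrices from a community model:
#   1. draw log mean abundance x_t from the mean mixture;
#   2. draw log fold change y_t from the LFC mixture conditional on x_t;
#   3. predict the dispersion d_t = scale * (c0 + c1 / M_t), M_t = base^x_t;
#   4. split M_t into group means that preserve the arithmetic mean;
#   5. draw counts from NB(mean = mu_group, dispersion = d_t) per sample.
# Counts use rnbinom(mu, size = 1/alpha), i.e. prob = size / (size + mu);
# alpha = 0 falls back to Poisson. Size factors are identically 1 unless
# lognormal library-size variation is switched on.

#' Split an overall mean into group means at a given fold change
#'
#' With fold change FC = 2^lfc (treatment over control), the control and
#' treatment means are `2M / (1 + FC)` and `2M FC / (1 + FC)`, so their
#' arithmetic mean is exactly the overall mean M.
#'
#' @param M overall mean abundance (positive; vectorised).
#' @param lfc log2 fold change (vectorised).
#' @return List with `mu_control` and `mu_treatment`.
#' @export
group_means <- function(M, lfc) {
  if (any(M <= 0)) stop("overall mean M must be positive", call. = FALSE)
  fc <- 2^lfc
  list(mu_control = 2 * M / (1 + fc), mu_treatment = 2 * M * fc / (1 + fc))
}

rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a case-control cohort from a community model
#'
#' Draws `n_taxa` independent taxa via the five-step procedure above and
#' returns the counts together with the ground-truth parameters that
#' generated them. One master seed drives deterministic sub-seeds per stage
#' so the whole draw is reproducible.
#'
#' @param model a `community_model`.
#' @param n_taxa number of taxa.
#' @param n_control,n_treatment samples per group (each at least 2).
#' @param seed integer seed.
#' @param force_lfc optional numeric scalar or length-`n_taxa` vector that
#'   overrides the drawn log fold changes (used for null calibration, e.g.
#'   `force_lfc = 0`).
#' @param library_size_sd standard deviation (log scale) of optional
#'   lognormal library-size multipliers; 0 (default) keeps all size factors
#'   at 1, matching the generative model.
#' @return A `simulated_dataset`: list with `counts` (a [count_matrix()]),
#'   `truth` (data.frame `taxon_id`, `x` = log2 M, `M`, `lfc`, `dispersion`,
#'   `mu_control`, `mu_treatment`), `seed`, and `model`.
#' @export
simulate_community <- function(model, n_taxa, n_control, n_treatment, seed = 1L,
                               force_lfc = NULL, library_size_sd = 0) {
  stopifnot(inherits(model, "community_model"), n_taxa >= 1L,
            n_control >= 2L, n_treatment >= 2L)
  lb <- model$log_base
  set.seed(sub_seed(seed, 1L))
  x <- rgmm(n_taxa, model$mean_mixture)
  set.seed(sub_seed(seed, 2L))
  y <- rlfc(x, model$lfc_mixture)
  if (!is.null(force_lfc)) y <- rep_len(as.numeric(force_lfc), n_taxa)
  M <- pmax(lb^x, 1e-6)
  d <- predict_dispersion(model$dispersion_trend, M)
  gm <- group_means(M, y * log2(lb))   # lfc stored in log2 units
  sfac <- rep(1, n_control + n_treatment)
  if (library_size_sd > 0) {
    set.seed(sub_seed(seed, 3L))
    sfac <- exp(stats::rnorm(n_control + n_treatment, 0, library_size_sd))
    sfac <- sfac / geometric_mean(sfac)
  }
  counts <- matrix(0L, n_taxa, n_control + n_treatment)
  set.seed(sub_seed(seed, 4L))
  for (i in seq_len(n_taxa)) {
    counts[i, ] <- c(rnb(n_control, gm$mu_control[i] * sfac[seq_len(n_control)], d[i]),
                     rnb(n_treatment,
                         gm$mu_treatment[i] * sfac[n_control + seq_len(n_treatment)],
                         d[i]))
  }
  ids <- sprintf("taxon%05d", seq_len(n_taxa))
  rownames(counts) <- ids
  colnames(counts) <- c(sprintf("ctrl_%03d", seq_len(n_control)),
                        sprintf("trt_%03d", seq_len(n_treatment)))
  cm <- count_matrix(counts, rep(c("control", "treatment"),
                                 c(n_control, n_treatment)))
  truth <- data.frame(taxon_id = ids, x = log2(M), M = M,
                      lfc = y * log2(lb), dispersion = d,
                      mu_control = gm$mu_control, mu_treatment = gm$mu_treatment,
                      stringsAsFactors = FALSE)
  structure(list(counts = cm, truth = truth, seed = seed, model = model),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset (seed", x$seed, ")\n")
  print(x$counts)
  cat(sprintf("  truth: median M = %.1f, median |lfc| = %.2f, median dispersion = %.3f\n",
              stats::median(x$truth$M), stats::median(abs(x$truth$lfc)),
              stats::median(x$truth$dispersion)))
  invisible(x)
}

#' Write a simulated dataset (counts, metadata, truth) as TSV files
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the three paths.
#' @export
write_simulated_dataset <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, paste0(prefix, "_counts.tsv"))
  mp <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_counts(sim$counts, cp, mp)
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cp, metadata = mp, truth = tp))
}

ks_statistic <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  max(abs(Fa - Fb))
}

#' Compare per-taxon mean and variance distributions of two count matrices
#'
#' Self-consistency check of the simulator: per-taxon means and variances of
#' the observed and simulated tables are compared on the log2 scale via the
#' two-sample Kolmogorov-Smirnov statistic and a quantile-quantile table.
#'
#' @param real,sim two [count_matrix()] objects (taxa need not match).
#' @param probs quantiles reported in the QQ table.
#' @return A `distribution_comparison`: `ks_mean`, `ks_variance`, `qq`
#'   (data.frame of quantiles), and the underlying log-scale summaries.
#' @export
compare_distributions <- function(real, sim, probs = seq(0.1, 0.9, by = 0.1)) {
  lm_r <- log2(rowMeans(real$counts)); lm_s <- log2(rowMeans(sim$counts))
  lv_r <- log2(apply(real$counts, 1L, stats::var))
  lv_s <- log2(apply(sim$counts, 1L, stats::var))
  lm_r <- lm_r[is.finite(lm_r)]; lm_s <- lm_s[is.finite(lm_s)]
  lv_r <- lv_r[is.finite(lv_r)]; lv_s <- lv_s[is.finite(lv_s)]
  qq <- data.frame(prob = probs,
                   mean_real = stats::quantile(lm_r, probs, names = FALSE),
                   mean_sim = stats::quantile(lm_s, probs, names = FALSE),
                   var_real = stats::quantile(lv_r, probs, names = FALSE),
                   var_sim = stats::quantile(lv_s, probs, names = FALSE))
  structure(list(ks_mean = ks_statistic(lm_r, lm_s),
                 ks_variance = ks_statistic(lv_r, lv_s),
                 qq = qq,
                 log_means = list(real = lm_r, sim = lm_s),
                 log_variances = list(real = lv_r, sim = lv_s)),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("distribution_comparison: KS(log2 mean) = %.3f, KS(log2 variance) = %.3f\n",
              x$ks_mean, x$ks_variance))
  print(round(x$qq, 3), row.names = FALSE)
  invisible(x)
}

#' Density plot of observed vs simulated log2 taxon means
#' @param x a `distribution_comparison`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.distribution_comparison <- function(x, ...) {
  dr <- stats::density(x$log_means$real)
  ds <- stats::density(x$log_means$sim)
  graphics::plot(dr, lty = 2, main = "Per-taxon log2 mean abundance",
                 xlab = "log2 mean count",
                 ylim = c(0, max(dr$y, ds$y)), ...)
  graphics::lines(ds, col = "firebrick")
  graphics::legend("topright", legend = c("observed", "simulated"),
                   lty = c(2, 1), col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Built-in reference community model
#'
#' A documented, fixed model used by the fixture generator and examples:
#' three mean-abundance components spanning rare to abundant taxa
#' (weights 0.45/0.35/0.20 at log2 means 3/6/9), a two-component LFC
#' mixture centred at zero — a tight bulk of near-null taxa plus a
#' heavier-tailed minority carrying detectable effects, both with log-sd
#' decreasing in abundance — and dispersion trend c0 = 0.2, c1 = 5 with
#' scale 0.3.
#'
#' @return A `community_model`.
#' @export
builtin_community_model <- function() {
  mm <- structure(list(weights = c(0.45, 0.35, 0.20), means = c(3, 6, 9),
                       sds = c(1.2, 1.0, 0.8), K = 3L),
                  class = "mean_mixture")
  lf <- structure(list(K = 2L, weights = c(0.7, 0.3), lambda = c(0, log(0.3 / 0.7)),
                       variance_form = "linear", degree = 1L,
                       mean_coef = rbind(c(0, 0), c(0, 0)),
                       sd_coef = rbind(c(-0.5, -0.05), c(0.8, -0.05))),
                  class = "lfc_mixture")
  dt <- structure(list(c0 = 0.2, c1 = 5, scale = 0.3,
                       n_used = NA_integer_, n_trimmed = NA_integer_),
                  class = "dispersion_trend")
  community_model(mm, lf, dt, log_base = 2)
}

#' Generate a synthetic pilot dataset with known truth
#'
#' Draws a cohort from [builtin_community_model()] and writes counts,
#' metadata and truth TSVs — a self-contained stand-in for pilot data in
#' examples and tests.
#'
#' @param dir output directory.
#' @param n_taxa,n_per_group design (defaults 500 taxa, 50 per group).
#' @param seed integer seed.
#' @return Invisibly, the written paths (as from [write_simulated_dataset()]).
#' @export
make_fixture_dataset <- function(dir, n_taxa = 500L, n_per_group = 50L,
                                 seed = 1L) {
  sim <- simulate_community(builtin_community_model(), n_taxa,
                            n_per_group, n_per_group, seed = seed)
  write_simulated_dataset(sim, dir, prefix = "pilot")
}
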
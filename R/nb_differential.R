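# Negative binomial differential abundance engine.
#
# Model per taxon i and sample j:
#   K_ij ~ NB(mean = mu_ij, dispersion = alpha_i),  mu_ij = s_j * q_{i,g(j)},
#   var(K_ij) = mu_ij + alpha_i * mu_ij^2,
# with s_j a per-sample size factor and g(j) the sample's group. The group
# effect is tested with a Wald statistic on log(q_treatment / q_control).

Q_FLOOR <- 1e-8  # lower bound on fitted group means (log scale), keeps
                 # one-group-only taxa finite with an honestly huge SE

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each taxon's reference is the
#' geometric mean of its positive counts, and a sample's size factor is the
#' median of its count-to-reference ratios over taxa with a positive count
#' in that sample (the positive-counts variant, which stays defined on
#' sparse ASV tables). Factors are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()], normally already filtered.
#' @return Numeric vector of positive size factors, one per sample, with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(cm) {
  validate_count_matrix(cm)
  counts <- cm$counts
  if (any(colSums(counts) == 0)) {
    bad <- cm$sample_ids[colSums(counts) == 0][1L]
    stop(sprintf("sample '%s' has all-zero counts", bad), call. = FALSE)
  }
  logref <- apply(counts, 1L, function(k) mean(log(k[k > 0])))
  usable <- is.finite(logref)
  if (!any(usable)) stop("no taxon with positive counts", call. = FALSE)
  lc <- log(counts[usable, , drop = FALSE])
  s <- vapply(seq_len(ncol(counts)), function(j) {
    r <- lc[, j] - logref[usable]
    exp(stats::median(r[is.finite(r)]))
  }, numeric(1))
  s <- s / geometric_mean(s)
  names(s) <- cm$sample_ids
  s
}

# Profile MLE of the group mean q (log scale) for one taxon/group at fixed
# dispersion alpha, by Fisher scoring on phi = log q. Returns phi-hat.
nb_fit_group_mean <- function(k, s, alpha) {
  mom <- mean(k / s)
  if (mom <= Q_FLOOR) return(log(Q_FLOOR))
  phi <- log(mom)
  lo <- log(Q_FLOOR)
  for (it in 1:50) {
    mu <- s * exp(phi)
    u <- sum((k - mu) / (1 + alpha * mu))
    w <- sum(mu / (1 + alpha * mu))
    step <- u / w
    step <- max(min(step, 5), -5)
    phi <- max(phi + step, lo)
    if (abs(step) < 1e-10 || phi <= lo) break
  }
  phi
}

nb_loglik_group <- function(k, s, alpha, phi) {
  mu <- pmax(s * exp(phi), 1e-12)
  if (alpha < 1e-10) return(sum(stats::dpois(k, mu, log = TRUE)))
  sum(stats::dnbinom(k, size = 1 / alpha, mu = mu, log = TRUE))
}

# Profile log-likelihood in alpha for one taxon (both group means profiled out)
nb_profile_ll <- function(alpha, k_c, s_c, k_t, s_t) {
  pc <- nb_fit_group_mean(k_c, s_c, alpha)
  pt <- nb_fit_group_mean(k_t, s_t, alpha)
  nb_loglik_group(k_c, s_c, alpha, pc) + nb_loglik_group(k_t, s_t, alpha, pt)
}

#' Per-taxon maximum likelihood dispersion estimates
#'
#' For each taxon, maximises the profile likelihood of the NB model with
#' group-specific means over the dispersion alpha in \[1e-8, 50\] (search on
#' the log scale). Taxa whose likelihood is maximised at the lower boundary
#' are reported as alpha = 0 (the Poisson limit) and flagged.
#'
#' @param cm a filtered [count_matrix()].
#' @param sf size factors from [estimate_size_factors()].
#' @param alpha_max upper search bound for the dispersion.
#' @return data.frame with columns `taxon_id`, `dispersion`, `at_boundary`.
#' @export
estimate_dispersions <- function(cm, sf, alpha_max = 50) {
  validate_count_matrix(cm)
  stopifnot(length(sf) == ncol(cm$counts), all(sf > 0))
  ic <- cm$group == "control"
  s_c <- sf[ic]; s_t <- sf[!ic]
  lo <- log(1e-8); hi <- log(alpha_max)
  res <- t(vapply(seq_len(nrow(cm$counts)), function(i) {
    k <- cm$counts[i, ]
    k_c <- k[ic]; k_t <- k[!ic]
    if (stats::var(k / sf) < 1e-12) return(c(0, 1))  # constant: Poisson limit
    f <- function(la) -nb_profile_ll(exp(la), k_c, s_c, k_t, s_t)
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-4)
    a_hat <- exp(opt$minimum)
    ll_hat <- -opt$objective
    ll_lo <- nb_profile_ll(1e-8, k_c, s_c, k_t, s_t)
    if (a_hat < 1e-6 || ll_lo >= ll_hat - 1e-8) c(0, 1) else c(a_hat, 0)
  }, numeric(2)))
  data.frame(taxon_id = cm$taxon_ids, dispersion = res[, 1L],
             at_boundary = res[, 2L] == 1, stringsAsFactors = FALSE)
}

#' Wald test of the group effect for every taxon
#'
#' Fits, per taxon, the NB generalised linear model with a log link, the
#' group indicator as the single covariate and log size factors as offset,
#' at the fixed dispersion estimate. With the saturated two-group design the
#' maximum likelihood group means have a one-dimensional score each; the
#' Wald statistic is the log fold change over its standard error from the
#' Fisher information, and the p-value the two-sided normal tail.
#'
#' @param cm a filtered [count_matrix()].
#' @param sf size factors.
#' @param dispersions data.frame from [estimate_dispersions()].
#' @return data.frame of per-taxon estimates: `taxon_id`, `base_mean` (mean
#'   normalised count), `lfc_raw` (log2 treatment vs control), `se_lfc`
#'   (log2 scale), `dispersion`, `p_value`, `q_value` (BH-adjusted),
#'   `tested` (FALSE for all-zero taxa, which get NA p and q and are
#'   excluded from the BH denominator).
#' @export
wald_test <- function(cm, sf, dispersions) {
  validate_count_matrix(cm)
  stopifnot(identical(dispersions$taxon_id, cm$taxon_ids))
  ic <- cm$group == "control"
  s_c <- sf[ic]; s_t <- sf[!ic]
  n <- nrow(cm$counts)
  base_mean <- lfc <- se <- pval <- numeric(n)
  tested <- rep(TRUE, n)
  for (i in seq_len(n)) {
    k <- cm$counts[i, ]
    base_mean[i] <- mean(k / sf)
    if (all(k == 0)) {
      tested[i] <- FALSE
      lfc[i] <- se[i] <- pval[i] <- NA_real_
      next
    }
    a <- dispersions$dispersion[i]
    phi_c <- nb_fit_group_mean(k[ic], s_c, a)
    phi_t <- nb_fit_group_mean(k[!ic], s_t, a)
    mu_c <- s_c * exp(phi_c); mu_t <- s_t * exp(phi_t)
    w_c <- sum(mu_c / (1 + a * mu_c)); w_t <- sum(mu_t / (1 + a * mu_t))
    b1 <- phi_t - phi_c                       # natural-log effect
    se_b1 <- sqrt(1 / w_c + 1 / w_t)
    lfc[i] <- b1 / log(2)
    se[i] <- se_b1 / log(2)
    pval[i] <- 2 * stats::pnorm(-abs(b1) / se_b1)
  }
  qval <- rep(NA_real_, n)
  qval[tested] <- bh_adjust(pval[tested])
  data.frame(taxon_id = cm$taxon_ids, base_mean = base_mean, lfc_raw = lfc,
             lfc_shrunk = NA_real_, se_lfc = se,
             dispersion = dispersions$dispersion, p_value = pval,
             q_value = qval, tested = tested, stringsAsFactors = FALSE)
}

#' Empirical-Bayes shrinkage of log fold changes
#'
#' Normal prior N(0, tau^2) on the true log2 fold change, with tau^2
#' estimated by moments: the between-taxon variance of raw LFCs in excess
#' of their mean squared standard error, floored at 0.01. Each posterior
#' mean is `lfc_raw * tau^2 / (tau^2 + se^2)`, so noisy estimates from
#' low-abundance taxa are pulled towards zero while precise ones are left
#' nearly unchanged.
#'
#' @param estimates data.frame from [wald_test()].
#' @return The same data.frame with `lfc_shrunk` filled in (0 for untested
#'   taxa); the prior variance is stored in `attr(, "tau2")`.
#' @export
shrink_lfc <- function(estimates) {
  ok <- estimates$tested & is.finite(estimates$lfc_raw) & is.finite(estimates$se_lfc)
  tau2 <- max(0.01, stats::var(estimates$lfc_raw[ok]) - mean(estimates$se_lfc[ok]^2))
  estimates$lfc_shrunk <- ifelse(ok,
    estimates$lfc_raw * tau2 / (tau2 + estimates$se_lfc^2), 0)
  attr(estimates, "tau2") <- tau2
  estimates
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate correction with monotonicity enforcement:
#' q_(i) = min over j >= i of n * p_(j) / j, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NAs are propagated.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pv)
  if (n == 0L) return(out)
  o <- order(pv)
  q <- pv[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  res <- numeric(n)
  res[o] <- q
  out[ok] <- res
  out
}

#' Full differential abundance pipeline
#'
#' Convenience wrapper: size factors, dispersion estimation, Wald test and
#' LFC shrinkage in one call.
#'
#' @param cm a filtered [count_matrix()].
#' @return The per-taxon estimates data.frame (see [wald_test()]) with
#'   shrunken LFCs; size factors in `attr(, "size_factors")`.
#' @export
da_test <- function(cm) {
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf)
  est <- shrink_lfc(wald_test(cm, sf, disp))
  est$at_boundary <- disp$at_boundary
  attr(est, "size_factors") <- sf
  est
}

#' Write a differential abundance result table as TSV
#' @param estimates data.frame from [da_test()] or [shrink_lfc()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_da_results <- function(estimates, path) {
  cols <- c("taxon_id", "base_mean", "lfc_raw", "lfc_shrunk", "se_lfc",
            "dispersion", "p_value", "q_value")
  utils::write.table(estimates[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
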
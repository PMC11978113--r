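# Univariate Gaussian mixtures for the log mean abundance distribution.
# EM with k-means-seeded restarts; the number of components is chosen by a
# sequential parametric-bootstrap likelihood-ratio test.

#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum likelihood fit of a K-component Gaussian mixture. EM runs from
#' `n_restarts` k-means-seeded starts to convergence (relative log-likelihood
#' change below `tol` or `max_iter` iterations) and keeps the best; a start
#' whose components collapse (sd below 1e-6) is discarded and retried.
#'
#' @param x numeric data vector, length at least `5 * K`.
#' @param K number of components.
#' @param seed integer seed controlling the k-means starts.
#' @param n_restarts number of EM starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per start.
#' @return List with `weights`, `means`, `sds`, `loglik`, `K`, `n_iter`, and
#'   `ll_trace` (the per-iteration log-likelihood of the winning start, which
#'   is non-decreasing).
#' @export
fit_gmm <- function(x, K, seed = 1L, n_restarts = 5L, tol = 1e-8,
                    max_iter = 500L) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)))
  if (length(x) < 5 * K) stop("need at least 5*K observations", call. = FALSE)
  if (K == 1L) {
    sdml <- sqrt(mean((x - mean(x))^2))
    ll <- sum(stats::dnorm(x, mean(x), sdml, log = TRUE))
    return(list(weights = 1, means = mean(x), sds = sdml, loglik = ll,
                K = 1L, n_iter = 0L, ll_trace = ll))
  }
  best <- NULL
  attempts <- 0L
  r <- 0L
  while (r < n_restarts && attempts < 4L * n_restarts) {
    attempts <- attempts + 1L
    set.seed(sub_seed(seed, attempts))
    km <- tryCatch(stats::kmeans(x, centers = K, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km)) next
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / length(x)
    mu <- as.numeric(km$centers)
    sd0 <- vapply(seq_len(K), function(k) {
      xk <- x[km$cluster == k]
      s <- if (length(xk) > 1L) stats::sd(xk) else 0
      max(s, stats::sd(x) / (4 * K), 1e-3)
    }, numeric(1))
    fit <- gmm_em_run(x, w, mu, sd0, tol, max_iter)
    if (is.null(fit)) next  # collapsed: restart
    r <- r + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts collapsed", call. = FALSE)
  best$K <- K
  best
}

gmm_em_run <- function(x, w, mu, sdv, tol, max_iter) {
  fit <- .gmm_em_cpp(x, w, mu, sdv, tol, max_iter)
  if (isTRUE(fit$collapsed)) return(NULL)
  list(weights = fit$weights, means = fit$means, sds = fit$sds,
       loglik = fit$ll_trace[fit$n_iter], n_iter = fit$n_iter,
       ll_trace = fit$ll_trace)
}

#' Draw from a fitted Gaussian mixture
#' @param n number of draws.
#' @param fit a mixture as returned by [fit_gmm()] (or the `mean_mixture`
#'   element of a community model).
#' @return Numeric vector of length `n`.
#' @export
rgmm <- function(n, fit) {
  z <- sample.int(length(fit$weights), n, replace = TRUE, prob = fit$weights)
  stats::rnorm(n, fit$means[z], fit$sds[z])
}

gmm_loglik <- function(x, fit) {
  K <- length(fit$weights)
  lmat <- vapply(seq_len(K), function(k)
    log(fit$weights[k]) + stats::dnorm(x, fit$means[k], fit$sds[k], log = TRUE),
    numeric(length(x)))
  if (K == 1L) sum(lmat) else sum(row_logsumexp(lmat))
}

#' Choose the mixture order by sequential parametric-bootstrap LRT
#'
#' For k = 1, 2, ... the k- and (k+1)-component mixtures are fitted and the
#' observed likelihood-ratio statistic 2 (loglik_{k+1} - loglik_k) is
#' compared against its null distribution obtained from `B` parametric
#' bootstrap datasets simulated from the fitted k-component model, refitting
#' both orders on each. The bootstrap p-value uses the +1 correction,
#' p = (1 + #\{T_b >= T_obs\}) / (B_ok + 1). Testing stops at the first
#' p above `level` (that k is selected) or at `K_max`.
#'
#' @param x numeric data vector.
#' @param K_max largest order considered.
#' @param B bootstrap replicates per test.
#' @param level significance threshold of each LRT.
#' @param seed integer seed; the whole procedure is reproducible given it.
#' @param n_restarts EM restarts for fits on the observed data (bootstrap
#'   refits use 2).
#' @return A `mean_mixture` object: the selected fit plus a `selection`
#'   data.frame recording each test (k, loglik of both orders, observed
#'   statistic, B used, p-value).
#' @export
select_components_bootstrap <- function(x, K_max = 5L, B = 100L, level = 0.05,
                                        seed = 1L, n_restarts = 5L) {
  stopifnot(all(is.finite(x)), K_max >= 1L)
  # The fitting procedure is part of the LRT statistic: observed and
  # bootstrap statistics use the same restart/iteration budget, otherwise
  # the observed statistic is systematically larger than its reference
  # distribution and the test over-selects components.
  b_restarts <- 2L; b_tol <- 1e-6; b_iter <- 120L
  fit_stat <- function(xx, k, sd_) {
    fit_gmm(xx, k, seed = sd_, n_restarts = b_restarts, tol = b_tol,
            max_iter = b_iter)
  }
  fits <- vector("list", K_max)
  fits[[1L]] <- fit_stat(x, 1L, sub_seed(seed, 1L))
  sel <- data.frame(k = integer(), loglik_null = numeric(), loglik_alt = numeric(),
                    statistic = numeric(), B = integer(), p_value = numeric())
  chosen <- 1L
  if (K_max > 1L) {
    for (k in seq_len(K_max - 1L)) {
      fits[[k + 1L]] <- fit_stat(x, k + 1L, sub_seed(seed, k + 1L))
      t_obs <- 2 * (fits[[k + 1L]]$loglik - fits[[k]]$loglik)
      t_boot <- rep(NA_real_, B)
      for (b in seq_len(B)) {
        bs <- sub_seed(seed, 100L + 97L * k + b)
        set.seed(bs)
        xb <- rgmm(length(x), fits[[k]])
        t_boot[b] <- tryCatch({
          f0 <- fit_stat(xb, k, bs)
          f1 <- fit_stat(xb, k + 1L, bs + 1L)
          2 * (f1$loglik - f0$loglik)
        }, error = function(e) NA_real_)
      }
      ok <- is.finite(t_boot)
      if (mean(ok) < 0.8) {
        stop(sprintf("bootstrap LRT for k = %d: %d%% of replicates failed to fit",
                     k, round(100 * mean(!ok))), call. = FALSE)
      }
      pval <- (1 + sum(t_boot[ok] >= t_obs)) / (sum(ok) + 1)
      sel <- rbind(sel, data.frame(k = k, loglik_null = fits[[k]]$loglik,
                                   loglik_alt = fits[[k + 1L]]$loglik,
                                   statistic = t_obs, B = sum(ok), p_value = pval))
      if (pval > level) { chosen <- k; break }
      chosen <- k + 1L
    }
  }
  # final fit of the selected order at full precision
  out <- fit_gmm(x, chosen, seed = sub_seed(seed, chosen), n_restarts = n_restarts)
  out$selection <- sel
  out$level <- level
  class(out) <- "mean_mixture"
  out
}

#' @export
print.mean_mixture <- function(x, ...) {
  cat(sprintf("mean_mixture: %d Gaussian component(s)\n", x$K))
  print(data.frame(weight = round(x$weights, 3), mean = round(x$means, 3),
                   sd = round(x$sds, 3)))
  if (!is.null(x$selection) && nrow(x$selection) > 0L) {
    cat("bootstrap LRT selection:\n")
    print(x$selection, row.names = FALSE)
  }
  invisible(x)
}
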
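# Conditional Gaussian mixture for log fold change given log mean abundance:
#   y | x ~ sum_i pi_i N(m_i0 + m_i1 x, sigma_i(x)^2),
#   sigma_i(x) = exp(f_i(x)),  f_i linear or quadratic in x,
#   pi_i = exp(lambda_i) / sum_k exp(lambda_k), lambda_1 = 0.
# Fitted by ECM: responsibilities, then weights, then weighted least squares
# for the mean lines at the current variances, then per-component BFGS for
# the log-sd coefficients. Order and variance form are chosen by AIC.

F_CLAMP <- 20  # |f_i(x)| bound; keeps exp(2f) finite during optimisation

lfc_sd_design <- function(x, degree) {
  if (degree == 1L) cbind(1, x) else cbind(1, x, x^2)
}

lfc_component_logdens <- function(x, y, mcoef, gcoef, Xs) {
  mu <- mcoef[1L] + mcoef[2L] * x
  f <- pmin(pmax(drop(Xs %*% gcoef), -F_CLAMP), F_CLAMP)
  stats::dnorm(y, mu, exp(f), log = TRUE)
}

lfc_mix_loglik <- function(x, y, fit) {
  Xs <- lfc_sd_design(x, fit$degree)
  lmat <- vapply(seq_len(fit$K), function(i)
    log(fit$weights[i]) +
      lfc_component_logdens(x, y, fit$mean_coef[i, ], fit$sd_coef[i, ], Xs),
    numeric(length(x)))
  if (fit$K == 1L) sum(lmat) else sum(row_logsumexp(lmat))
}

# one ECM run from given responsibilities; returns NULL on collapse
lfc_em_run <- function(x, y, resp, degree, tol = 1e-8, max_iter = 300L) {
  n <- length(x); K <- ncol(resp)
  Xm <- cbind(1, x)
  Xs <- lfc_sd_design(x, degree)
  p <- degree + 1L
  mcoef <- matrix(0, K, 2L)
  gcoef <- matrix(0, K, p)
  # init from responsibilities: OLS mean line, constant log-sd
  for (i in seq_len(K)) {
    wls <- stats::lm.wfit(Xm, y, pmax(resp[, i], 1e-10))
    mcoef[i, ] <- wls$coefficients
    s2 <- sum(resp[, i] * wls$residuals^2) / sum(resp[, i])
    gcoef[i, 1L] <- 0.5 * log(max(s2, 1e-8))
  }
  w <- pmax(colMeans(resp), 1e-8); w <- w / sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lmat <- vapply(seq_len(K), function(i)
      log(w[i]) + lfc_component_logdens(x, y, mcoef[i, ], gcoef[i, ], Xs),
      numeric(n))
    lse <- if (K == 1L) drop(lmat) else row_logsumexp(lmat)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (!is.finite(ll)) return(NULL)
    resp <- exp(lmat - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-6) || any(nk < 3)) return(NULL)
    w <- nk / n
    for (i in seq_len(K)) {
      f <- pmin(pmax(drop(Xs %*% gcoef[i, ]), -F_CLAMP), F_CLAMP)
      wls <- stats::lm.wfit(Xm, y, resp[, i] * exp(-2 * f))
      mcoef[i, ] <- wls$coefficients
      mu <- drop(Xm %*% mcoef[i, ])
      r2 <- (y - mu)^2
      ri <- resp[, i]
      negQ <- function(g) {
        fg <- pmin(pmax(drop(Xs %*% g), -F_CLAMP), F_CLAMP)
        sum(ri * (fg + 0.5 * r2 * exp(-2 * fg)))
      }
      negQg <- function(g) {
        fg <- pmin(pmax(drop(Xs %*% g), -F_CLAMP), F_CLAMP)
        drop(crossprod(Xs, ri * (1 - r2 * exp(-2 * fg))))
      }
      opt <- tryCatch(
        stats::optim(gcoef[i, ], negQ, negQg, method = "BFGS",
                     control = list(maxit = 50)),
        error = function(e) NULL)
      if (!is.null(opt) && opt$value <= negQ(gcoef[i, ]) + 1e-10) {
        gcoef[i, ] <- opt$par
      }
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(weights = w, mean_coef = mcoef, sd_coef = gcoef, loglik = trace[length(trace)],
       n_iter = length(trace), ll_trace = trace, K = K, degree = degree)
}

lfc_init_resp <- function(x, y, K, seed) {
  n <- length(x)
  if (K == 1L) return(matrix(1, n, 1L))
  r <- stats::lm.fit(cbind(1, x), y)$residuals
  set.seed(seed)
  km <- stats::kmeans(cbind(scale(r), 0.2 * scale(x)), centers = K, nstart = 3L)
  resp <- matrix(1e-3, n, K)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  resp / rowSums(resp)
}

#' Fit the conditional log fold change mixture
#'
#' For every order in `K_range` and both variance forms (log-sd linear or
#' quadratic in log mean abundance) the conditional mixture is fitted by EM;
#' the (order, form) pair with minimum AIC is returned. The parameter count
#' is (K - 1) mixing parameters + 2K mean coefficients + K (degree + 1)
#' log-sd coefficients.
#'
#' @param x log2 mean abundance per taxon.
#' @param y (shrunken) log2 fold change per taxon.
#' @param K_range candidate component numbers.
#' @param variance_forms subset of `c("linear", "quadratic")`.
#' @param seed integer seed for the k-means initialisations.
#' @param n_restarts EM starts per candidate.
#' @return An `lfc_mixture` object: `K`, `weights`, `lambda` (log-odds
#'   mixing parameters, first fixed at 0), `mean_coef` (K x 2), `sd_coef`
#'   (K x (degree+1)), `variance_form`, `aic`, `loglik`, `ll_trace`, and the
#'   AIC table of all candidates.
#' @export
fit_lfc_mixture <- function(x, y, K_range = 1:5,
                            variance_forms = c("linear", "quadratic"),
                            seed = 1L, n_restarts = 3L) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 50) stop("need at least 50 taxa to fit the LFC mixture",
                           call. = FALSE)
  cand <- expand.grid(K = K_range, form = variance_forms,
                      stringsAsFactors = FALSE)
  tab <- data.frame(K = integer(), variance_form = character(),
                    loglik = numeric(), n_params = integer(), aic = numeric())
  best <- NULL
  for (ci in seq_len(nrow(cand))) {
    K <- cand$K[ci]
    deg <- if (cand$form[ci] == "linear") 1L else 2L
    fit_c <- NULL
    for (r in seq_len(n_restarts)) {
      resp <- tryCatch(lfc_init_resp(x, y, K, sub_seed(seed, 13L * ci + r)),
                       error = function(e) NULL)
      if (is.null(resp)) next
      f <- lfc_em_run(x, y, resp, deg)
      if (is.null(f)) next
      if (is.null(fit_c) || f$loglik > fit_c$loglik) fit_c <- f
    }
    if (is.null(fit_c)) {
      warning(sprintf("LFC mixture candidate K = %d (%s variance) failed to fit",
                      K, cand$form[ci]))
      next
    }
    npar <- (K - 1L) + 2L * K + K * (deg + 1L)
    aic <- 2 * npar - 2 * fit_c$loglik
    tab <- rbind(tab, data.frame(K = K, variance_form = cand$form[ci],
                                 loglik = fit_c$loglik, n_params = npar,
                                 aic = aic))
    fit_c$variance_form <- cand$form[ci]
    fit_c$aic <- aic
    if (is.null(best) || aic < best$aic) best <- fit_c
  }
  if (is.null(best)) stop("no LFC mixture candidate could be fitted", call. = FALSE)
  best$lambda <- log(best$weights / best$weights[1L])
  best$candidates <- tab
  class(best) <- "lfc_mixture"
  best
}

#' Draw log fold changes conditional on log mean abundance
#' @param x vector of log2 mean abundances to condition on.
#' @param fit an `lfc_mixture`.
#' @return Numeric vector of draws, one per element of `x`.
#' @export
rlfc <- function(x, fit) {
  n <- length(x)
  z <- sample.int(fit$K, n, replace = TRUE, prob = fit$weights)
  Xs <- lfc_sd_design(x, fit$degree)
  mu <- fit$mean_coef[z, 1L] + fit$mean_coef[z, 2L] * x
  f <- pmin(pmax(rowSums(Xs * fit$sd_coef[z, , drop = FALSE]), -F_CLAMP), F_CLAMP)
  stats::rnorm(n, mu, exp(f))
}

#' Conditional density of the fitted LFC mixture
#' @param y,x points at which to evaluate (recycled to common length).
#' @param fit an `lfc_mixture`.
#' @return Density values.
#' @export
dlfc <- function(y, x, fit) {
  nn <- max(length(x), length(y))
  x <- rep_len(x, nn); y <- rep_len(y, nn)
  Xs <- lfc_sd_design(x, fit$degree)
  d <- 0
  for (i in seq_len(fit$K)) {
    d <- d + fit$weights[i] *
      exp(lfc_component_logdens(x, y, fit$mean_coef[i, ], fit$sd_coef[i, ], Xs))
  }
  d
}

#' @export
print.lfc_mixture <- function(x, ...) {
  cat(sprintf("lfc_mixture: %d component(s), %s variance form, AIC %.1f\n",
              x$K, x$variance_form, x$aic))
  for (i in seq_len(x$K)) {
    cat(sprintf("  comp %d: pi = %.3f, mean = %.3f %+.3f x, log-sd coefs (%s)\n",
                i, x$weights[i], x$mean_coef[i, 1L], x$mean_coef[i, 2L],
                paste(sprintf("%.3f", x$sd_coef[i, ]), collapse = ", ")))
  }
  invisible(x)
}
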
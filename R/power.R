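# Taxon-level power estimation.
#
# Monte-Carlo detection outcomes (one Bernoulli row per simulated taxon,
# per replicate) are smoothed with a shape-constrained Bernoulli model:
#   y ~ Bernoulli(p),  logit p = eta(x1, x2),
# where x1 is log2 mean abundance and x2 the ABSOLUTE log2 fold change.
# eta is a tensor-product B-spline surface whose coefficient matrix is a
# double cumulative sum of exponentiated parameters (first entry free), so
# the surface is monotone non-decreasing in both inputs by construction.

#' Run the power Monte-Carlo
#'
#' For each replicate: draw a cohort from the model, apply the abundance
#' pre-filter, run the NB test pipeline, and record one row per taxon with
#' its true log2 mean abundance (`x1`), true absolute log2 fold change
#' (`x2`) and the detection indicator `y` (q-value below `alpha_sig`).
#' Taxa removed by the filter can never be detected and contribute `y = 0`
#' rows unless `conditional = TRUE`, in which case they are omitted and the
#' result is power conditional on surviving the filter.
#'
#' @param model a `community_model`.
#' @param n_taxa taxa per replicate (default 1000).
#' @param n_per_group samples per group (default 100).
#' @param n_sims number of replicates (default 100).
#' @param alpha_sig q-value significance threshold (default 0.1).
#' @param seed integer seed.
#' @param conditional report filter-conditional power instead of
#'   unconditional.
#' @param min_count,min_samples pre-filter thresholds.
#' @param force_lfc passed to [simulate_community()] (null calibration).
#' @return A `power_outcomes` data.frame with columns `sim`, `taxon_id`,
#'   `x1`, `x2`, `y`, `q_value` and attributes `alpha_sig`, `design`,
#'   `n_dropped`.
#' @export
run_power_simulation <- function(model, n_taxa = 1000L, n_per_group = 100L,
                                 n_sims = 100L, alpha_sig = 0.1, seed = 1L,
                                 conditional = FALSE, min_count = 5L,
                                 min_samples = 3L, force_lfc = NULL) {
  stopifnot(inherits(model, "community_model"), alpha_sig > 0, alpha_sig < 1)
  rows <- vector("list", n_sims)
  dropped <- 0L
  for (s in seq_len(n_sims)) {
    sim <- simulate_community(model, n_taxa, n_per_group, n_per_group,
                              seed = sub_seed(seed, s), force_lfc = force_lfc)
    res <- tryCatch({
      fcm <- filter_low_abundance(sim$counts, min_count, min_samples)
      est <- da_test(fcm)
      detected <- est$taxon_id[!is.na(est$q_value) & est$q_value < alpha_sig]
      qmap <- stats::setNames(est$q_value, est$taxon_id)
      kept <- est$taxon_id
      list(detected = detected, qmap = qmap, kept = kept)
    }, error = function(e) {
      warning(sprintf("replicate %d failed (%s); dropped", s, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { dropped <- dropped + 1L; next }
    tr <- sim$truth
    keep <- if (conditional) tr$taxon_id %in% res$kept else rep(TRUE, nrow(tr))
    tr <- tr[keep, , drop = FALSE]
    rows[[s]] <- data.frame(
      sim = s, taxon_id = tr$taxon_id, x1 = tr$x, x2 = abs(tr$lfc),
      y = as.integer(tr$taxon_id %in% res$detected),
      q_value = unname(res$qmap[tr$taxon_id]), stringsAsFactors = FALSE)
  }
  if (dropped > 0.1 * n_sims) {
    stop(sprintf("%d of %d replicates failed", dropped, n_sims), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "alpha_sig") <- alpha_sig
  attr(out, "design") <- list(n_taxa = n_taxa, n_per_group = n_per_group,
                              n_sims = n_sims, conditional = conditional)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("power_outcomes", "data.frame")
  out
}

# ---- monotone tensor-product Bernoulli surface ------------------------------

mono_basis_1d <- function(x, range, df) {
  # cubic B-spline basis with equally spaced interior knots on the range
  knots <- if (df > 4L) seq(range[1L], range[2L], length.out = df - 2L)[-c(1L, df - 2L)] else NULL
  splines::splineDesign(
    knots = c(rep(range[1L], 4L), knots, rep(range[2L], 4L)),
    x = pmin(pmax(x, range[1L]), range[2L]), ord = 4L)
}

# map unconstrained gamma (d1 x d2) to coefficient matrix C by double cumsum
# of c(gamma[1,1], exp(gamma[-1])) -> C non-decreasing along rows and columns
mono_coef <- function(gamma) {
  delta <- exp(gamma)
  delta[1L, 1L] <- gamma[1L, 1L]
  t(apply(apply(delta, 2L, cumsum), 1L, cumsum))
}

surface_eta <- function(B1, B2, C) {
  rowSums((B1 %*% C) * B2)
}

# second-difference + ridge penalty matrix on vec(gamma), d1 x d2 grid
surface_penalty <- function(d1, d2) {
  D <- function(d) { if (d < 3L) return(matrix(0, 0L, d)); diff(diag(d), differences = 2L) }
  S <- kronecker(diag(d2), crossprod(D(d1))) + kronecker(crossprod(D(d2)), diag(d1))
  S + 1e-4 * diag(d1 * d2)
}

#' Fit the monotone power surface
#'
#' Penalised Bernoulli likelihood with logit link over a tensor-product
#' cubic B-spline basis in (x1, x2) = (log2 mean abundance, |log2 fold
#' change|). Coefficients are the double cumulative sum of exponentiated
#' free parameters, which makes the fitted surface monotone non-decreasing
#' in both directions by construction. The smoothing parameter is chosen by
#' generalized cross-validation over a small grid.
#'
#' @param outcomes a `power_outcomes` table (needs both detected and
#'   undetected rows).
#' @param df marginal basis dimension (default 5, giving a 25-coefficient
#'   surface).
#' @param lambda_grid candidate smoothing parameters.
#' @param maxit optimiser iteration cap.
#' @return A `power_surface` with the basis description, coefficients,
#'   `intercept` (the free corner parameter), chosen `lambda`, GCV table and
#'   the training box; use [predict()] for power values.
#' @export
fit_power_surface <- function(outcomes, df = 5L, lambda_grid = c(0.1, 1, 10),
                              maxit = 200L) {
  y <- outcomes$y
  if (length(unique(y)) < 2L) {
    stop("outcomes are all-detected or all-undetected; cannot fit a surface",
         call. = FALSE)
  }
  x1 <- outcomes$x1; x2 <- outcomes$x2
  box <- list(x1 = range(x1), x2 = range(x2))
  B1 <- mono_basis_1d(x1, box$x1, df)
  B2 <- mono_basis_1d(x2, box$x2, df)
  d1 <- ncol(B1); d2 <- ncol(B2)
  S <- surface_penalty(d1, d2)
  n <- length(y)

  negll <- function(gam_vec, lambda) {
    gam <- matrix(gam_vec, d1, d2)
    eta <- surface_eta(B1, B2, mono_coef(gam))
    softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))  # log(1 + e^eta), stable
    -sum(y * eta - softplus) + lambda * drop(gam_vec %*% S %*% gam_vec)
  }
  grad <- function(gam_vec, lambda) {
    gam <- matrix(gam_vec, d1, d2)
    C <- mono_coef(gam)
    eta <- surface_eta(B1, B2, C)
    p <- stats::plogis(eta)
    G <- crossprod(B1, (y - p) * B2)           # dll / dC, d1 x d2
    # dC[a,b]/d delta[u,v] = 1{u<=a, v<=b}: reverse double cumsum of G
    R <- apply(apply(G, 2L, function(cc) rev(cumsum(rev(cc)))), 1L,
               function(rr) rev(cumsum(rev(rr))))
    R <- t(R)
    dd <- exp(gam); dd[1L, 1L] <- 1
    -as.vector(R * dd) + 2 * lambda * drop(S %*% gam_vec)
  }

  init <- matrix(-3, d1, d2)
  init[1L, 1L] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  fits <- list(); gcv <- numeric(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    opt <- stats::optim(as.vector(init), negll, grad, lambda = lam,
                        method = "L-BFGS-B",
                        lower = c(-30, rep(-20, d1 * d2 - 1L)),
                        upper = c(30, rep(10, d1 * d2 - 1L)),
                        control = list(maxit = maxit))
    gam <- matrix(opt$par, d1, d2)
    C <- mono_coef(gam)
    eta <- surface_eta(B1, B2, C)
    p <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    # effective df via the working-weight information in the free parameters
    dd <- exp(gam); dd[1L, 1L] <- 1
    # J column for (u, v): sum over a>=u, b>=v of B1[,a] B2[,b] * dd[u,v]
    J <- matrix(0, n, d1 * d2)
    cs1 <- t(apply(B1[, d1:1, drop = FALSE], 1L, cumsum))[, d1:1, drop = FALSE]
    cs2 <- t(apply(B2[, d2:1, drop = FALSE], 1L, cumsum))[, d2:1, drop = FALSE]
    idx <- 0L
    for (v in seq_len(d2)) for (u in seq_len(d1)) {
      idx <- idx + 1L
      J[, idx] <- cs1[, u] * cs2[, v] * dd[u, v]
    }
    w <- p * (1 - p)
    H <- crossprod(J * sqrt(w))
    edf <- sum(diag(solve(H + 2 * lam * S, H)))
    gcv[li] <- n * dev / (n - edf)^2
    fits[[li]] <- list(gamma = gam, C = C, lambda = lam, edf = edf,
                       deviance = dev, convergence = opt$convergence)
  }
  bi <- which.min(gcv)
  fit <- fits[[bi]]
  structure(list(gamma = fit$gamma, coef = fit$C, intercept = fit$gamma[1L, 1L],
                 df = c(d1, d2), box = box, lambda = fit$lambda, edf = fit$edf,
                 deviance = fit$deviance,
                 gcv = data.frame(lambda = lambda_grid, gcv = gcv),
                 alpha_sig = attr(outcomes, "alpha_sig") %||% NA_real_,
                 design = attr(outcomes, "design")),
            class = "power_surface")
}

#' Predict power from a fitted surface
#'
#' Inputs are clamped to the training box (boundary value, no
#' extrapolation); any clamping is reported via `attr(, "n_clamped")`.
#'
#' @param object a `power_surface`.
#' @param x1 log2 mean abundance.
#' @param x2 absolute log2 fold change (recycled against `x1`).
#' @param ... unused.
#' @return Power values in \[0, 1\].
#' @export
predict.power_surface <- function(object, x1, x2, ...) {
  nn <- max(length(x1), length(x2))
  x1 <- rep_len(x1, nn); x2 <- rep_len(x2, nn)
  n_clamped <- sum(x1 < object$box$x1[1L] | x1 > object$box$x1[2L] |
                   x2 < object$box$x2[1L] | x2 > object$box$x2[2L])
  if (n_clamped > 0L) dap_log("predict.power_surface: clamped %d points", n_clamped)
  B1 <- mono_basis_1d(x1, object$box$x1, object$df[1L])
  B2 <- mono_basis_1d(x2, object$box$x2, object$df[2L])
  p <- stats::plogis(surface_eta(B1, B2, object$coef))
  attr(p, "n_clamped") <- n_clamped
  p
}

#' @export
print.power_surface <- function(x, ...) {
  cat(sprintf("power_surface: %d x %d monotone tensor-product basis, lambda = %g, edf = %.1f\n",
              x$df[1L], x$df[2L], x$lambda, x$edf))
  cat(sprintf("  training box: x1 in [%.2f, %.2f], x2 in [%.2f, %.2f]; alpha_sig = %s\n",
              x$box$x1[1L], x$box$x1[2L], x$box$x2[1L], x$box$x2[2L],
              format(x$alpha_sig)))
  invisible(x)
}

#' Contour plot of a power surface
#'
#' @param x a `power_surface`.
#' @param outcomes optional `power_outcomes` whose detected/undetected taxa
#'   are overlaid (red/black points, subsampled).
#' @param grid_n grid resolution per axis.
#' @param levels contour levels.
#' @param max_points point-cloud cap.
#' @param ... passed to [graphics::contour()].
#' @return Invisibly, `x`.
#' @export
plot.power_surface <- function(x, outcomes = NULL, grid_n = 60L,
                               levels = seq(0.1, 0.9, by = 0.2),
                               max_points = 2000L, ...) {
  g1 <- seq(x$box$x1[1L], x$box$x1[2L], length.out = grid_n)
  g2 <- seq(x$box$x2[1L], x$box$x2[2L], length.out = grid_n)
  gg <- expand.grid(x1 = g1, x2 = g2)
  z <- matrix(predict(x, gg$x1, gg$x2), grid_n, grid_n)
  graphics::plot(NA, xlim = x$box$x1, ylim = x$box$x2,
                 xlab = "log2 mean abundance", ylab = "|log2 fold change|",
                 main = "Estimated power")
  if (!is.null(outcomes)) {
    o <- outcomes
    if (nrow(o) > max_points) o <- o[sample.int(nrow(o), max_points), ]
    graphics::points(o$x1, o$x2, pch = 16, cex = 0.3,
                     col = ifelse(o$y == 1, "firebrick", "grey30"))
  }
  graphics::contour(g1, g2, z, levels = levels, add = TRUE, col = "steelblue",
                    lwd = 1.5, ...)
  invisible(x)
}

#' Summarise per-taxon power
#'
#' Evaluates the surface at each taxon's (x1, x2), then reports per-taxon
#' powers, their quantiles, the average power, and the expected number of
#' significant taxa (the sum of per-taxon powers, identically n times the
#' average).
#'
#' @param surface a `power_surface`.
#' @param taxa data.frame with columns `x1` and `x2` (one row per taxon);
#'   values outside the training box are clamped.
#' @param alpha_sig significance threshold label carried on the output.
#' @return A `power_summary`: `power` (per-taxon), `n`, `average_power`,
#'   `expected_significant`, `quantiles` (10% to 90%), `alpha_sig`,
#'   `design`, `n_clamped`.
#' @export
power_summary <- function(surface, taxa, alpha_sig = surface$alpha_sig) {
  stopifnot(inherits(surface, "power_surface"))
  if (NROW(taxa) == 0L) stop("empty taxa table", call. = FALSE)
  p <- predict(surface, taxa$x1, taxa$x2)
  n <- length(p)
  p_bar <- mean(p)
  structure(list(power = as.numeric(p), n = n, average_power = p_bar,
                 expected_significant = n * p_bar,
                 quantiles = stats::quantile(p, seq(0.1, 0.9, by = 0.1)),
                 alpha_sig = alpha_sig, design = surface$design,
                 n_clamped = attr(p, "n_clamped")),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("power_summary (alpha_sig = %s): %d taxa\n",
              format(x$alpha_sig), x$n))
  cat(sprintf("  average power %.3f; expected significant taxa %.1f\n",
              x$average_power, x$expected_significant))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' Power as a function of sample size
#'
#' For each per-group sample size, runs the power Monte-Carlo, fits the
#' monotone surface, and records (i) predicted power at a reference log2
#' mean abundance for each requested absolute log2 fold change and (ii) the
#' expected number of significant taxa, computed per replicate from the
#' simulated taxa and averaged.
#'
#' @param model a `community_model`.
#' @param sizes per-group sample sizes (default 30 to 190 by 20).
#' @param lfc_values absolute log2 fold changes at which power is read off.
#' @param x1_ref reference log2 mean abundance (default 5).
#' @param n_taxa,n_sims,alpha_sig Monte-Carlo design.
#' @param seed integer seed.
#' @return data.frame with columns `size`, `lfc`, `power`,
#'   `expected_significant` (repeated within size), class `power_sweep`.
#' @export
sample_size_sweep <- function(model, sizes = seq(30L, 190L, by = 20L),
                              lfc_values = c(2, 3, 4), x1_ref = 5,
                              n_taxa = 1000L, n_sims = 100L, alpha_sig = 0.1,
                              seed = 1L) {
  out <- list()
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    oc <- run_power_simulation(model, n_taxa = n_taxa, n_per_group = sz,
                               n_sims = n_sims, alpha_sig = alpha_sig,
                               seed = sub_seed(seed, si))
    surf <- fit_power_surface(oc)
    pw <- predict(surf, rep(x1_ref, length(lfc_values)), lfc_values)
    mu_s <- vapply(split(oc, oc$sim), function(d)
      sum(predict(surf, d$x1, d$x2)), numeric(1))
    out[[si]] <- data.frame(size = sz, lfc = lfc_values, power = as.numeric(pw),
                            expected_significant = mean(mu_s))
  }
  res <- do.call(rbind, out)
  attr(res, "x1_ref") <- x1_ref
  attr(res, "alpha_sig") <- alpha_sig
  class(res) <- c("power_sweep", "data.frame")
  res
}
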
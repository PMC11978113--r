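# The generative community model: mean-abundance mixture, conditional LFC
# mixture, and the dispersion-mean trend d(m) = scale * (c0 + c1 / m).

#' Fit the dispersion-mean trend
#'
#' Least squares of the per-taxon dispersion on (1, 1/m) with non-negativity
#' constraints on both coefficients, iterated once after trimming points
#' more than 10-fold off the fitted trend. c0 is the asymptotic dispersion
#' of high-abundance taxa; c1 captures the extra dispersion of rare taxa.
#' The multiplicative `scale` (default 0.3) is applied at prediction time,
#' not to the stored coefficients: raw maximum likelihood dispersions
#' overstate the variability of real communities, and scaling them brings
#' the coefficient of variation of simulated counts in line with observed
#' data.
#'
#' @param base_means per-taxon mean normalised counts (positive).
#' @param dispersions per-taxon dispersion estimates (non-negative);
#'   boundary-flagged taxa should be excluded by the caller.
#' @param scale dispersion scale factor in (0, 1] used by
#'   [predict_dispersion()].
#' @return A `dispersion_trend` object with fields `c0`, `c1`, `scale`,
#'   `n_used`, `n_trimmed`.
#' @export
fit_dispersion_trend <- function(base_means, dispersions, scale = 0.3) {
  ok <- is.finite(base_means) & is.finite(dispersions) & base_means > 0 &
    dispersions >= 0
  m <- base_means[ok]; d <- dispersions[ok]
  if (length(m) < 10L) stop("need at least 10 usable taxa", call. = FALSE)
  stopifnot(scale > 0, scale <= 1)
  cf <- nnls2(cbind(1, 1 / m), d)
  pred <- pmax(cf[1L] + cf[2L] / m, 1e-12)
  # trim relative to the typical (median) deviation so that a first pass
  # dominated by gross outliers still flags the outliers, not the bulk
  ratio <- d / pred
  med <- stats::median(ratio[d > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  keep <- ratio / med <= 10 & ratio / med >= 0.1
  keep[d == 0] <- TRUE  # zero dispersions carry no ratio information
  n_trimmed <- sum(!keep)
  if (n_trimmed > 0L && sum(keep) >= 10L) {
    cf <- nnls2(cbind(1, 1 / m[keep]), d[keep])
  }
  structure(list(c0 = cf[1L], c1 = cf[2L], scale = scale,
                 n_used = sum(keep), n_trimmed = n_trimmed),
            class = "dispersion_trend")
}

# two-column non-negative least squares by case analysis
nnls2 <- function(X, y) {
  b <- tryCatch(qr.solve(X, y), error = function(e) c(-1, -1))
  if (all(b >= 0)) return(b)
  b1 <- c(max(0, mean(y)), 0)                                # c1 = 0
  b2 <- c(0, max(0, sum(y * X[, 2L]) / sum(X[, 2L]^2)))      # c0 = 0
  rss <- function(b) sum((y - X %*% b)^2)
  if (rss(b1) <= rss(b2)) b1 else b2
}

#' Predicted (scaled) dispersion at a mean abundance
#' @param trend a `dispersion_trend`.
#' @param m mean abundance on the count scale (positive).
#' @return `scale * (c0 + c1 / m)`, floored at 1e-8 so the value is a valid
#'   NB dispersion.
#' @export
predict_dispersion <- function(trend, m) {
  stopifnot(inherits(trend, "dispersion_trend"), all(m > 0))
  pmax(trend$scale * (trend$c0 + trend$c1 / m), 1e-8)
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion_trend: d(m) = %.3g * (%.4g + %.4g / m)  [%d taxa, %d trimmed]\n",
              x$scale, x$c0, x$c1, x$n_used, x$n_trimmed))
  invisible(x)
}

#' Per-taxon (log mean abundance, log fold change) summaries
#'
#' The fitting targets of the community model: x is the log2 of the
#' arithmetic mean of normalised counts over all samples (both groups
#' pooled) and y the shrunken log2 fold change. Taxa with zero base mean
#' are excluded.
#'
#' @param estimates per-taxon results from [da_test()] (shrunken LFCs
#'   required).
#' @return data.frame with `taxon_id`, `x`, `y`; the number of excluded taxa
#'   in `attr(, "n_excluded")`.
#' @export
compute_taxon_summaries <- function(estimates) {
  if (all(is.na(estimates$lfc_shrunk))) {
    stop("run shrink_lfc() before computing taxon summaries", call. = FALSE)
  }
  ok <- estimates$base_mean > 0 & is.finite(estimates$lfc_shrunk)
  out <- data.frame(taxon_id = estimates$taxon_id[ok],
                    x = log2(estimates$base_mean[ok]),
                    y = estimates$lfc_shrunk[ok], stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  dap_log("compute_taxon_summaries: excluded %d taxa with zero base mean", sum(!ok))
  out
}

#' Assemble a community model
#'
#' @param mean_mixture a `mean_mixture` (from [select_components_bootstrap()]
#'   or a hand-built list with `weights`, `means`, `sds`).
#' @param lfc_mixture an `lfc_mixture` (from [fit_lfc_mixture()] or
#'   hand-built).
#' @param dispersion_trend a `dispersion_trend`.
#' @param log_base base of the log scale shared by the mean-abundance and
#'   fold-change components (default 2).
#' @return A `community_model` object.
#' @export
community_model <- function(mean_mixture, lfc_mixture, dispersion_trend,
                            log_base = 2) {
  stopifnot(abs(sum(mean_mixture$weights) - 1) < 1e-8,
            all(mean_mixture$sds > 0),
            abs(sum(lfc_mixture$weights) - 1) < 1e-8,
            inherits(dispersion_trend, "dispersion_trend"),
            log_base > 1)
  structure(list(mean_mixture = mean_mixture, lfc_mixture = lfc_mixture,
                 dispersion_trend = dispersion_trend, log_base = log_base,
                 schema_version = 1L),
            class = "community_model")
}

#' Fit the full community model to pilot data
#'
#' Runs the whole fitting pipeline on a (filtered) pilot count matrix:
#' differential abundance estimates, taxon summaries, bootstrap-selected
#' mean-abundance mixture, AIC-selected conditional LFC mixture, and the
#' dispersion trend (fitted on taxa away from the Poisson boundary).
#'
#' @param cm a filtered [count_matrix()].
#' @param K_max,B,level mean-mixture order selection controls
#'   (see [select_components_bootstrap()]).
#' @param lfc_K_range candidate LFC mixture orders.
#' @param dispersion_scale scale factor stored on the trend.
#' @param seed integer seed.
#' @return A `community_model`; the per-taxon estimates used for fitting are
#'   attached as `attr(, "estimates")`.
#' @export
fit_community_model <- function(cm, K_max = 5L, B = 100L, level = 0.05,
                                lfc_K_range = 1:5, dispersion_scale = 0.3,
                                seed = 1L) {
  est <- da_test(cm)
  xy <- compute_taxon_summaries(est)
  mm <- select_components_bootstrap(xy$x, K_max = K_max, B = B, level = level,
                                    seed = sub_seed(seed, 1L))
  lm_fit <- fit_lfc_mixture(xy$x, xy$y, K_range = lfc_K_range,
                            seed = sub_seed(seed, 2L))
  use <- est$tested & !at_boundary_safe(est)
  dt <- fit_dispersion_trend(est$base_mean[use], est$dispersion[use],
                             scale = dispersion_scale)
  model <- community_model(mm, lm_fit, dt, log_base = 2)
  attr(model, "estimates") <- est
  model
}

# dispersion rows usable for the trend: tested and not at the Poisson boundary
at_boundary_safe <- function(est) {
  if (!is.null(est$at_boundary)) est$at_boundary else est$dispersion <= 0
}

#' @export
print.community_model <- function(x, ...) {
  cat("community_model (log base", x$log_base, ")\n")
  print(x$mean_mixture)
  print(x$lfc_mixture)
  print(x$dispersion_trend)
  invisible(x)
}

#' Write a community model to a YAML file
#'
#' Human-readable, versioned serialization so fitted models can be stored,
#' shared and re-loaded for simulation.
#'
#' @param model a `community_model`.
#' @param path output path (conventionally `.yaml`).
#' @return Invisibly, the path.
#' @export
write_community_model <- function(model, path) {
  stopifnot(inherits(model, "community_model"))
  mm <- model$mean_mixture
  lf <- model$lfc_mixture
  dt <- model$dispersion_trend
  obj <- list(
    schema = "dapower/community_model",
    schema_version = 1L,
    log_base = model$log_base,
    mean_mixture = list(K = length(mm$weights),
                        weights = as.numeric(mm$weights),
                        means = as.numeric(mm$means),
                        sds = as.numeric(mm$sds)),
    lfc_mixture = list(K = lf$K,
                       weights = as.numeric(lf$weights),
                       lambda = as.numeric(lf$lambda %||% log(lf$weights / lf$weights[1L])),
                       variance_form = lf$variance_form,
                       mean_coef = apply(lf$mean_coef, 1L, as.numeric, simplify = FALSE),
                       sd_coef = apply(lf$sd_coef, 1L, as.numeric, simplify = FALSE)),
    dispersion_trend = list(c0 = dt$c0, c1 = dt$c1, scale = dt$scale))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a community model written by [write_community_model()]
#' @param path path to the YAML file.
#' @return A `community_model`.
#' @export
read_community_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "dapower/community_model")) {
    stop("not a dapower community model file: ", path, call. = FALSE)
  }
  mm <- list(weights = as.numeric(obj$mean_mixture$weights),
             means = as.numeric(obj$mean_mixture$means),
             sds = as.numeric(obj$mean_mixture$sds),
             K = as.integer(obj$mean_mixture$K))
  class(mm) <- "mean_mixture"
  lfK <- as.integer(obj$lfc_mixture$K)
  form <- obj$lfc_mixture$variance_form
  lf <- list(K = lfK,
             weights = as.numeric(obj$lfc_mixture$weights),
             lambda = as.numeric(obj$lfc_mixture$lambda),
             variance_form = form,
             degree = if (form == "linear") 1L else 2L,
             mean_coef = do.call(rbind, lapply(obj$lfc_mixture$mean_coef, as.numeric)),
             sd_coef = do.call(rbind, lapply(obj$lfc_mixture$sd_coef, as.numeric)))
  class(lf) <- "lfc_mixture"
  dt <- structure(list(c0 = as.numeric(obj$dispersion_trend$c0),
                       c1 = as.numeric(obj$dispersion_trend$c1),
                       scale = as.numeric(obj$dispersion_trend$scale),
                       n_used = NA_integer_, n_trimmed = NA_integer_),
                  class = "dispersion_trend")
  community_model(mm, lf, dt, log_base = as.numeric(obj$log_base))
}
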
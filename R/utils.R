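#' @keywords internal
#' @useDynLib dapower, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Derive a deterministic sub-seed from a master seed and a stream index.
# Keeps results reproducible when one user-facing seed drives several
# independent random stages (mixture draws, count draws, bootstrap loops).
# Always returns a value in [1, 2^31 - 2] so set.seed() accepts it.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.double(seed) %% m) + 1
  for (k in seq_len(max(1L, as.integer(stream)))) {
    x <- (x * 48271) %% m
  }
  as.integer(1 + (x %% (m - 2)))
}

# log(sum(exp(x))) by row for a matrix, guarded against underflow.
# K is small, so the row maximum is built by pmax over columns rather than
# apply(), which dominates EM runtime otherwise.
row_logsumexp <- function(lmat) {
  mx <- lmat[, 1L]
  for (k in seq_len(ncol(lmat))[-1L]) mx <- pmax(mx, lmat[, k])
  mx + log(rowSums(exp(lmat - mx)))
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

dap_log <- function(fmt, ..., verbose = getOption("dapower.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
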
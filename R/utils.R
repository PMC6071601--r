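# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' (genotype simulation, design randomization, permutations, ...) uses a
#' distinct derived seed so that re-running a single stage reproduces it
#' exactly. Derived seeds stay below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (small non-negative integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(offset)) %% 2147483629)
}

# rescale a vector so that its sample variance is exactly v (n-1 denominator);
# a zero-variance input with v > 0 is an error, v = 0 returns zeros
scale_to_var <- function(x, v) {
  stopifnot(v >= 0)
  if (v == 0) return(rep(0, length(x)))
  s <- stats::var(x)
  if (!is.finite(s) || s <= 0) stop("cannot rescale a zero-variance vector to positive variance")
  x * sqrt(v / s)
}

# column mean imputation of a numeric matrix (NA -> column mean of observed)
mean_impute <- function(X) {
  nas <- is.na(X)
  if (!any(nas)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  idx <- which(nas, arr.ind = TRUE)
  X[nas] <- mu[idx[, 2L]]
  X
}

# sparse incidence matrix for a factor (rows = observations, cols = levels)
incidence <- function(f) {
  f <- droplevels(as.factor(f))
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                       x = 1, dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_format <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
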
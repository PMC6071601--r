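# Linkage disequilibrium: raw and structure/kinship-corrected r2, and the
# exponential decay fit used to calibrate the regional-scan window length.

#' Enumerate (or sample) marker pairs
#'
#' @param map marker map (0-based positions).
#' @param max_distance_bp keep same-chromosome pairs closer than this.
#' @param cross_chromosome if TRUE, return pairs on different chromosomes
#'   (distance reported as `NA`), e.g. to study unlinked background LD.
#' @param n_max optional cap; a seeded uniform subsample is taken.
#' @param seed seed for the subsample.
#' @return data.frame with columns `i`, `j` (map row indices), `marker1`,
#'   `marker2`, `chromosome` (NA for cross-chromosome pairs), `dist_bp`.
#' @export
marker_pairs <- function(map, max_distance_bp = Inf, cross_chromosome = FALSE,
                         n_max = NULL, seed = 1L) {
  if (cross_chromosome) {
    chr <- map$chromosome
    n <- nrow(map)
    set.seed(derive_seed(seed, 4L))
    want <- n_max %||% 20000L
    i <- sample.int(n, want, replace = TRUE)
    j <- sample.int(n, want, replace = TRUE)
    keep <- chr[i] != chr[j] & i < j
    out <- unique(data.frame(i = i[keep], j = j[keep]))
    out$chromosome <- NA_integer_
    out$dist_bp <- NA_real_
  } else {
    parts <- lapply(split(seq_len(nrow(map)), map$chromosome), function(on_chr) {
      pos <- map$position_bp[on_chr]
      pr <- expand_pairs(length(on_chr))
      d <- abs(pos[pr$a] - pos[pr$b])
      keep <- d <= max_distance_bp
      data.frame(i = on_chr[pr$a[keep]], j = on_chr[pr$b[keep]],
                 chromosome = map$chromosome[on_chr[1L]],
                 dist_bp = d[keep])
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    if (!is.null(n_max) && nrow(out) > n_max) {
      set.seed(derive_seed(seed, 4L))
      out <- out[sort(sample.int(nrow(out), n_max)), , drop = FALSE]
    }
  }
  out$marker1 <- map$marker_id[out$i]
  out$marker2 <- map$marker_id[out$j]
  rownames(out) <- NULL
  out
}

expand_pairs <- function(n) {
  if (n < 2L) return(list(a = integer(0), b = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(a = idx[, 1L], b = idx[, 2L])
}

#' Pairwise linkage disequilibrium r2
#'
#' `r2` is the squared sample correlation of the (mean-imputed) numeric
#' marker codes. Zero-variance markers cannot be correlated; their pairs
#' are dropped and counted in `attr(, "n_skipped")`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pairs pair table from [marker_pairs()]; when `NULL`, all
#'   same-chromosome pairs within `max_distance_bp`.
#' @param max_distance_bp distance cutoff used when `pairs` is `NULL`.
#' @return the pair table with an `r2` column.
#' @export
pairwise_r2 <- function(genotypes, pairs = NULL, max_distance_bp = Inf) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(pairs))
    pairs <- marker_pairs(genotypes$map, max_distance_bp = max_distance_bp)
  W <- mean_impute(genotypes$values)
  r2_from_matrix(W, pairs)
}

r2_from_matrix <- function(W, pairs) {
  s <- apply(W, 2L, sd)
  ok <- s[pairs$i] > 0 & s[pairs$j] > 0
  n_skip <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  Wc <- sweep(W, 2L, colMeans(W))
  num <- colSums(Wc[, pairs$i, drop = FALSE] * Wc[, pairs$j, drop = FALSE])
  den <- colSums(Wc[, pairs$i, drop = FALSE]^2) *
    colSums(Wc[, pairs$j, drop = FALSE]^2)
  pairs$r2 <- num^2 / den
  rownames(pairs) <- NULL
  attr(pairs, "n_skipped") <- n_skip
  pairs
}

#' Structure/relatedness-corrected linkage disequilibrium
#'
#' Computes r2 between marker codes after (i) projecting out structure
#' covariates (plus an intercept) and (ii) decorrelating by the kinship
#' factor: codes are premultiplied by `V^{-1/2}` with
#' `V = K + ridge * mean(diag(K)) * I`, then residualized on the
#' transformed covariates -- a generalized-least-squares residual
#' correlation. With identity kinship and no covariates this equals the raw
#' r2.
#'
#' @param genotypes a [genotype_matrix()].
#' @param kinship a `grm` or symmetric matrix over the same accessions.
#' @param structure_covariates optional matrix of covariates (e.g. leading
#'   principal components from [structure_pcs()]).
#' @param pairs pair table; when `NULL`, all same-chromosome pairs within
#'   `max_distance_bp`.
#' @param max_distance_bp distance cutoff used when `pairs` is `NULL`.
#' @param ridge regularization added before inversion (default 1e-8).
#' @return the pair table with an `r2` column (corrected).
#' @export
corrected_r2 <- function(genotypes, kinship, structure_covariates = NULL,
                         pairs = NULL, max_distance_bp = Inf, ridge = 1e-8) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(pairs))
    pairs <- marker_pairs(genotypes$map, max_distance_bp = max_distance_bp)
  K <- if (inherits(kinship, "grm")) kinship$matrix else as.matrix(kinship)
  n <- nrow(genotypes$values)
  if (nrow(K) != n) stop_format("kinship dimension does not match accessions")
  ed <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- ed$values + ridge * mean(diag(K))
  if (min(lam) <= 0)
    stop_format("kinship is singular even after regularization")
  Vih <- ed$vectors %*% (t(ed$vectors) / sqrt(lam))
  W <- Vih %*% mean_impute(genotypes$values)
  Xc <- cbind(rep(1, n), structure_covariates)
  Xc <- Vih %*% Xc
  qrX <- qr(Xc)
  W <- W - qr.fitted(qrX, W)
  r2_from_matrix(W, pairs)
}

#' Leading principal components of the genotype matrix
#'
#' Standard surrogate for population-structure covariates: PCs of the
#' mean-imputed, column-centered marker codes.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n number of components (default 2, one per gene pool boundary).
#' @return matrix of PC scores (accessions x n).
#' @export
structure_pcs <- function(genotypes, n = 2L) {
  W <- mean_impute(genotypes$values)
  pr <- prcomp(W, center = TRUE, scale. = FALSE, rank. = n)
  sc <- pr$x[, seq_len(min(n, ncol(pr$x))), drop = FALSE]
  rownames(sc) <- rownames(genotypes$values)
  sc
}

#' Fit an exponential LD decay curve
#'
#' Nonlinear least squares of `r2(d) = r0 * exp(-lambda * d) + c` on
#' binned mean r2 against distance (Mb). Reports the half-decay r2 level
#' `r0 / 2 + c` and the distance `log(2) / lambda` at which the fitted
#' curve attains it (infinite when the curve is flat).
#'
#' @param pairs pair table with `dist_bp` and `r2` columns.
#' @param n_bins number of equal-count distance bins (default 50).
#' @param min_pairs minimum pairs required (default 20).
#' @return object of class `ld_decay_fit` with `r0`, `lambda`, `c`,
#'   `half_decay_r2`, `half_decay_mb`, `flat` flag and the binned means.
#' @export
fit_ld_decay <- function(pairs, n_bins = 50L, min_pairs = 20L) {
  pairs <- pairs[is.finite(pairs$dist_bp) & is.finite(pairs$r2), , drop = FALSE]
  if (nrow(pairs) < min_pairs)
    stop_format("need at least %d pairs to fit the decay curve", min_pairs)
  d_mb <- pairs$dist_bp / 1e6
  # bin only genuinely large pair clouds; small exact curves are fitted as-is
  if (nrow(pairs) > max(2000L, 4L * n_bins)) {
    br <- unique(quantile(d_mb, probs = seq(0, 1, length.out = n_bins + 1L)))
    bin <- cut(d_mb, br, include.lowest = TRUE)
    dat <- data.frame(d = tapply(d_mb, bin, mean),
                      r2 = tapply(pairs$r2, bin, mean),
                      w = as.numeric(table(bin)))
    dat <- dat[dat$w > 0, , drop = FALSE]
  } else {
    dat <- data.frame(d = d_mb, r2 = pairs$r2, w = 1)
  }
  r2rng <- range(dat$r2)
  if (diff(r2rng) < 1e-9) {            # flat profile: no decay to fit
    return(structure(list(r0 = 0, lambda = 0, c = mean(dat$r2),
                          half_decay_r2 = mean(dat$r2), half_decay_mb = Inf,
                          flat = TRUE, bins = dat,
                          curve = function(d) rep(mean(dat$r2), length(d))),
                     class = "ld_decay_fit"))
  }
  start <- list(r0 = max(r2rng[2L] - r2rng[1L], 1e-3), lambda = 1,
                cc = max(r2rng[1L], 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ r0 * exp(-lambda * d) + cc, data = dat,
                      start = start, weights = dat$w,
                      lower = c(r0 = 0, lambda = 0, cc = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_format("LD decay fit did not converge: %s", conditionMessage(e)))
  cf <- coef(fit)
  flat <- cf[["lambda"]] < 1e-8 || cf[["r0"]] < 1e-10
  structure(list(r0 = cf[["r0"]], lambda = cf[["lambda"]], c = cf[["cc"]],
                 half_decay_r2 = cf[["r0"]] / 2 + cf[["cc"]],
                 half_decay_mb = if (flat) Inf else log(2) / cf[["lambda"]],
                 flat = flat, bins = dat,
                 curve = function(d) cf[["r0"]] * exp(-cf[["lambda"]] * d) + cf[["cc"]]),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay: r2(d) = %.4f * exp(-%.4f d) + %.4f  (d in Mb)\n",
              x$r0, x$lambda, x$c))
  if (x$flat) cat("  curve is flat; half-decay distance undefined\n")
  else cat(sprintf("  half-decay r2 = %.4f at %.3f Mb\n",
                   x$half_decay_r2, x$half_decay_mb))
  invisible(x)
}
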
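# Fast accession-level REML paths used by the association and regional
# scans: the response has one record per accession, the polygenic term has
# incidence I and covariance G, so everything can be rotated once by the
# eigenvectors of G. A regional term adds a low-rank block handled in C++.

#' Eigendecomposition of a genomic relationship matrix
#'
#' Computed once per scan and reused across windows, permutations and
#' markers. Negative eigenvalues within numerical tolerance are clipped.
#'
#' @param G a [build_grm()] result or plain symmetric matrix.
#' @return list with `U` (eigenvectors), `d` (eigenvalues), `ids`.
#' @export
grm_eigen <- function(G) {
  ids <- NULL
  if (inherits(G, "grm")) { ids <- G$accession_ids; G <- G$matrix }
  ed <- eigen(G, symmetric = TRUE)
  list(U = ed$vectors, d = pmax(ed$values, 0), ids = ids %||% rownames(G))
}

# shared rotation helper
rotate_xy <- function(eig, y, X) {
  list(yr = as.numeric(crossprod(eig$U, y)), Xr = crossprod(eig$U, X))
}

#' REML fit of the single-kinship polygenic model
#'
#' Fits `y = X beta + u + e`, `u ~ N(0, sigma2_u G)`, by profiling the
#' residual variance and optimizing the variance ratio on the log scale in
#' the eigenbasis of G (one O(n) likelihood evaluation per step). This is
#' the null/background model of both the association scan and the regional
#' scan, and the model behind whole-genome heritability.
#'
#' @param y accession-level response (named or aligned with `G`).
#' @param X fixed-effect matrix (`NULL` = intercept).
#' @param G genomic relationship matrix ([build_grm()] result or matrix).
#' @param eig optional precomputed [grm_eigen()] of `G`.
#' @return a `vc_fit` with components `genomic` and `residual`, BLUPs of
#'   the polygenic values, and `h2` = sigma2_u / (sigma2_u + sigma2_e).
#' @export
fit_kinship_reml <- function(y, X = NULL, G = NULL, eig = NULL) {
  if (is.null(eig)) {
    if (is.null(G)) stop_format("supply G or its eigendecomposition")
    eig <- grm_eigen(G)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (length(eig$d) != n) stop_format("length of y (%d) does not match G (%d)", n, length(eig$d))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  p <- ncol(X)
  ro <- rotate_xy(eig, y, X)
  f <- function(l) reml_nll_kinship(l, eig$d, ro$yr, ro$Xr)
  op <- optimize(f, c(-25, 25), tol = 1e-9)
  lth <- op$minimum; val <- op$objective
  # explicit boundary candidate at theta -> 0
  v0 <- f(-36)
  boundary <- character(0)
  if (v0 <= val + 1e-9) { lth <- -36; val <- v0; boundary <- "genomic" }
  parts <- reml_parts(lth, 0, eig$d, ro$yr, ro$Xr,
                      matrix(0, n, 0), FALSE)
  s2u <- if (length(boundary)) 0 else parts$sigma2_u
  s2e <- parts$sigma2_e
  # BLUP of the polygenic values: u = U diag(thu d / (1 + thu d)) (yr - Xr beta)
  thu <- if (length(boundary)) 0 else parts$theta_u
  resid_r <- ro$yr - as.numeric(ro$Xr %*% parts$beta)
  ur <- thu * eig$d / (1 + thu * eig$d) * resid_r
  u <- as.numeric(eig$U %*% ur)
  names(u) <- eig$ids
  structure(list(sigma2 = c(genomic = s2u, residual = s2e),
                 theta = c(genomic = thu),
                 logLik = parts$logLik,
                 beta = setNames(as.numeric(parts$beta), colnames(X)),
                 se_beta = setNames(as.numeric(parts$se_beta), colnames(X)),
                 blup = list(genomic = u), pev = NULL, reliability = NULL,
                 boundary = boundary, labels = "genomic", N = n, p = p,
                 y = y, X = X, h2 = s2u / (s2u + s2e),
                 convergence = list(iterations = NA_integer_, code = 0L,
                                    criterion = val)),
            class = "vc_fit")
}

# Fit the two-variance-component regional model in rotated coordinates.
# yr, Xr: response/design rotated by eigenvectors of G; d: eigenvalues;
# Wt: rotated, centered, frequency-scaled regional marker block.
# null_fit: list(lth, nll) from fit_region_null().
# Returns lrt, sigma2 components and logLik of the full model.
fit_region_ml <- function(yr, Xr, d, Wt, null_fit, use_score_skip = TRUE) {
  n <- length(yr); p <- ncol(Xr)
  lth0 <- null_fit$lth
  if (use_score_skip) {
    sc <- region_score_null(lth0, d, yr, Xr, Wt)
    if (sc <= 0) {
      parts <- reml_parts(lth0, 0, d, yr, Xr, matrix(0, n, 0), FALSE)
      return(list(lrt = 0, sigma2_u = parts$sigma2_u, sigma2_v = 0,
                  sigma2_e = parts$sigma2_e, logLik = parts$logLik,
                  boundary = TRUE))
    }
  }
  obj <- function(par) {
    par <- pmin(pmax(par, -30), 30)
    reml_nll_region(par[1L], par[2L], d, yr, Xr, Wt)
  }
  start <- c(lth0, max(lth0 - 2, -8))
  op <- optim(start, obj, method = "Nelder-Mead",
              control = list(maxit = 400L, reltol = 1e-10))
  par <- pmin(pmax(op$par, -30), 30)
  full_nll <- op$value
  lrt <- max(0, 2 * (null_fit$nll - full_nll))
  parts <- reml_parts(par[1L], par[2L], d, yr, Xr, Wt, TRUE)
  bnd <- exp(par[2L]) < 1e-9
  list(lrt = lrt, sigma2_u = parts$sigma2_u,
       sigma2_v = if (bnd) 0 else parts$sigma2_v,
       sigma2_e = parts$sigma2_e, logLik = parts$logLik, boundary = bnd)
}

# 1-D null fit in rotated coordinates; returns log theta and criterion value
fit_region_null <- function(yr, Xr, d) {
  f <- function(l) reml_nll_kinship(l, d, yr, Xr)
  op <- optimize(f, c(-25, 25), tol = 1e-9)
  lth <- op$minimum; val <- op$objective
  v0 <- f(-36)
  if (v0 <= val + 1e-9) { lth <- -36; val <- v0 }
  list(lth = lth, nll = val)
}
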
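# General REML solver for linear mixed models with arbitrary random-effect
# covariance structures, via Henderson's mixed-model equations.
#
# Each random term j contributes u_j ~ N(0, sigma2_j K_j) through incidence
# Z_j; the residual is iid. Terms with K != I are absorbed by the
# substitution u_j = L_j alpha_j (L_j L_j' = K_j), so a single sparse
# coefficient matrix C covers every model. The residual variance is profiled
# out and the variance ratios theta_j = sigma2_j / sigma2_e are optimized on
# the log scale with a deterministic equal-split start, with an explicit
# boundary check at theta = 0 for each term.

#' Specify a random term for [fit_reml()]
#'
#' @param z incidence: a factor (one level per effect), or a numeric /
#'   sparse incidence matrix with one column per effect level.
#' @param K optional covariance among effect levels (symmetric PSD);
#'   `NULL` means identity.
#' @param label term label (used in outputs and nesting checks).
#' @return a `reml_term` list.
#' @export
reml_term <- function(z, K = NULL, label = NULL) {
  if (is.factor(z) || is.character(z)) {
    lab <- label %||% deparse(substitute(z))
    z <- incidence(z)
  } else {
    lab <- label %||% "term"
    z <- as(as(z, "generalMatrix"), "CsparseMatrix")
  }
  if (!is.null(K)) {
    K <- as.matrix(K)
    if (nrow(K) != ncol(z))
      stop_format("term '%s': K is %d x %d but Z has %d columns",
                  lab, nrow(K), ncol(K), ncol(z))
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      stop_format("term '%s': K is not symmetric", lab)
  }
  structure(list(Z = z, K = K, label = lab), class = "reml_term")
}

# factor L with K = L L' via eigendecomposition (tolerates PSD rank deficiency)
psd_factor <- function(K, label) {
  ed <- eigen((K + t(K)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ed$values), 1)
  if (min(ed$values) < -tol)
    stop_format("term '%s': covariance K is not positive semidefinite (min eigenvalue %.3g)",
                label, min(ed$values))
  ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nrow(K))
}

#' Fit a linear mixed model by REML
#'
#' Maximizes the restricted likelihood of
#' `y = X beta + sum_j Z_j u_j + e`, `u_j ~ N(0, sigma2_j K_j)`,
#' `e ~ N(0, sigma2_e I)`, over the non-negative variance orthant.
#' Returns estimates, BLUPs `u_hat_j`, their prediction error variances,
#' fixed effects with standard errors, and the restricted log-likelihood
#' (profiled criterion, comparable across nested fits on the same data).
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix; `NULL` for an intercept. Rank
#'   deficient columns are dropped (pivoted QR).
#' @param random list of [reml_term()] objects (possibly empty).
#' @param pev_terms labels of terms for which prediction error variances of
#'   the BLUPs are computed (`TRUE` = all, `FALSE`/`NULL` = none).
#' @param options list: `maxit` (default 200), `reltol` (1e-10 on the
#'   criterion), `boundary_tol` (theta below this is refit at exactly 0).
#' @return an object of class `vc_fit`; see Details.
#' @details The fitted object carries `sigma2` (named vector of variance
#'   components, last element `residual`), `logLik`, `beta`, `se_beta`,
#'   `blup` and `pev` (named lists), `reliability` (1 - PEV / (sigma2_j
#'   K_jii)), `boundary` (labels of components estimated at zero) and a
#'   `convergence` record. Two random terms with (near) proportional
#'   marginal covariances Z K Z' trigger a non-identifiability warning and
#'   usually a boundary solution.
#' @export
fit_reml <- function(y, X = NULL, random = list(), pev_terms = TRUE,
                     options = list()) {
  opts <- utils::modifyList(list(maxit = 200L, reltol = 1e-10,
                                 boundary_tol = 1e-6, warn_identifiability = TRUE),
                            options)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop_format("response contains missing values; subset first")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  if (n <= p) stop_format("need more observations (%d) than fixed effects (%d)", n, p)
  if (inherits(random, "reml_term")) random <- list(random)
  J <- length(random)
  labels <- vapply(seq_len(J), function(j)
    random[[j]]$label %||% paste0("term", j), "")
  if (anyDuplicated(labels)) stop_format("random term labels must be unique")

  Ztil <- vector("list", J)
  Lfac <- vector("list", J)
  lev <- vector("list", J)
  for (j in seq_len(J)) {
    tm <- random[[j]]
    if (!inherits(tm, "reml_term")) tm <- reml_term(tm$Z %||% tm[[1]], tm$K, labels[j])
    if (nrow(tm$Z) != n)
      stop_format("term '%s': incidence has %d rows, response has %d",
                  labels[j], nrow(tm$Z), n)
    lev[[j]] <- colnames(tm$Z) %||% as.character(seq_len(ncol(tm$Z)))
    if (is.null(tm$K)) {
      Ztil[[j]] <- tm$Z
    } else {
      Lfac[[j]] <- psd_factor(tm$K, labels[j])
      Ztil[[j]] <- as(tm$Z %*% Lfac[[j]], "CsparseMatrix")
    }
  }
  qs <- vapply(Ztil, ncol, 0L)
  Xs <- as(as(X, "generalMatrix"), "CsparseMatrix")
  M <- do.call(cbind, c(list(Xs), Ztil))
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(M))
  Mty <- as.numeric(Matrix::crossprod(M, y))
  yty <- sum(y^2)
  idx <- split(p + seq_len(sum(qs)), rep(seq_len(J), qs))

  if (J > 0 && opts$warn_identifiability && n <= 600)
    check_identifiability(Ztil, labels, n)

  np <- n - p
  const <- np * (1 + log(2 * pi))
  nll <- function(rho, active = seq_len(J)) {
    dinv <- rep(0, p + sum(qs))
    for (k in seq_along(active)) dinv[idx[[active[k]]]] <- exp(-rho[k])
    Cm <- MtM + Matrix::Diagonal(x = dinv)
    keep <- c(seq_len(p), unlist(idx[active], use.names = FALSE))
    Cm <- Cm[keep, keep, drop = FALSE]
    ch <- tryCatch(Matrix::Cholesky(Cm, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    b <- as.numeric(Matrix::solve(ch, Mty[keep], system = "A"))
    ypy <- yty - sum(Mty[keep] * b)
    if (ypy <= 0) return(1e10)
    0.5 * (np * log(ypy / np) + ldet +
             sum(qs[active] * rho) + const)
  }

  # optimize over log variance ratios, deterministic equal-split start
  if (J == 0L) {
    rho_hat <- numeric(0); active <- integer(0)
    value <- nll(numeric(0), integer(0)); counts <- 0L; convcode <- 0L
  } else if (J == 1L) {
    op <- optimize(function(r) nll(r, 1L), c(-25, 25), tol = 1e-9)
    rho_hat <- op$minimum; value <- op$objective
    counts <- NA_integer_; convcode <- 0L; active <- 1L
  } else {
    st <- rep(0, J)
    op <- optim(st, nll, method = "Nelder-Mead",
                control = list(maxit = opts$maxit * 5L, reltol = opts$reltol))
    op2 <- optim(op$par, nll, method = "Nelder-Mead",
                 control = list(maxit = opts$maxit * 5L, reltol = opts$reltol))
    if (op2$value < op$value) op <- op2
    rho_hat <- op$par; value <- op$value
    counts <- op$counts[[1L]]; convcode <- op$convergence; active <- seq_len(J)
  }

  # boundary handling: components pinned near zero are refit at exactly zero
  boundary <- character(0)
  repeat {
    theta <- exp(rho_hat)
    small <- which(theta < opts$boundary_tol)
    if (length(small) == 0L || length(active) == 0L) break
    drop_j <- active[small[1L]]
    active2 <- setdiff(active, drop_j)
    if (length(active2) == 0L) {
      v2 <- nll(numeric(0), integer(0)); r2 <- numeric(0)
    } else if (length(active2) == 1L) {
      op <- optimize(function(r) nll(r, active2), c(-25, 25), tol = 1e-9)
      r2 <- op$minimum; v2 <- op$objective
    } else {
      op <- optim(rho_hat[-small[1L]], nll, active = active2,
                  method = "Nelder-Mead",
                  control = list(maxit = opts$maxit * 5L, reltol = opts$reltol))
      r2 <- op$par; v2 <- op$value
    }
    if (v2 <= value + 1e-7) {
      boundary <- c(boundary, labels[drop_j])
      active <- active2; rho_hat <- r2; value <- v2
    } else break
  }

  # final solve for estimates, BLUPs and PEVs
  theta_full <- rep(0, J)
  theta_full[active] <- exp(rho_hat)
  dinv <- rep(0, p + sum(qs))
  for (j in active) dinv[idx[[j]]] <- 1 / theta_full[j]
  keep <- c(seq_len(p), unlist(idx[active], use.names = FALSE))
  Cm <- (MtM + Matrix::Diagonal(x = dinv))[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Cm, LDL = FALSE, perm = TRUE)
  b <- as.numeric(Matrix::solve(ch, Mty[keep], system = "A"))
  ypy <- yty - sum(Mty[keep] * b)
  s2e <- ypy / np
  sigma2 <- setNames(c(theta_full * s2e, s2e), c(labels, "residual"))
  beta <- setNames(b[seq_len(p)], colnames(X))

  want_pev <- if (isTRUE(pev_terms)) labels
              else if (isFALSE(pev_terms) || is.null(pev_terms)) character(0)
              else intersect(pev_terms, labels)
  need_cols <- seq_len(p)
  pos_of <- function(j) match(idx[[j]], keep)
  for (j in active) if (labels[j] %in% want_pev) need_cols <- c(need_cols, pos_of(j))
  Ei <- Matrix::sparseMatrix(i = need_cols, j = seq_along(need_cols),
                             x = 1, dims = c(length(keep), length(need_cols)))
  Cinv_cols <- as.matrix(Matrix::solve(ch, Ei, system = "A"))
  se_beta <- setNames(sqrt(pmax(s2e * diag(Cinv_cols[seq_len(p), seq_len(p),
                                                     drop = FALSE]), 0)),
                      colnames(X))

  blup <- setNames(vector("list", J), labels)
  pev <- setNames(vector("list", J), labels)
  col_at <- p
  for (j in seq_len(J)) {
    if (!(j %in% active)) {
      blup[[j]] <- setNames(rep(0, length(lev[[j]])), lev[[j]])
      if (labels[j] %in% want_pev) pev[[j]] <- setNames(rep(0, length(lev[[j]])), lev[[j]])
      next
    }
    alpha <- b[pos_of(j)]
    u <- if (is.null(Lfac[[j]])) alpha else as.numeric(Lfac[[j]] %*% alpha)
    blup[[j]] <- setNames(u, lev[[j]])
    if (labels[j] %in% want_pev) {
      cols <- col_at + seq_len(qs[j])
      col_at <- col_at + qs[j]
      Cjj <- Cinv_cols[pos_of(j), cols, drop = FALSE]
      pv <- if (is.null(Lfac[[j]])) diag(Cjj)
            else rowSums((Lfac[[j]] %*% Cjj) * Lfac[[j]])
      pev[[j]] <- setNames(pmax(s2e * pv, 0), lev[[j]])
    }
  }

  reliability <- setNames(vector("list", J), labels)
  for (j in seq_len(J)) {
    if (is.null(pev[[j]])) next
    kdiag <- if (is.null(random[[j]]$K)) rep(1, qs[j]) else diag(random[[j]]$K)
    denom <- sigma2[j] * kdiag
    r2 <- ifelse(denom > 0, pmax(0, pmin(1, 1 - pev[[j]] / denom)), 0)
    reliability[[j]] <- setNames(r2, lev[[j]])
  }

  structure(list(sigma2 = sigma2, theta = setNames(theta_full, labels),
                 logLik = -value, beta = beta, se_beta = se_beta,
                 blup = blup, pev = pev, reliability = reliability,
                 boundary = boundary, labels = labels, N = n, p = p,
                 y = y, X = X,
                 convergence = list(iterations = counts, code = convcode,
                                    criterion = value)),
            class = "vc_fit")
}

check_identifiability <- function(Ztil, labels, n) {
  S <- lapply(Ztil, function(z) as.matrix(Matrix::tcrossprod(z)))
  S <- c(S, list(diag(n)))
  labs <- c(labels, "residual")
  for (a in seq_along(S)) for (b in seq_len(a - 1L)) {
    num <- sum(S[[a]] * S[[b]])
    den <- sqrt(sum(S[[a]]^2) * sum(S[[b]]^2))
    if (den > 0 && num / den > 0.9999)
      warn_format(paste0("random terms '%s' and '%s' have proportional ",
                         "marginal covariances; the fit is not identifiable ",
                         "and a boundary solution is expected"),
                  labs[b], labs[a])
  }
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance-component fit\n")
  cat(sprintf("  n = %d, fixed effects = %d, logLik = %.4f\n", x$N, x$p, x$logLik))
  print(round(x$sigma2, 6))
  if (length(x$boundary))
    cat("  components at boundary (0):", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' @param full,reduced `vc_fit` objects on the same response and fixed
#'   design, the reduced model's random terms a subset of the full model's.
#' @return list of class `lrt_result` with the statistic (floored at 0),
#'   the difference in number of variance components, and the
#'   boundary-corrected chi-square mixture p-value
#'   (`0.5 chi2_0 + 0.5 chi2_1` when one component is dropped), usable as a
#'   fast pre-screen before permutation calibration.
#' @export
likelihood_ratio <- function(full, reduced) {
  stopifnot(inherits(full, "vc_fit"), inherits(reduced, "vc_fit"))
  if (!isTRUE(all.equal(full$y, reduced$y, tolerance = 1e-12)))
    stop_format("fits are not on the same response")
  if (!isTRUE(all.equal(unname(full$X), unname(reduced$X), tolerance = 1e-12)))
    stop_format("fits do not share the fixed-effect design")
  if (!all(reduced$labels %in% full$labels))
    stop_format("reduced model is not nested in the full model")
  df <- length(full$labels) - length(reduced$labels)
  lrt <- max(0, 2 * (full$logLik - reduced$logLik))
  p_mix <- if (df == 1L) {
    if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    pchisq(lrt, df = max(df, 1L), lower.tail = FALSE)
  }
  structure(list(lrt = lrt, df = df, p_mixture = p_mix), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT = %.4f (df = %d), chi-square mixture p = %.4g\n",
              x$lrt, x$df, x$p_mixture))
  invisible(x)
}
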
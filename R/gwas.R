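# Stage 2a: single-marker mixed-model association scan with a polygenic
# term (covariance = whole-genome GRM), permutation/Bonferroni thresholds,
# per-marker heritability, and the allelic-substitution contrast.
#
# The background variance components are estimated once under the
# no-marker null and held fixed across markers (the standard two-step
# approximation); `exact_per_marker = TRUE` re-estimates them per marker.

#' Mixed-model association scan
#'
#' For each marker, fits `y* = X beta + m_i a_i + u + e` with
#' `u ~ N(0, sigma2_u G)` and tests the fixed marker effect by a Wald
#' t-test. With the background components fixed (default), the model is
#' whitened by `V^{-1/2}` once and every marker reduces to a generalized
#' least-squares slope, so the scan is a single matrix product.
#'
#' @param ystar named vector of deregressed phenotypes (accession level).
#' @param genotypes a [genotype_matrix()]; accessions are aligned by name.
#' @param G whole-genome [build_grm()] (or `NULL` for an ordinary
#'   least-squares scan without polygenic control).
#' @param covariates optional fixed covariates (e.g. structure PCs).
#' @param h2_ref optional trait heritability used for the explained
#'   fraction column.
#' @param exact_per_marker re-estimate variance components for every
#'   marker (slow; changes little in moderate panels).
#' @return data.frame of class `gwas_result`: marker, chromosome,
#'   position_bp, marker_type, effect, se, p_wald, neg_log10_p, two_pq,
#'   h2_gwas, explained_pct, skipped flag for monomorphic markers. The
#'   null-model variance components are kept in `attr(, "null_fit")`.
#' @export
gwas_scan <- function(ystar, genotypes, G = NULL, covariates = NULL,
                      h2_ref = NULL, exact_per_marker = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- align_ids(ystar, genotypes)
  y <- as.numeric(ystar[ids])
  W <- mean_impute(genotypes$values[ids, , drop = FALSE])
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
  p_allele <- (colMeans(W) + 1) / 2
  mono <- p_allele <= 0 | p_allele >= 1 | apply(W, 2L, sd) == 0

  if (!is.null(G)) {
    eig <- sub_eigen(G, ids)
    null_fit <- fit_kinship_reml(y, X, eig = eig)
    s <- 1 / sqrt(1 + null_fit$theta[["genomic"]] * eig$d)
    Ut <- t(eig$U)
    ys <- s * as.numeric(Ut %*% y)
    Xs <- s * (Ut %*% X)
    Ws <- s * (Ut %*% W)
  } else {
    null_fit <- NULL
    ys <- y; Xs <- X; Ws <- W
  }
  stats <- marker_gls(ys, Xs, Ws)
  if (isTRUE(exact_per_marker) && !is.null(G)) {
    for (k in which(!mono)) {
      fk <- fit_kinship_reml(y, cbind(X, W[, k]), eig = eig)
      eff <- unname(fk$beta[length(fk$beta)])
      se <- unname(fk$se_beta[length(fk$se_beta)])
      tt <- eff / se
      stats$effect[k] <- eff; stats$se[k] <- se
      stats$p[k] <- 2 * pt(-abs(tt), df = n - ncol(X) - 1L)
    }
  }
  two_pq <- 2 * p_allele * (1 - p_allele)
  if (!is.null(null_fit)) {
    s2bg <- null_fit$sigma2[["genomic"]] + null_fit$sigma2[["residual"]]
  } else {
    s2bg <- stats$s2
  }
  h2m <- two_pq * stats$effect^2 / (two_pq * stats$effect^2 + s2bg)
  out <- data.frame(marker = colnames(W),
                    chromosome = genotypes$map$chromosome,
                    position_bp = genotypes$map$position_bp,
                    marker_type = genotypes$map$marker_type,
                    effect = stats$effect, se = stats$se,
                    p_wald = stats$p,
                    neg_log10_p = -log10(stats$p),
                    two_pq = two_pq, h2_gwas = h2m,
                    stringsAsFactors = FALSE)
  out$explained_pct <- if (!is.null(h2_ref)) explained_pct(out$h2_gwas, h2_ref, 1) else NA_real_
  out$skipped <- mono
  out[mono, c("effect", "se", "p_wald", "neg_log10_p", "h2_gwas", "explained_pct")] <- NA_real_
  attr(out, "null_fit") <- null_fit
  attr(out, "n_accessions") <- n
  class(out) <- c("gwas_result", "data.frame")
  out
}

# vectorized per-marker GLS slopes after whitening: residualize on X,
# slope, per-marker residual variance, Wald t with n - p - 1 df
marker_gls <- function(ys, Xs, Ws) {
  n <- length(ys); p <- ncol(Xs)
  qx <- qr(Xs)
  yr <- qr.resid(qx, ys)
  Wr <- qr.resid(qx, Ws)
  mm <- colSums(Wr^2)
  ok <- mm > 1e-12
  effect <- se <- pval <- rep(NA_real_, ncol(Ws))
  effect[ok] <- colSums(Wr[, ok, drop = FALSE] * yr) / mm[ok]
  df <- n - p - 1L
  rss <- pmax(sum(yr^2) - effect[ok]^2 * mm[ok], 1e-300)
  s2 <- rss / df
  se[ok] <- sqrt(s2 / mm[ok])
  tt <- effect[ok] / se[ok]
  pval[ok] <- 2 * pt(-abs(tt), df = df)
  pval[ok] <- pmax(pval[ok], 1e-300)
  list(effect = effect, se = se, p = pval, s2 = mean(s2))
}

align_ids <- function(ystar, genotypes) {
  if (is.null(names(ystar)))
    stop_format("ystar must be named by accession id")
  ids <- intersect(genotypes$accession_ids, names(ystar))
  ids <- ids[!is.na(ystar[ids])]
  if (length(ids) < 3L)
    stop_format("fewer than 3 accessions shared between phenotypes and genotypes")
  ids
}

sub_eigen <- function(G, ids) {
  stopifnot(inherits(G, "grm"))
  if (identical(G$accession_ids, ids)) return(grm_eigen(G))
  idx <- match(ids, G$accession_ids)
  if (anyNA(idx)) stop_format("GRM does not cover all phenotyped accessions")
  ed <- eigen(G$matrix[idx, idx], symmetric = TRUE)
  list(U = ed$vectors, d = pmax(ed$values, 0), ids = ids)
}

#' Permutation significance threshold for the association scan
#'
#' Permutes the phenotype across accessions (breaking the
#' genotype-phenotype link while keeping the marker correlation
#' structure), re-runs the scan per permutation, pools the per-marker
#' p-values into an empirical null, and places the threshold at the
#' Bonferroni per-test quantile `global_alpha / n_tests` of that null,
#' reported on the -log10(p) scale.
#'
#' @inheritParams gwas_scan
#' @param n_perm number of permutations (>= 100).
#' @param global_alpha family-wise error target (default 0.05).
#' @param n_tests number of tests for the Bonferroni division (default:
#'   number of polymorphic markers).
#' @param seed permutation seed.
#' @return list of class `sig_threshold`: `threshold_neg_log10_p`,
#'   `per_test_alpha`, `global_alpha`, `n_tests`, `n_perm`, `seed`.
#' @export
gwas_threshold <- function(ystar, genotypes, G = NULL, covariates = NULL,
                           n_perm = 200L, global_alpha = 0.05,
                           n_tests = NULL, seed = 1L) {
  if (n_perm < 100L) stop_format("n_perm must be at least 100")
  ids <- align_ids(ystar, genotypes)
  y <- as.numeric(ystar[ids])
  W <- mean_impute(genotypes$values[ids, , drop = FALSE])
  mono <- apply(W, 2L, sd) == 0
  W <- W[, !mono, drop = FALSE]
  n <- length(y)
  n_tests <- n_tests %||% ncol(W)
  alpha_i <- per_test_alpha(global_alpha, n_tests)
  min_perm <- ceiling(1 / (alpha_i * ncol(W)))
  if (n_perm < min_perm)
    stop_format("n_perm = %d too small for the %.3g quantile; need at least %d",
                n_perm, alpha_i, min_perm)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
  eig <- if (!is.null(G)) sub_eigen(G, ids) else NULL
  Ut <- if (!is.null(eig)) t(eig$U) else NULL
  Wr0 <- if (!is.null(eig)) Ut %*% W else W
  Xr0 <- if (!is.null(eig)) Ut %*% X else X

  set.seed(derive_seed(seed, 5L))
  pool <- matrix(NA_real_, n_perm, ncol(W))
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    if (!is.null(eig)) {
      ro <- list(yr = as.numeric(Ut %*% yp), Xr = Xr0)
      nf <- fit_region_null(ro$yr, ro$Xr, eig$d)
      s <- 1 / sqrt(1 + exp(nf$lth) * eig$d)
      st <- marker_gls(s * ro$yr, s * Xr0, s * Wr0)
    } else {
      st <- marker_gls(yp, X, W)
    }
    pool[b, ] <- st$p
  }
  thr_p <- quantile(pool, probs = alpha_i, type = 1, names = FALSE, na.rm = TRUE)
  structure(list(threshold_neg_log10_p = -log10(thr_p),
                 per_test_alpha = alpha_i, global_alpha = global_alpha,
                 n_tests = n_tests, n_perm = n_perm, seed = seed,
                 kind = "gwas"),
            class = "sig_threshold")
}

#' @export
print.sig_threshold <- function(x, ...) {
  cat(sprintf("%s permutation threshold: alpha %.3g / %d tests = %.3g per test\n",
              toupper(x$kind), x$global_alpha, x$n_tests, x$per_test_alpha))
  if (!is.null(x$threshold_neg_log10_p))
    cat(sprintf("  -log10(p) threshold = %.3f (%d permutations, seed %d)\n",
                x$threshold_neg_log10_p, x$n_perm, x$seed))
  if (!is.null(x$threshold_lrt))
    cat(sprintf("  LRT threshold = %.3f (%d permutations, seed %d)\n",
                x$threshold_lrt, x$n_perm, x$seed))
  invisible(x)
}

#' Bonferroni per-test significance level
#'
#' @param global_alpha family-wise error target.
#' @param n_tests number of tests.
#' @return `global_alpha / n_tests`.
#' @export
per_test_alpha <- function(global_alpha, n_tests) {
  stopifnot(global_alpha > 0, global_alpha < 1, n_tests >= 1)
  global_alpha / n_tests
}

#' Per-marker heritability
#'
#' `h2_GWAS = 2pq m^2 / (2pq m^2 + sigma2_u + sigma2_e)`: the variance
#' contributed by the marker at its allele frequency against the total of
#' marker, polygenic and residual variance. The 2pq-times-squared-effect
#' convention is inferred from the reporting style that prints 2pq next to
#' the marker heritability; it is not uniquely pinned down by the source
#' analyses, and is documented as such.
#'
#' Under full inbreeding the realized variance of a dosage-coded marker is
#' `4pq`, twice the Hardy-Weinberg `2pq`, so the conventional form roughly
#' halves the variance a causal marker actually contributes in an inbred
#' panel; supplying `var_marker` (the empirical variance of the marker
#' codes) replaces `2pq` and makes the estimate recover planted variance
#' shares in simulation.
#'
#' @param effect estimated allele-substitution effect.
#' @param p allele frequency of the +1 allele.
#' @param sigma2_u,sigma2_e background polygenic and residual variances.
#' @param var_marker optional empirical marker-code variance used in place
#'   of `2 p (1 - p)`.
#' @return the marker heritability.
#' @export
marker_h2 <- function(effect, p, sigma2_u, sigma2_e, var_marker = NULL) {
  vqtl <- (var_marker %||% (2 * p * (1 - p))) * effect^2
  den <- vqtl + sigma2_u + sigma2_e
  if (any(den <= 0)) stop_format("zero denominator in marker heritability")
  vqtl / den
}

#' Welch's unequal-variance t-test between allelic classes
#'
#' @param y phenotype values.
#' @param genotype_classes factor/vector with exactly two classes.
#' @return list: `t`, `df`, `p`, `class_means`, `class_n`.
#' @export
welch_allelic_test <- function(y, genotype_classes) {
  g <- factor(genotype_classes)
  if (nlevels(g) != 2L)
    stop_format("allelic-substitution test needs exactly 2 classes, got %d", nlevels(g))
  ns <- table(g)
  if (any(ns < 2L))
    stop_format("each allelic class needs at least 2 observations")
  y1 <- y[g == levels(g)[1L]]; y2 <- y[g == levels(g)[2L]]
  if (sd(y1) == 0 && sd(y2) == 0) {
    d <- mean(y1) - mean(y2)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_,
                p = if (d == 0) 1 else 0,
                class_means = c(mean(y1), mean(y2)),
                class_n = as.integer(ns)))
  }
  tt <- t.test(y1, y2, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       class_means = setNames(c(mean(y1), mean(y2)), levels(g)),
       class_n = as.integer(ns))
}
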
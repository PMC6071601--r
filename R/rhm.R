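# Stage 2b: regional heritability scan. For every window the full model
#   y* = X beta + u + v + e,  u ~ N(0, sigma2_u G),  v ~ N(0, sigma2_v G_REG)
# is compared by LRT against the reduced model without the regional term.
# The same whole-genome G is used for every window (regional markers are
# not removed from it by default); everything is evaluated in the
# eigenbasis of G with the regional block handled as a low-rank update, so
# a window fit costs O(n m^2).

# rotated, centered, frequency-scaled regional marker block so that
# G_REG = Wt Wt' (on the phenotyped subset)
region_block <- function(W, idx, Ut, scale = "2pq") {
  Wk <- W[, idx, drop = FALSE]
  p <- (colMeans(Wk) + 1) / 2
  poly <- p > 0 & p < 1 & apply(Wk, 2L, sd) > 0
  Wk <- Wk[, poly, drop = FALSE]
  if (ncol(Wk) == 0L) return(NULL)
  p <- p[poly]
  Wc <- sweep(Wk, 2L, colMeans(Wk))
  denom <- if (scale == "2pq") sum(2 * p * (1 - p)) else sum(apply(Wk, 2L, var))
  (Ut %*% Wc) / sqrt(denom)
}

#' Whole-genome heritability per marker set
#'
#' Fits the reduced (no-region) polygenic model on each marker set and
#' reports `h2_G = sigma2_u / (sigma2_u + sigma2_e)`, optionally with the
#' explained share `h2_G / h2_trait`.
#'
#' @param ystar named accession-level response.
#' @param genotypes a [genotype_matrix()].
#' @param marker_sets named list of marker-id/index subsets; default the
#'   conventional three: SNP-only, DArT-only, combined.
#' @param h2_trait optional stage-1 trait heritability for the explained
#'   percentage.
#' @param scale GRM scaling, see [build_grm()].
#' @return data.frame of class `genome_h2`: set, n_markers, h2_G,
#'   explained_pct, sigma2_u, sigma2_e, logLik.
#' @export
genome_h2 <- function(ystar, genotypes, marker_sets = NULL, h2_trait = NULL,
                      scale = "2pq") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(marker_sets)) {
    ty <- genotypes$map$marker_type
    marker_sets <- list(SNP = which(ty == "SNP"), DART = which(ty == "DART"),
                        combined = seq_len(nrow(genotypes$map)))
    marker_sets <- marker_sets[vapply(marker_sets, length, 0L) > 0L]
  }
  rows <- lapply(names(marker_sets), function(nm) {
    res <- tryCatch({
      G <- build_grm(genotypes, marker_subset = marker_sets[[nm]], scale = scale)
      ids <- align_ids(ystar, genotypes)
      eig <- sub_eigen(G, ids)
      fit <- fit_kinship_reml(as.numeric(ystar[ids]), eig = eig)
      data.frame(set = nm, n_markers = length(G$markers_used),
                 h2_G = fit$h2,
                 explained_pct = if (!is.null(h2_trait))
                   explained_pct(fit$h2, h2_trait, 2) else NA_real_,
                 sigma2_u = fit$sigma2[["genomic"]],
                 sigma2_e = fit$sigma2[["residual"]],
                 logLik = fit$logLik, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(set = nm, n_markers = NA_integer_, h2_G = NA_real_,
                 explained_pct = NA_real_, sigma2_u = NA_real_,
                 sigma2_e = NA_real_, logLik = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genome_h2", "data.frame")
  out
}

#' Regional heritability scan
#'
#' @param ystar named accession-level response (deregressed values).
#' @param genotypes a [genotype_matrix()].
#' @param windows a [window_grid()]; when `NULL`, the default 2-Mb /
#'   1-Mb-step grid over the marker map.
#' @param G whole-genome [build_grm()]; built from all markers when `NULL`.
#' @param h2_ref optional trait heritability for explained fractions.
#' @param exclude_region_from_G rebuild the background GRM without the
#'   window markers for each window (slower; default keeps the same G for
#'   all windows, the conservative convention).
#' @param scale GRM scaling, see [build_grm()].
#' @param use_score_skip use the analytic boundary check at
#'   `sigma2_v = 0` to shortcut windows whose regional variance estimate
#'   is pinned at zero (identical results, fewer optimizations).
#' @return data.frame of class `rhm_result`, one row per window:
#'   variance components, `h2_rhm = sigma2_v / (sigma2_v + sigma2_u +
#'   sigma2_e)`, LRT, chi-square-mixture screening p-value,
#'   explained fraction. The reduced-model fit is cached in
#'   `attr(, "null_fit")`; `attr(, "h2_background")` holds the background
#'   share per window. Overlapping windows test correlated hypotheses and
#'   double-count regional signal; downstream summaries must merge
#'   overlapping significant windows (see [compare_gwas_rhm()]).
#' @export
rhm_scan <- function(ystar, genotypes, windows = NULL, G = NULL, h2_ref = NULL,
                     exclude_region_from_G = FALSE, scale = "2pq",
                     use_score_skip = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(windows)) windows <- window_grid(genotypes$map)
  if (is.null(G)) G <- build_grm(genotypes, scale = scale)
  ids <- align_ids(ystar, genotypes)
  y <- as.numeric(ystar[ids])
  W <- mean_impute(genotypes$values[ids, , drop = FALSE])
  eig <- sub_eigen(G, ids)
  Ut <- t(eig$U)
  X <- matrix(1, length(y), 1)
  ro <- list(yr = as.numeric(Ut %*% y), Xr = Ut %*% X)
  nf <- fit_region_null(ro$yr, ro$Xr, eig$d)
  null_parts <- reml_parts(nf$lth, 0, eig$d, ro$yr, ro$Xr,
                           matrix(0, length(y), 0), FALSE)

  nw <- nrow(windows)
  res <- data.frame(window_id = windows$window_id,
                    chromosome = windows$chromosome,
                    start_bp = windows$start_bp, end_bp = windows$end_bp,
                    n_markers = NA_integer_, sigma2_v = NA_real_,
                    sigma2_u = NA_real_, sigma2_e = NA_real_,
                    h2_rhm = NA_real_, lrt = NA_real_,
                    p_mixture = NA_real_, failed = FALSE,
                    stringsAsFactors = FALSE)
  h2_bg <- rep(NA_real_, nw)
  for (k in seq_len(nw)) {
    idx <- windows$markers[[k]]
    Wt <- region_block(W, idx, Ut, scale)
    if (is.null(Wt)) { res$failed[k] <- TRUE; next }
    res$n_markers[k] <- ncol(Wt)
    fit <- tryCatch({
      if (exclude_region_from_G) {
        keep <- setdiff(seq_len(ncol(genotypes$values)), idx)
        Gk <- build_grm(genotypes, marker_subset = keep, scale = scale)
        ek <- sub_eigen(Gk, ids)
        Utk <- t(ek$U)
        rok <- list(yr = as.numeric(Utk %*% y), Xr = Utk %*% X)
        nfk <- fit_region_null(rok$yr, rok$Xr, ek$d)
        Wtk <- region_block(W, idx, Utk, scale)
        fit_region_ml(rok$yr, rok$Xr, ek$d, Wtk, nfk, use_score_skip)
      } else {
        fit_region_ml(ro$yr, ro$Xr, eig$d, Wt, nf, use_score_skip)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) { res$failed[k] <- TRUE; next }
    tot <- fit$sigma2_v + fit$sigma2_u + fit$sigma2_e
    res$sigma2_v[k] <- fit$sigma2_v
    res$sigma2_u[k] <- fit$sigma2_u
    res$sigma2_e[k] <- fit$sigma2_e
    res$h2_rhm[k] <- fit$sigma2_v / tot
    res$lrt[k] <- fit$lrt
    res$p_mixture[k] <- if (fit$lrt <= 0) 1 else 0.5 * pchisq(fit$lrt, 1, lower.tail = FALSE)
    h2_bg[k] <- fit$sigma2_u / tot
  }
  res$explained_pct <- if (!is.null(h2_ref)) explained_pct(res$h2_rhm, h2_ref, 1) else NA_real_
  attr(res, "null_fit") <- list(logLik = null_parts$logLik,
                                sigma2_u = null_parts$sigma2_u,
                                sigma2_e = null_parts$sigma2_e,
                                h2_G = null_parts$sigma2_u /
                                  (null_parts$sigma2_u + null_parts$sigma2_e))
  attr(res, "h2_background") <- h2_bg
  attr(res, "n_accessions") <- length(y)
  class(res) <- c("rhm_result", "data.frame")
  res
}

#' Permutation significance threshold for the regional scan
#'
#' Permutes the response across accessions, recomputes every window's LRT,
#' pools the permuted statistics into an empirical null, converts observed
#' LRTs to empirical p-values against that null and thresholds them at the
#' Bonferroni per-test level `global_alpha / n_windows`.
#'
#' @inheritParams rhm_scan
#' @param n_perm number of permutations (>= 100).
#' @param global_alpha family-wise error target.
#' @param seed permutation seed.
#' @return list of class `sig_threshold` with `threshold_lrt` (the LRT a
#'   window must exceed), `per_test_alpha`, the pooled `null_lrt`
#'   distribution, and bookkeeping fields.
#' @export
rhm_threshold <- function(ystar, genotypes, windows = NULL, G = NULL,
                          n_perm = 200L, global_alpha = 0.05, seed = 1L,
                          scale = "2pq") {
  if (n_perm < 100L) stop_format("n_perm must be at least 100")
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(windows)) windows <- window_grid(genotypes$map)
  if (is.null(G)) G <- build_grm(genotypes, scale = scale)
  ids <- align_ids(ystar, genotypes)
  y <- as.numeric(ystar[ids])
  W <- mean_impute(genotypes$values[ids, , drop = FALSE])
  eig <- sub_eigen(G, ids)
  Ut <- t(eig$U)
  X <- matrix(1, length(y), 1)
  Xr <- Ut %*% X
  nw <- nrow(windows)
  alpha_i <- per_test_alpha(global_alpha, nw)
  min_perm <- ceiling(1 / (alpha_i * nw))
  if (n_perm < min_perm)
    stop_format("n_perm = %d too small for the %.3g quantile; need at least %d",
                n_perm, alpha_i, min_perm)
  blocks <- lapply(seq_len(nw), function(k)
    region_block(W, windows$markers[[k]], Ut))
  set.seed(derive_seed(seed, 6L))
  null_lrt <- matrix(NA_real_, n_perm, nw)
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(length(y))]
    yr <- as.numeric(Ut %*% yp)
    nfb <- fit_region_null(yr, Xr, eig$d)
    for (k in seq_len(nw)) {
      if (is.null(blocks[[k]])) next
      ft <- tryCatch(fit_region_ml(yr, Xr, eig$d, blocks[[k]], nfb, TRUE),
                     error = function(e) NULL)
      null_lrt[b, k] <- if (is.null(ft)) NA_real_ else ft$lrt
    }
  }
  pool <- null_lrt[is.finite(null_lrt)]
  structure(list(threshold_lrt = quantile(pool, probs = 1 - alpha_i,
                                          type = 1, names = FALSE),
                 null_lrt = pool, per_test_alpha = alpha_i,
                 global_alpha = global_alpha, n_tests = nw,
                 n_perm = n_perm, seed = seed, kind = "rhm"),
            class = "sig_threshold")
}

#' Empirical p-values and significance flags for a regional scan
#'
#' @param scan a [rhm_scan()] result.
#' @param threshold a [rhm_threshold()] result.
#' @return the scan with `p_perm`, `neg_log10_p` and `significant` columns.
#' @export
rhm_significance <- function(scan, threshold) {
  stopifnot(inherits(scan, "rhm_result"), inherits(threshold, "sig_threshold"))
  pool <- threshold$null_lrt
  np <- length(pool)
  scan$p_perm <- vapply(scan$lrt, function(l)
    if (!is.finite(l)) NA_real_ else (1 + sum(pool >= l)) / (1 + np), 0)
  scan$neg_log10_p <- -log10(scan$p_perm)
  scan$significant <- !is.na(scan$p_perm) & scan$p_perm <= threshold$per_test_alpha
  scan
}

#' Compare association-scan and regional-scan findings
#'
#' @param gwas a [gwas_scan()] result carrying a `significant` column (add
#'   one by comparing `neg_log10_p` to a [gwas_threshold()]).
#' @param rhm a [rhm_significance()]-annotated regional scan.
#' @return list of class `rhm_gwas_comparison`: per significant window
#'   whether a significant marker falls inside, counts of significant
#'   markers/windows, merged unique significant regions, and summed
#'   explained fractions per method.
#' @export
compare_gwas_rhm <- function(gwas, rhm) {
  stopifnot(inherits(gwas, "gwas_result"), inherits(rhm, "rhm_result"))
  if (!"significant" %in% names(gwas))
    stop_format("gwas result lacks a 'significant' column; apply a threshold first")
  if (!"significant" %in% names(rhm))
    stop_format("rhm result lacks a 'significant' column; apply rhm_significance() first")
  sg <- gwas[which(gwas$significant), , drop = FALSE]
  sw <- rhm[which(rhm$significant), , drop = FALSE]
  overlap <- if (nrow(sw)) vapply(seq_len(nrow(sw)), function(k)
    any(sg$chromosome == sw$chromosome[k] &
          sg$position_bp >= sw$start_bp[k] &
          sg$position_bp < sw$end_bp[k]), TRUE) else logical(0)
  windows_tab <- if (nrow(sw))
    data.frame(sw[, c("window_id", "chromosome", "start_bp", "end_bp",
                      "h2_rhm", "lrt", "explained_pct")],
               contains_gwas_hit = overlap, stringsAsFactors = FALSE)
  else data.frame()
  regions <- merge_regions(sw)
  markers_in_sig_windows <- if (nrow(sw)) sum(sw$n_markers[!duplicated(sw$window_id)]) else 0L
  structure(list(
    windows = windows_tab,
    unique_regions = regions,
    n_sig_gwas_markers = nrow(sg),
    n_sig_windows = nrow(sw),
    n_unique_regions = nrow(regions),
    gwas_hits_inside_rhm = if (nrow(sg)) vapply(seq_len(nrow(sg)), function(i)
      any(sw$chromosome == sg$chromosome[i] &
            sg$position_bp[i] >= sw$start_bp &
            sg$position_bp[i] < sw$end_bp), TRUE) else logical(0),
    explained_sum_gwas = sum(sg$explained_pct, na.rm = TRUE),
    explained_max_rhm = if (nrow(sw) && any(is.finite(sw$explained_pct)))
      max(sw$explained_pct, na.rm = TRUE) else NA_real_),
    class = "rhm_gwas_comparison")
}

# merge overlapping/adjacent significant windows per chromosome
merge_regions <- function(sw) {
  if (nrow(sw) == 0L)
    return(data.frame(chromosome = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  sw <- sw[order(sw$chromosome, sw$start_bp), , drop = FALSE]
  out <- list()
  cur <- sw[1L, c("chromosome", "start_bp", "end_bp")]
  for (i in seq_len(nrow(sw))[-1L]) {
    if (sw$chromosome[i] == cur$chromosome && sw$start_bp[i] <= cur$end_bp) {
      cur$end_bp <- max(cur$end_bp, sw$end_bp[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- sw[i, c("chromosome", "start_bp", "end_bp")]
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' @export
print.rhm_gwas_comparison <- function(x, ...) {
  cat(sprintf("GWAS vs RHM: %d significant marker(s); %d significant window(s) in %d unique region(s)\n",
              x$n_sig_gwas_markers, x$n_sig_windows, x$n_unique_regions))
  if (nrow(x$windows)) {
    cat(sprintf("  windows containing a GWAS hit: %d / %d\n",
                sum(x$windows$contains_gwas_hit), nrow(x$windows)))
  } else cat("  no significant associations\n")
  invisible(x)
}
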
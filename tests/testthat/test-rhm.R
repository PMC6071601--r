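test_that("whole-genome heritability behaves at the identity and null limits", {
  sim <- mapping_sim(n = 150, seed = 501, poly_h2 = 0.5,
                     markers_per_chr = 200, chr_mb = c(15, 15))
  hg <- genome_h2(sim$y, sim$gm, h2_trait = 0.5)
  expect_true(all(c("SNP", "DART", "combined") %in% hg$set))
  comb <- hg[hg$set == "combined", ]
  expect_gt(comb$h2_G, 0.25)
  expect_equal(comb$explained_pct, explained_pct(comb$h2_G, 0.5, 2))
  # identity kinship: h2_G equals the intraclass ratio from the same fit
  set.seed(502)
  y <- rnorm(60)
  fid <- fit_kinship_reml(y, G = diag(60))
  expect_equal(fid$h2, fid$sigma2[["genomic"]] /
                 (fid$sigma2[["genomic"]] + fid$sigma2[["residual"]]),
               tolerance = 1e-10)
  # pure noise: near-zero genomic heritability on average
  h0 <- vapply(1:10, function(s) {
    set.seed(510 + s)
    yn <- setNames(rnorm(nrow(sim$gm$values)), sim$gm$accession_ids)
    genome_h2(yn, sim$gm, marker_sets = list(all = seq_len(ncol(sim$gm$values))))$h2_G
  }, 0)
  expect_lt(mean(h0), 0.07)
})

test_that("regional scan recovers a planted window and is null-calibrated", {
  hits <- 0; h2_at_best <- numeric(0)
  for (s in 1:5) {
    sim <- mapping_sim(n = 300, seed = 520 + s, regional_h2 = 0.3,
                       poly_h2 = 0.3, markers_per_chr = 250, chr_mb = c(20, 20),
                       window = c(8e6, 10e6))
    G <- build_grm(sim$gm)
    scan <- rhm_scan(sim$y, sim$gm, window_grid(sim$gm$map), G)
    best <- which.max(scan$lrt)
    on_target <- scan$chromosome[best] == 1 &&
      scan$start_bp[best] <= 10e6 && scan$end_bp[best] >= 8e6
    hits <- hits + on_target
    h2_at_best <- c(h2_at_best, scan$h2_rhm[best])
    # invariants on every scan
    expect_true(all(scan$lrt >= 0, na.rm = TRUE))
    expect_true(all(scan$h2_rhm >= 0 & scan$h2_rhm <= 1, na.rm = TRUE))
    bg <- attr(scan, "h2_background")
    expect_true(all(scan$h2_rhm + bg <= 1 + 1e-8, na.rm = TRUE))
    expect_true(!is.unsorted(order(scan$chromosome, scan$start_bp)))
  }
  expect_gte(hits, 4)
  expect_gt(mean(h2_at_best), 0.15)
  # null trait: boundary mass and tiny regional estimates
  simn <- mapping_sim(n = 200, seed = 530, poly_h2 = 0.4,
                      markers_per_chr = 150, chr_mb = c(15, 15))
  scan0 <- rhm_scan(simn$y, simn$gm, window_grid(simn$gm$map), build_grm(simn$gm))
  expect_gt(mean(scan0$sigma2_v == 0, na.rm = TRUE), 0.3)
  expect_lt(mean(scan0$h2_rhm, na.rm = TRUE), 0.02)
})

test_that("the reduced-model likelihood is window-independent and cached", {
  sim <- mapping_sim(n = 100, seed = 541, poly_h2 = 0.4,
                     markers_per_chr = 100, chr_mb = c(10, 10))
  G <- build_grm(sim$gm)
  scan <- rhm_scan(sim$y, sim$gm, window_grid(sim$gm$map), G)
  nf <- attr(scan, "null_fit")
  expect_true(is.finite(nf$logLik))
  # recompute the null through the generic engine: same restricted likelihood
  ids <- names(sim$y)
  fit <- fit_kinship_reml(sim$y[ids], G = G$matrix)
  expect_equal(nf$logLik, fit$logLik, tolerance = 1e-6)
  expect_equal(nf$h2_G, fit$h2, tolerance = 1e-6)
})

test_that("window fits agree with the generic two-kinship REML solver", {
  sim <- mapping_sim(n = 80, seed = 543, regional_h2 = 0.35, poly_h2 = 0.2,
                     markers_per_chr = 120, chr_mb = c(10, 10),
                     window = c(4e6, 6e6))
  G <- build_grm(sim$gm)
  wg <- window_grid(sim$gm$map)
  scan <- rhm_scan(sim$y, sim$gm, wg, G, use_score_skip = FALSE)
  k <- which(scan$chromosome == 1 & scan$start_bp == 4e6)
  Greg <- build_regional_grm(sim$gm, wg[k, ])
  y <- sim$y[names(sim$y)]
  full <- fit_reml(as.numeric(y), NULL,
                   list(reml_term(Matrix::Diagonal(length(y)), K = G$matrix,
                                  label = "genome"),
                        reml_term(Matrix::Diagonal(length(y)), K = Greg$matrix,
                                  label = "region")),
                   pev_terms = FALSE,
                   options = list(warn_identifiability = FALSE))
  reduced <- fit_reml(as.numeric(y), NULL,
                      list(reml_term(Matrix::Diagonal(length(y)), K = G$matrix,
                                     label = "genome")), pev_terms = FALSE,
                      options = list(warn_identifiability = FALSE))
  lrt_generic <- likelihood_ratio(full, reduced)$lrt
  expect_equal(scan$lrt[k], lrt_generic, tolerance = 0.02)
  expect_equal(scan$sigma2_v[k], full$sigma2[["region"]], tolerance = 0.05)
})

test_that("permutation thresholding controls window-level significance", {
  sim <- mapping_sim(n = 150, seed = 545, regional_h2 = 0.35, poly_h2 = 0.2,
                     markers_per_chr = 150, chr_mb = c(15, 15),
                     window = c(6e6, 8e6))
  G <- build_grm(sim$gm)
  wg <- window_grid(sim$gm$map)
  scan <- rhm_scan(sim$y, sim$gm, wg, G)
  thr <- rhm_threshold(sim$y, sim$gm, wg, G, n_perm = 100, seed = 3)
  thr2 <- rhm_threshold(sim$y, sim$gm, wg, G, n_perm = 100, seed = 3)
  expect_identical(thr$threshold_lrt, thr2$threshold_lrt)
  ann <- rhm_significance(scan, thr)
  expect_true(any(ann$significant[ann$chromosome == 1 &
                                    ann$start_bp >= 5e6 & ann$start_bp <= 8e6]))
  expect_true(all(ann$lrt[ann$significant] > quantile(thr$null_lrt, 0.95)))
  expect_error(rhm_threshold(sim$y, sim$gm, wg, G, n_perm = 10), "at least 100")
})

test_that("comparison table captures containment and the empty case", {
  sim <- mapping_sim(n = 120, seed = 547, poly_h2 = 0.4,
                     markers_per_chr = 100, chr_mb = c(10, 10))
  G <- build_grm(sim$gm)
  wg <- window_grid(sim$gm$map)
  scan <- rhm_scan(sim$y, sim$gm, wg, G)
  gsc <- gwas_scan(sim$y, sim$gm, G)
  gsc$significant <- FALSE
  ann <- scan; ann$p_perm <- 1; ann$significant <- FALSE
  class(ann) <- class(scan)
  cmp <- compare_gwas_rhm(gsc, ann)
  expect_equal(cmp$n_sig_windows, 0)
  expect_equal(cmp$n_sig_gwas_markers, 0)
  expect_equal(nrow(cmp$windows), 0)
  # forced flags exercise containment and region merging
  gsc$significant[which(gsc$chromosome == 1 & gsc$position_bp >= 4e6 &
                          gsc$position_bp < 6e6)[1]] <- TRUE
  ann$significant[ann$chromosome == 1 & ann$start_bp %in% c(3e6, 4e6, 5e6)] <- TRUE
  cmp2 <- compare_gwas_rhm(gsc, ann)
  expect_equal(cmp2$n_unique_regions, 1)
  expect_true(any(cmp2$windows$contains_gwas_hit))
  expect_true(all(cmp2$gwas_hits_inside_rhm))
})
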
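test_that("null markers independent of the trait give uniform p-values", {
  sim <- mapping_sim(n = 200, seed = 301, poly_h2 = 0.5,
                     markers_per_chr = 250, chr_mb = c(20, 20))
  G <- build_grm(sim$gm)
  set.seed(302)
  n <- length(sim$y)
  Wnull <- matrix(sample(c(-1, 1), n * 500, TRUE), n,
                  dimnames = list(names(sim$y), sprintf("N%03d", 1:500)))
  mapn <- data.frame(marker_id = colnames(Wnull), chromosome = 1,
                     position_bp = seq_len(500), marker_type = "DART")
  scan <- gwas_scan(sim$y, genotype_matrix(Wnull, mapn), G)
  ks <- suppressWarnings(stats::ks.test(scan$p_wald, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("perfect association collapses to the regression slope", {
  gm <- tiny_panel(n = 40, m = 30, seed = 303)
  j <- which(apply(gm$values, 2, sd) > 0)[1]
  y <- gm$values[, j] - mean(gm$values[, j])
  names(y) <- gm$accession_ids
  scan <- gwas_scan(y, gm, G = NULL)      # sigma_u fixed at 0 (no kinship)
  expect_equal(scan$effect[j], 1, tolerance = 1e-10)
  expect_lt(scan$p_wald[j], 1e-200)
})

test_that("with identity G and zero polygenic variance the scan is per-marker OLS", {
  sim <- mapping_sim(n = 80, seed = 305, poly_h2 = 0, markers_per_chr = 60,
                     chr_mb = c(10, 10))
  scan0 <- gwas_scan(sim$y, sim$gm, G = NULL)
  ols <- vapply(seq_len(ncol(sim$gm$values)), function(j) {
    x <- sim$gm$values[, j]
    if (sd(x) == 0) return(c(NA_real_, NA_real_))
    f <- summary(lm(sim$y ~ x))
    c(coef(f)[2, 1], coef(f)[2, 4])
  }, numeric(2))
  ok <- !scan0$skipped
  expect_equal(scan0$effect[ok], ols[1, ok], tolerance = 1e-8)
  expect_equal(scan0$p_wald[ok], ols[2, ok], tolerance = 1e-8)
})

test_that("p-values are invariant to affine rescaling of the response", {
  sim <- mapping_sim(n = 100, seed = 307, poly_h2 = 0.4,
                     markers_per_chr = 80, chr_mb = c(10, 10))
  G <- build_grm(sim$gm)
  s1 <- gwas_scan(sim$y, sim$gm, G)
  s2 <- gwas_scan(3.7 * sim$y + 11, sim$gm, G)
  ok <- !s1$skipped
  expect_equal(s1$p_wald[ok], s2$p_wald[ok], tolerance = 1e-6)
  expect_equal(s2$effect[ok], 3.7 * s1$effect[ok], tolerance = 1e-6)
})

test_that("kinship correction controls structure-driven inflation", {
  cfg <- sim_config(n_accessions = 200, n_genotyped = 200, n_checks = 0,
                    n_blocks = 1, n_environments = 1,
                    chromosome_lengths_bp = c(20e6, 20e6),
                    markers_per_chromosome = 300, fraction_dart = 0,
                    missing_rate = 0, pool_divergence = 0.45,
                    breeding_fraction = 0,   # isolate the two-pool confounder
                    traits = list(tr = list(h2 = 0.5, c2_int = 0, block_var = 0)),
                    seed = 309)
  sim <- simulate_genotypes(cfg)
  # polygenic trait in a two-pool panel: correlated with pool membership,
  # so the uncorrected scan inflates through structure-driven LD
  des <- make_augmented_design(200, 0, 1, seed = 309)
  ph <- simulate_phenotypes(sim, des, cfg)
  y <- setNames(ph$pheno$tr, ph$pheno$accession)
  expect_gt(abs(cor(y, sim$truth$pools[names(y)])), 0.1)
  lambda_gc <- function(p) {
    chi <- qchisq(p, df = 1, lower.tail = FALSE)
    median(chi, na.rm = TRUE) / qchisq(0.5, 1)
  }
  naive <- gwas_scan(y, sim$genotypes, G = NULL)
  corrected <- gwas_scan(y, sim$genotypes, build_grm(sim$genotypes))
  expect_gt(lambda_gc(naive$p_wald), 1.3)
  l_corr <- lambda_gc(corrected$p_wald)
  expect_gt(l_corr, 0.9); expect_lt(l_corr, 1.1)
})

test_that("permutation thresholds are seeded, bounded and Bonferroni-scaled", {
  expect_equal(per_test_alpha(0.05, 6677), 0.05 / 6677)
  expect_equal(signif(per_test_alpha(0.05, 6677), 3), 7.49e-6)
  expect_equal(signif(per_test_alpha(0.05, 478), 4), 1.046e-4)
  sim <- mapping_sim(n = 100, seed = 311, poly_h2 = 0.4,
                     markers_per_chr = 100, chr_mb = c(10, 10))
  G <- build_grm(sim$gm)
  t1 <- gwas_threshold(sim$y, sim$gm, G, n_perm = 100, seed = 9)
  t2 <- gwas_threshold(sim$y, sim$gm, G, n_perm = 100, seed = 9)
  expect_identical(t1$threshold_neg_log10_p, t2$threshold_neg_log10_p)
  t3 <- gwas_threshold(sim$y, sim$gm, G, n_perm = 100, seed = 10)
  expect_false(identical(t1$threshold_neg_log10_p, t3$threshold_neg_log10_p))
  expect_error(gwas_threshold(sim$y, sim$gm, G, n_perm = 50), "at least 100")
})

test_that("marker heritability follows the 2pq convention and recovers planted shares", {
  expect_equal(marker_h2(0, 0.3, 0.5, 0.5), 0)
  expect_equal(marker_h2(1, 0.5, 0.25, 0.25), 0.5, tolerance = 1e-12)
  # single large-effect causal marker with known variance share; the
  # empirical-variance scaling recovers it, the 2pq convention reports
  # about half of it for fully inbred codes
  h2hat <- vapply(1:10, function(s) {
    sim <- mapping_sim(n = 500, seed = 320 + s, regional_h2 = 0.2, n_causal = 1,
                       poly_h2 = 0.2, markers_per_chr = 150, chr_mb = c(15, 15),
                       window = c(5e6, 5.5e6))
    G <- build_grm(sim$gm)
    scan <- gwas_scan(sim$y, sim$gm, G)
    causal <- names(sim$truth$causal$tr[[1]])
    row <- scan[scan$marker == causal, ]
    x <- sim$gm$values[, causal]
    nf <- attr(scan, "null_fit")
    c(emp = marker_h2(row$effect, (1 + mean(x)) / 2,
                      nf$sigma2[["genomic"]], nf$sigma2[["residual"]],
                      var_marker = var(x)),
      conv = marker_h2(row$effect, (1 + mean(x)) / 2,
                       nf$sigma2[["genomic"]], nf$sigma2[["residual"]]))
  }, numeric(2))
  expect_lt(abs(mean(h2hat["emp", ]) - 0.2), 0.04)
  expect_lt(mean(h2hat["conv", ]), mean(h2hat["emp", ]))
})

test_that("Welch allelic test matches the textbook formula and edge cases", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  res <- welch_allelic_test(c(a, b), rep(c("A", "B"), c(3, 5)))
  se2 <- var(a) / 3 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  # identical groups
  same <- welch_allelic_test(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero-variance group stays finite under Welch
  zv <- welch_allelic_test(c(2, 2, 2, 1, 3, 5), rep(c("A", "B"), each = 3))
  expect_true(is.finite(zv$t))
  expect_error(welch_allelic_test(c(1, 2, 3), c("A", "A", "B")), "at least 2")
})
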
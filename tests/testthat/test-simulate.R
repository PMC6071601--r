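test_that("selfing drives heterozygosity below 1% and toward 0", {
  base <- list(n_accessions = 120, n_genotyped = 120, n_checks = 0, n_blocks = 1,
               chromosome_lengths_bp = c(20e6, 20e6),
               markers_per_chromosome = 250, fraction_dart = 0,
               missing_rate = 0, seed = 31)
  het_at <- function(s) {
    cfg <- do.call(sim_config, c(base, list(selfing_generations = s)))
    simulate_genotypes(cfg)$truth$heterozygosity
  }
  h10 <- het_at(10)
  expect_lt(h10, 0.01)
  h0 <- het_at(0); h3 <- het_at(3); h50 <- het_at(50)
  expect_gt(h0, h3)
  expect_gt(h3, h10)
  expect_lte(h50, h10)
  expect_lt(h50, 1e-4)
})

test_that("default panel matches the emulated study structure", {
  cfg <- sim_config(seed = 4)
  expect_equal(sum(cfg$markers_per_chromosome), 6677)
  expect_equal(length(cfg$chromosome_lengths_bp), 11)
  expect_equal(sum(cfg$chromosome_lengths_bp) / 1e6, 513.54)
  sim <- simulate_genotypes(cfg)
  expect_equal(nrow(sim$genotypes$values), 580)
  expect_length(sim$truth$genotyped_ids, 181)
  expect_equal(sum(sim$genotypes$map$marker_type == "DART"), 3443)
  expect_lt(sim$truth$heterozygosity, 0.01)
})

test_that("pool divergence separates accessions on PC1; no divergence does not", {
  base <- list(n_accessions = 100, n_genotyped = 100, n_checks = 0, n_blocks = 1,
               chromosome_lengths_bp = 20e6, markers_per_chromosome = 400,
               fraction_dart = 0, missing_rate = 0, seed = 32)
  div <- simulate_genotypes(do.call(sim_config, c(base, list(pool_divergence = 0.4,
                                                             pool_props = c(1, 1)))))
  pc <- structure_pcs(div$genotypes, 1)[, 1]
  pools <- div$truth$pools
  side <- pc > 0
  agree <- max(mean(side == (pools == 1)), mean(side == (pools == 2)))
  expect_gt(agree, 0.95)
  flat <- simulate_genotypes(do.call(sim_config, c(base, list(pool_divergence = 0,
                                                              n_gene_pools = 1,
                                                              pool_props = 1))))
  pr <- prcomp(flat$genotypes$values)
  share1 <- pr$sdev[1]^2 / sum(pr$sdev^2)
  expect_lt(share1, 0.12)
})

test_that("simulation is bit-reproducible under the same seed", {
  cfg <- sim_config(n_accessions = 40, n_genotyped = 40, n_checks = 2,
                    n_blocks = 2, chromosome_lengths_bp = 10e6,
                    markers_per_chromosome = 60, seed = 33)
  a <- simulate_genotypes(cfg); b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  des <- make_augmented_design(40, 2, 2, seed = 33)
  des2 <- make_augmented_design(40, 2, 2, seed = 33)
  expect_identical(des, des2)
  pa <- simulate_phenotypes(a, des, cfg); pb <- simulate_phenotypes(b, des2, cfg)
  expect_identical(as.data.frame(pa$pheno), as.data.frame(pb$pheno))
  des3 <- make_augmented_design(40, 2, 2, seed = 34)
  expect_false(identical(des$accession, des3$accession))
})

test_that("augmented design places every accession once and checks per block", {
  des <- make_augmented_design(580, 4, 20, seed = 6)
  expect_equal(nrow(des), 660)
  counts <- table(des$accession[des$is_check])
  expect_true(all(counts == 20))
  expect_true(all(table(des$accession[!des$is_check]) == 1))
  expect_true(all(table(des$block[!des$is_check]) == 29))
  small <- make_augmented_design(5, 0, 1, seed = 6)
  expect_equal(nrow(small), 5)
  expect_error(make_augmented_design(5, 0, 0), "n_blocks")
})

test_that("LD decays with distance in the simulated panel", {
  sim <- mapping_sim(n = 150, seed = 35, markers_per_chr = 400,
                     chr_mb = c(25, 25))
  prs <- pairwise_r2(sim$gm, max_distance_bp = 5e6)
  near <- prs$r2[prs$dist_bp <= 0.5e6]
  far <- prs$r2[prs$dist_bp >= 4e6 & prs$dist_bp <= 5e6]
  expect_gt(mean(near), mean(far))
})

test_that("phenotype variance bookkeeping matches the configured shares", {
  reps <- lapply(1:8, function(s) {
    cfg <- sim_config(n_accessions = 400, n_genotyped = 400, n_checks = 4,
                      n_blocks = 10, n_environments = 2,
                      chromosome_lengths_bp = c(15e6, 15e6),
                      markers_per_chromosome = 150, missing_rate = 0,
                      traits = list(tr = list(h2 = 0.8, c2_int = 0.2,
                                              block_var = 0.05)),
                      seed = 100 + s)
    sim <- simulate_genotypes(cfg)
    des <- make_augmented_design(400, 4, 10, seed = 100 + s)
    ph <- simulate_phenotypes(sim, des, cfg)
    test_rows <- !ph$pheno$is_check
    c(vtot = var(ph$pheno$tr[test_rows]),
      vg = var(ph$truth$g$tr[, 1]))
  })
  m <- colMeans(do.call(rbind, reps))
  # per-environment genetic variance = main (0.6) + interaction (0.2)
  expect_lt(abs(m[["vg"]] - 0.8), 0.05)
  expect_lt(abs(m[["vtot"]] - 1.05), 0.08)
})

test_that("no-interaction limit gives identical per-environment genetic values", {
  cfg <- sim_config(n_accessions = 50, n_genotyped = 50, n_checks = 2,
                    n_blocks = 2, n_environments = 2,
                    chromosome_lengths_bp = 10e6, markers_per_chromosome = 80,
                    traits = list(tr = list(h2 = 0.6, c2_int = 0, block_var = 0.05)),
                    seed = 37)
  sim <- simulate_genotypes(cfg)
  des <- make_augmented_design(50, 2, 2, seed = 37)
  ph <- simulate_phenotypes(sim, des, cfg)
  g <- ph$truth$g$tr
  expect_equal(g[, 1], g[, 2])
  expect_equal(cor(g[, 1], g[, 2]), 1)
})

test_that("QTL windows without markers and bad configs are rejected", {
  expect_error(sim_config(markers_per_chromosome = 1), "markers_per_chromosome")
  expect_error(sim_config(traits = list(t = list(h2 = 0.4, c2_int = 0.5))), "c2_int")
  expect_error(sim_config(traits = list(t = list(
    h2 = 0.5, c2_int = 0,
    qtl = list(list(chromosome = 1, start_bp = 9e9, end_bp = 9.1e9,
                    regional_h2 = 0.1, n_causal = 2))))), "outside chromosome")
  cfg <- sim_config(n_accessions = 30, n_genotyped = 30, n_checks = 0,
                    n_blocks = 1, chromosome_lengths_bp = 10e6,
                    markers_per_chromosome = 10,
                    traits = list(t = list(h2 = 0.5, c2_int = 0, block_var = 0,
                      qtl = list(list(chromosome = 1, start_bp = 0, end_bp = 1,
                                      regional_h2 = 0.1, n_causal = 2)))),
                    seed = 38)
  sim <- simulate_genotypes(cfg)
  des <- make_augmented_design(30, 0, 1, seed = 38)
  expect_error(simulate_phenotypes(sim, des, cfg), "contains no")
})
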
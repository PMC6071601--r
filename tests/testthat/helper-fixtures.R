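# Small in-code fixtures shared across test files.

# tiny deterministic genotype matrix with a mixed SNP/DArT map
tiny_panel <- function(n = 12, m = 20, seed = 101, n_chr = 2) {
  set.seed(seed)
  chrom <- rep(seq_len(n_chr), each = ceiling(m / n_chr))[seq_len(m)]
  map <- data.frame(
    marker_id = sprintf("m%03d", seq_len(m)),
    chromosome = chrom,
    position_bp = unlist(lapply(split(chrom, chrom), function(g)
      sort(sample.int(5e6, length(g))))),
    marker_type = rep(c("SNP", "DART"), length.out = m),
    stringsAsFactors = FALSE)
  vals <- sapply(seq_len(m), function(j) {
    if (map$marker_type[j] == "SNP") sample(c(-1, 0, 1), n, TRUE, prob = c(.45, .1, .45))
    else sample(c(-1, 1), n, TRUE)
  })
  dimnames(vals) <- list(sprintf("ACC%04d", seq_len(n)), map$marker_id)
  genotype_matrix(vals, map)
}

# simulated accession-level mapping panel with an optional planted window
mapping_sim <- function(n = 150, seed = 1, regional_h2 = 0, n_causal = 8,
                        poly_h2 = 0.3, markers_per_chr = 300,
                        chr_mb = c(20, 20), window = c(8e6, 10e6),
                        effects = "normal", recomb = 0.5, founders = 30,
                        hidden_causal = FALSE, breeding = 0.5) {
  qtl <- if (regional_h2 > 0)
    list(list(chromosome = 1, start_bp = window[1], end_bp = window[2],
              regional_h2 = regional_h2, n_causal = n_causal,
              effects = effects))
  else NULL
  cfg <- sim_config(n_accessions = n, n_genotyped = n, n_checks = 0,
                    n_blocks = 1, n_environments = 1,
                    chromosome_lengths_bp = chr_mb * 1e6,
                    markers_per_chromosome = markers_per_chr,
                    missing_rate = 0, recombination_rate_per_mb = recomb,
                    n_founders = founders, breeding_fraction = breeding,
                    traits = list(tr = list(h2 = poly_h2 + regional_h2,
                                            c2_int = 0, block_var = 0,
                                            qtl = qtl)),
                    hidden_causal = hidden_causal,
                    seed = seed)
  sim <- simulate_genotypes(cfg)
  des <- make_augmented_design(n, 0, 1, seed = seed)
  ph <- simulate_phenotypes(sim, des, cfg)
  y <- setNames(ph$pheno$tr, ph$pheno$accession)
  gm_out <- if (is.null(ph$panel)) sim$genotypes else ph$panel
  list(gm = gm_out, y = y[gm_out$accession_ids],
       truth = ph$truth, cfg = cfg)
}

expect_no_na <- function(x) expect_false(anyNA(x))
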
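# Seeded generator of two-gene-pool inbred panels and augmented-block trials.
#
# The defaults emulate the common-bean diversity-panel setting: 580
# phenotyped accessions of which 181 are genotyped, 6677 markers (3234 SNP +
# 3443 dominant DArT) on 11 chromosomes totalling 513.54 Mb, two divergent
# gene pools, heterozygosity under 1% after repeated selfing, two field
# environments laid out as 20 augmented blocks of 29 accessions plus 4
# replicated checks, and three traits with joint heritabilities 0.81 / 0.79
# / 0.43 and G x E coefficients 0.17 / 0.21 / 0.41.

# chromosome lengths (Mb) and per-chromosome marker counts of the emulated
# 11-chromosome panel
BEAN_CHROM_MB <- c(52.02, 49.01, 52.18, 45.80, 40.57, 31.95,
                   51.71, 59.63, 37.42, 43.25, 50.00)
BEAN_MARKERS_PER_CHROM <- c(606, 867, 722, 439, 533, 537, 606, 709, 610, 458, 590)

#' Simulation configuration
#'
#' Collects every knob of the synthetic panel and trial generator. Defaults
#' reproduce the emulated study conditions; tests use smaller values.
#'
#' @param n_accessions number of phenotyped accessions (default 580).
#' @param n_genotyped number of accessions with genotypes, sampled from the
#'   phenotyped set (default 181).
#' @param n_checks number of replicated check cultivars (default 4).
#' @param n_blocks number of augmented blocks per environment (default 20).
#' @param n_environments number of field environments (default 2).
#' @param chromosome_lengths_bp chromosome lengths in bp.
#' @param markers_per_chromosome integer vector (recycled) of marker counts.
#' @param fraction_dart fraction of markers emitted as dominant
#'   presence/absence DArT columns (default 3443/6677).
#' @param n_gene_pools number of divergent gene pools (default 2).
#' @param pool_props relative pool sizes (default 69:112, the two-pool split
#'   of the emulated panel).
#' @param pool_divergence Balding-Nichols drift parameter F controlling
#'   allele-frequency divergence between pools (default 0.4, a strongly
#'   structured pair of gene pools).
#' @param n_founders founder haplotypes per pool from which accession
#'   gametes are recombined (default 30).
#' @param breeding_fraction fraction of accessions that are breeding
#'   lines: recombinant inbreds of crosses among a small pool of elite
#'   ancestor genomes, so they share half- and full-sib relatedness; the
#'   rest are independent founder mosaics (landrace-like). Default 0.5,
#'   the split of the emulated collection. Pervasive relatedness is what
#'   gives a panel of a few hundred accessions usable information about
#'   its genomic variance component.
#' @param n_elite_lineages elite ancestor genomes per pool from which
#'   breeding lines are crossed (default 8).
#' @param recombination_rate_per_mb expected founder-switch points per Mb
#'   along a gamete (default 0.5, giving LD decay on the Mb scale).
#' @param selfing_generations generations of self-fertilization applied to
#'   each accession (default 5; expected heterozygosity halves each
#'   generation, landing below 1%).
#' @param missing_rate per-entry probability of a missing genotype call
#'   (default 0.02).
#' @param traits named list of per-trait settings, each a list with
#'   `h2` (joint heritability, genetic + interaction share of the plot
#'   variance), `c2_int` (interaction share), `block_var` (block share) and
#'   optionally `qtl`, a list of regional QTL each given as
#'   `list(chromosome, start_bp, end_bp, regional_h2, n_causal)` with an
#'   optional `effects` field: `"normal"` (default, independent normal
#'   draws) or `"equal"` (equal-magnitude random-sign effects, the
#'   dispersed many-small-effects regime).
#' @param hidden_causal if TRUE, causal markers are dropped from the emitted
#'   marker panel so that mapping relies on imperfect LD.
#' @param seed master seed; all stages derive their own seeds from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 580,
                       n_genotyped = 181,
                       n_checks = 4,
                       n_blocks = 20,
                       n_environments = 2,
                       chromosome_lengths_bp = BEAN_CHROM_MB * 1e6,
                       markers_per_chromosome = BEAN_MARKERS_PER_CHROM,
                       fraction_dart = 3443 / 6677,
                       n_gene_pools = 2,
                       pool_props = c(69, 112),
                       pool_divergence = 0.4,
                       n_founders = 30,
                       breeding_fraction = 0.5,
                       n_elite_lineages = 8,
                       recombination_rate_per_mb = 0.5,
                       selfing_generations = 5,
                       missing_rate = 0.02,
                       traits = list(
                         architecture = list(h2 = 0.81, c2_int = 0.17, block_var = 0.05),
                         lodging      = list(h2 = 0.79, c2_int = 0.21, block_var = 0.05),
                         productivity = list(h2 = 0.43, c2_int = 0.41, block_var = 0.05)),
                       hidden_causal = FALSE,
                       seed = 1L) {
  cfg <- list(n_accessions = n_accessions, n_genotyped = min(n_genotyped, n_accessions),
              n_checks = n_checks, n_blocks = n_blocks,
              n_environments = n_environments,
              chromosome_lengths_bp = as.numeric(chromosome_lengths_bp),
              markers_per_chromosome =
                rep_len(as.integer(markers_per_chromosome),
                        length(chromosome_lengths_bp)),
              fraction_dart = fraction_dart, n_gene_pools = n_gene_pools,
              pool_props = rep_len(as.numeric(pool_props), n_gene_pools),
              pool_divergence = pool_divergence, n_founders = n_founders,
              breeding_fraction = breeding_fraction,
              n_elite_lineages = as.integer(max(n_elite_lineages, 2)),
              recombination_rate_per_mb = recombination_rate_per_mb,
              selfing_generations = as.integer(selfing_generations),
              missing_rate = missing_rate, traits = traits,
              hidden_causal = isTRUE(hidden_causal), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$markers_per_chromosome < 2))
    stop_format("markers_per_chromosome must be >= 2 on every chromosome")
  if (cfg$fraction_dart < 0 || cfg$fraction_dart > 1)
    stop_format("fraction_dart must lie in [0, 1]")
  if (cfg$pool_divergence < 0 || cfg$pool_divergence >= 1)
    stop_format("pool_divergence must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_format("missing_rate must lie in [0, 1)")
  if (cfg$breeding_fraction < 0 || cfg$breeding_fraction > 1)
    stop_format("breeding_fraction must lie in [0, 1]")
  for (nm in names(cfg$traits)) {
    tr <- cfg$traits[[nm]]
    h2 <- tr$h2 %||% stop_format("trait '%s': h2 missing", nm)
    c2 <- tr$c2_int %||% 0
    bv <- tr$block_var %||% 0
    if (h2 < 0 || c2 < 0 || bv < 0) stop_format("trait '%s': negative variance share", nm)
    if (c2 > h2) stop_format("trait '%s': c2_int (%g) exceeds h2 (%g)", nm, c2, h2)
    if (h2 + bv > 1) stop_format("trait '%s': h2 + block_var exceeds 1", nm)
    reg <- sum(vapply(tr$qtl %||% list(), function(q) q$regional_h2, 0))
    if (reg > h2 - c2)
      stop_format("trait '%s': regional heritability (%g) exceeds the main genetic share (%g)",
                  nm, reg, h2 - c2)
    for (q in tr$qtl %||% list()) {
      L <- cfg$chromosome_lengths_bp[q$chromosome]
      if (q$start_bp < 0 || q$end_bp > L || q$start_bp >= q$end_bp)
        stop_format("trait '%s': QTL window [%g, %g) outside chromosome %d",
                    nm, q$start_bp, q$end_bp, q$chromosome)
    }
  }
  invisible(cfg)
}

#' Simulate genotypes for a structured panel of inbred lines
#'
#' Two-pool population model: per-marker ancestral frequencies are drawn
#' uniformly, pool frequencies follow a Balding-Nichols distribution with
#' drift `pool_divergence`, founder haplotypes per pool carry the pool
#' frequencies, and each accession's two gametes are founder mosaics with
#' Poisson-distributed switch points (rate `recombination_rate_per_mb`),
#' which creates distance-dependent LD. `selfing_generations` rounds of
#' self-fertilization then erode heterozygosity by half per round. DArT
#' columns are scored dominantly: presence (+1) unless homozygous absent.
#'
#' @param config a [sim_config()].
#' @return a list with `genotypes` (a [genotype_matrix()] over all
#'   `n_accessions`) and `truth` (pool assignment, per-pool allele
#'   frequencies, realized heterozygosity, genotyped accession ids).
#' @export
simulate_genotypes <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_accessions
  n_chr <- length(cfg$chromosome_lengths_bp)
  pools <- sample(rep(seq_len(cfg$n_gene_pools),
                      times = round(cfg$pool_props / sum(cfg$pool_props) * n))[seq_len(n)])
  pools[is.na(pools)] <- 1L
  acc_ids <- sprintf("ACC%04d", seq_len(n))

  # breeding-line assignment (constant across chromosomes): a breeding
  # accession is a recombinant inbred of a cross between two elite
  # lineage genomes of its pool, so lines sharing an ancestor are genome-
  # wide half/full sibs; the remainder are independent founder mosaics
  is_breeding <- rep(FALSE, n)
  par1 <- par2 <- rep(0L, n)
  nl <- cfg$n_elite_lineages
  for (k in seq_len(cfg$n_gene_pools)) {
    members <- which(pools == k)
    bl <- members[seq_len(round(cfg$breeding_fraction * length(members)))]
    is_breeding[bl] <- TRUE
    for (i in bl) {
      pr <- sample.int(nl, 2L)
      par1[i] <- pr[1L]; par2[i] <- pr[2L]
    }
  }

  maps <- vector("list", n_chr)
  doses <- vector("list", n_chr)
  pool_freq <- vector("list", n_chr)
  FST <- cfg$pool_divergence
  for (chr in seq_len(n_chr)) {
    m <- cfg$markers_per_chromosome[chr]
    L <- cfg$chromosome_lengths_bp[chr]
    pos <- sort(sample.int(L, m))
    p_anc <- runif(m, 0.1, 0.9)
    pf <- if (FST > 0) {
      vapply(seq_len(cfg$n_gene_pools), function(k)
        rbeta(m, p_anc * (1 - FST) / FST, (1 - p_anc) * (1 - FST) / FST),
        numeric(m))
    } else matrix(p_anc, m, cfg$n_gene_pools)
    pf <- matrix(pmin(pmax(pf, 1e-4), 1 - 1e-4), m, cfg$n_gene_pools)
    # founder haplotypes per pool: m x n_founders 0/1
    founders <- lapply(seq_len(cfg$n_gene_pools), function(k)
      matrix(rbinom(m * cfg$n_founders, 1, pf[, k]), m, cfg$n_founders))
    # gametes as founder mosaics
    rate <- cfg$recombination_rate_per_mb * L / 1e6
    gam <- function(pool) {
      fo <- founders[[pool]]
      nseg <- 1L + rpois(1L, rate)
      if (nseg == 1L) return(fo[, sample.int(cfg$n_founders, 1L)])
      brk <- sort(runif(nseg - 1L, 0, L))
      seg <- findInterval(pos, brk) + 1L
      pick <- sample.int(cfg$n_founders, nseg, replace = TRUE)
      fo[cbind(seq_len(m), pick[seg])]
    }
    # one meiosis between two haplotypes: Poisson switch points at `rate`
    cross <- function(h1, h2) {
      nsw <- rpois(1L, rate)
      if (nsw == 0L) return(if (runif(1) < 0.5) h1 else h2)
      brk <- sort(runif(nsw, 0, L))
      seg <- findInterval(pos, brk) + 1L
      use1 <- sample(c(TRUE, FALSE), nsw + 1L, replace = TRUE)[seg]
      ifelse(use1, h1, h2)
    }
    # elite lineage genomes for this chromosome (inbred: one haplotype)
    lin_hap <- lapply(seq_len(cfg$n_gene_pools), function(k)
      vapply(seq_len(cfg$n_elite_lineages), function(j) gam(k), numeric(m)))
    # each accession: two gametes (fresh founder mosaics for landrace-like
    # accessions, meioses of its two elite ancestors for breeding lines),
    # then selfing by single-seed descent -- the inbred line fixes whole
    # segments of one or the other gamete (switch rate ~2x one meiosis,
    # the usual map expansion of repeated selfing), with residual
    # heterozygosity 2^-s at scattered loci; segment-wise fixation
    # preserves haplotype LD, unlike independent per-locus resolution
    s <- cfg$selfing_generations
    dose <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      if (is_breeding[i]) {
        lh <- lin_hap[[pools[i]]]
        g1 <- cross(lh[, par1[i]], lh[, par2[i]])
        g2 <- cross(lh[, par1[i]], lh[, par2[i]])
      } else {
        g1 <- gam(pools[i]); g2 <- gam(pools[i])
      }
      if (s > 0L) {
        nsw <- rpois(1L, 2 * rate)
        pickg <- if (nsw == 0L) {
          rep(sample.int(2L, 1L), m)
        } else {
          brk <- sort(runif(nsw, 0, L))
          seg <- findInterval(pos, brk) + 1L
          sample.int(2L, nsw + 1L, replace = TRUE)[seg]
        }
        d <- ifelse(pickg == 1L, 2L * g1, 2L * g2)
        het <- which(g1 != g2 & runif(m) < 2^(-s))
        if (length(het)) d[het] <- 1L
        dose[i, ] <- d
      } else {
        dose[i, ] <- g1 + g2
      }
    }
    doses[[chr]] <- dose
    pool_freq[[chr]] <- pf
    maps[[chr]] <- data.frame(marker_id = sprintf("M%02d_%05d", chr, seq_len(m)),
                              chromosome = chr, position_bp = pos - 1,
                              marker_type = "SNP", stringsAsFactors = FALSE)
  }
  dose <- do.call(cbind, doses)
  map <- do.call(rbind, maps)
  M <- nrow(map)
  het_realized <- mean(dose == 1L)

  # marker-type assignment and coding
  is_dart <- rep(FALSE, M)
  n_dart <- round(cfg$fraction_dart * M)
  if (n_dart > 0) is_dart[sample.int(M, n_dart)] <- TRUE
  map$marker_type[is_dart] <- "DART"
  codes <- dose - 1                       # SNP coding {-1, 0, 1}
  if (any(is_dart))                       # dominant: present unless homozygous absent
    codes[, is_dart] <- ifelse(dose[, is_dart] >= 1L, 1, -1)
  if (cfg$missing_rate > 0)
    codes[runif(length(codes)) < cfg$missing_rate] <- NA_real_
  dimnames(codes) <- list(acc_ids, map$marker_id)

  genotyped_ids <- sort(sample(acc_ids, cfg$n_genotyped))
  truth <- list(pools = setNames(pools, acc_ids),
                is_breeding = setNames(is_breeding, acc_ids),
                parents = cbind(par1, par2),
                pool_freq = pool_freq,
                heterozygosity = het_realized,
                genotyped_ids = genotyped_ids,
                dose = dose)
  list(genotypes = genotype_matrix(codes, map), truth = truth)
}

#' Lay out an augmented block design
#'
#' Each non-check accession appears exactly once, in one block; each check
#' appears once in every block. Plot order within block is randomized.
#'
#' @param n_accessions number of unreplicated test accessions.
#' @param n_checks number of replicated checks.
#' @param n_blocks number of blocks (the last block may be smaller).
#' @param seed seed for the randomization.
#' @return data.frame with columns `plot`, `block`, `accession`, `is_check`.
#' @export
make_augmented_design <- function(n_accessions, n_checks, n_blocks, seed = 1L) {
  if (n_blocks < 1L) stop_format("n_blocks must be >= 1")
  set.seed(derive_seed(seed, 2L))
  acc <- sprintf("ACC%04d", seq_len(n_accessions))
  checks <- if (n_checks > 0L) sprintf("CHK%02d", seq_len(n_checks)) else character(0)
  assignment <- split(sample(acc), rep(seq_len(n_blocks),
                                       length.out = n_accessions))
  rows <- lapply(seq_len(n_blocks), function(b) {
    ids <- c(assignment[[as.character(b)]] %||% character(0), checks)
    ids <- sample(ids)
    data.frame(block = sprintf("B%02d", b), accession = ids,
               is_check = ids %in% checks, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(plot = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate augmented-block phenotypes with known variance structure
#'
#' Builds each trait as: environment mean + check mean (check plots) or
#' genetic value (test plots) + block effect + genotype-by-environment
#' deviation + plot residual. The genetic value is a polygenic sum of many
#' small marker effects plus optional regional QTL effects restricted to
#' configured windows. Every component is rescaled so its realized sample
#' variance hits the configured share exactly (total plot variance 1), which
#' removes one layer of Monte-Carlo noise from recovery tests.
#'
#' @param sim result of [simulate_genotypes()] (or a `genotype_matrix`;
#'   then causal effects use mean-imputed codes).
#' @param design data.frame from [make_augmented_design()]; it is laid out
#'   once per environment.
#' @param config the [sim_config()] used for the genotypes.
#' @return list with `pheno` (a [pheno_table()]), and `truth`: per-accession
#'   true genetic values per environment, causal markers and effects, and
#'   realized regional variances. With `hidden_causal = TRUE` the list also
#'   carries `panel`, the genotype matrix with every causal marker removed,
#'   so mapping must rely on imperfect LD with the remaining markers (the
#'   missing-heritability regime).
#' @export
simulate_phenotypes <- function(sim, design, config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  gm <- if (inherits(sim, "genotype_matrix")) sim else sim$genotypes
  set.seed(derive_seed(cfg$seed, 3L))
  acc <- unique(design$accession[!design$is_check])
  if (!all(acc %in% gm$accession_ids))
    stop_format("design contains accessions without simulated genotypes")
  W <- mean_impute(gm$values[acc, , drop = FALSE])
  Wc <- sweep(W, 2L, colMeans(W))
  map <- gm$map
  envs <- sprintf("E%d", seq_len(cfg$n_environments))
  checks <- unique(design$accession[design$is_check])

  plots <- do.call(rbind, lapply(envs, function(e)
    data.frame(design, environment = e, stringsAsFactors = FALSE)))
  n_plot <- nrow(plots)
  truth <- list(g = list(), causal = list(), regional_var = list())
  pheno_cols <- list()

  for (tr_name in names(cfg$traits)) {
    tr <- cfg$traits[[tr_name]]
    c2 <- tr$c2_int %||% 0
    bv <- tr$block_var %||% 0
    sg2 <- tr$h2 - c2            # main genetic share
    se2 <- 1 - tr$h2 - bv
    qtl <- tr$qtl %||% list()

    causal_idx <- integer(0)
    u_reg <- rep(0, length(acc))
    reg_var <- numeric(0)
    causal_eff <- list()
    for (qi in seq_along(qtl)) {
      q <- qtl[[qi]]
      inside <- which(map$chromosome == q$chromosome &
                        map$position_bp >= q$start_bp &
                        map$position_bp < q$end_bp)
      inside <- inside[apply(Wc[, inside, drop = FALSE], 2L, function(x) any(x != 0))]
      if (length(inside) == 0L)
        stop_format("trait '%s': QTL window on chromosome %d contains no polymorphic markers",
                    tr_name, q$chromosome)
      pick <- sample(inside, min(q$n_causal %||% length(inside), length(inside)))
      # "normal" draws let one locus dominate by chance; "equal" gives every
      # causal marker the same variance contribution with random signs;
      # "repulsion" additionally picks each sign opposing the accumulated
      # local effect (repulsion-phase linkage), so marginal single-marker
      # associations stay small while the window carries the full variance
      kind <- q$effects %||% "normal"
      beta <- if (kind == "normal") {
        rnorm(length(pick))
      } else {
        ord <- order(map$position_bp[pick])
        pick <- pick[ord]
        Xq <- Wc[, pick, drop = FALSE]
        sds <- pmax(apply(Xq, 2L, stats::sd), 1e-8)
        if (kind == "equal") {
          sample(c(-1, 1), length(pick), replace = TRUE) / sds
        } else if (kind == "repulsion") {
          b <- numeric(length(pick))
          b[1L] <- 1 / sds[1L]
          cum_eff <- Xq[, 1L] * b[1L]
          for (jj in seq_along(pick)[-1L]) {
            sgn <- -sign(sum(Xq[, jj] * cum_eff))
            if (sgn == 0) sgn <- 1
            b[jj] <- sgn / sds[jj]
            cum_eff <- cum_eff + Xq[, jj] * b[jj]
          }
          b
        } else stop_format("unknown QTL effects kind '%s'", kind)
      }
      contrib <- drop(Wc[, pick, drop = FALSE] %*% beta)
      contrib <- scale_to_var(contrib, q$regional_h2)
      u_reg <- u_reg + contrib
      causal_idx <- c(causal_idx, pick)
      reg_var <- c(reg_var, q$regional_h2)
      causal_eff[[qi]] <- setNames(beta, map$marker_id[pick])
    }
    poly_idx <- setdiff(seq_len(ncol(Wc)), causal_idx)
    u_poly <- drop(Wc[, poly_idx, drop = FALSE] %*% rnorm(length(poly_idx)))
    sg2_poly <- max(sg2 - sum(reg_var), 0)
    g <- scale_to_var(u_poly, sg2_poly) + u_reg
    names(g) <- acc

    # compound-symmetric G x E deviations, exact variance per environment
    k <- matrix(0, length(acc), length(envs), dimnames = list(acc, envs))
    if (c2 > 0 && length(envs) > 1L)
      for (e in seq_along(envs)) k[, e] <- scale_to_var(rnorm(length(acc)), c2)
    g_env <- g + k

    blocks <- sort(unique(paste(plots$environment, plots$block)))
    b_eff <- if (bv > 0) setNames(scale_to_var(rnorm(length(blocks)), bv), blocks)
             else setNames(rep(0, length(blocks)), blocks)
    chk_eff <- setNames(rnorm(length(checks), sd = sqrt(max(tr$h2, 1e-8))), checks)

    e_plot <- scale_to_var(rnorm(n_plot), se2)
    y <- numeric(n_plot)
    is_chk <- plots$is_check
    bkey <- paste(plots$environment, plots$block)
    y[!is_chk] <- g_env[cbind(match(plots$accession[!is_chk], acc),
                              match(plots$environment[!is_chk], envs))]
    y[is_chk] <- chk_eff[plots$accession[is_chk]]
    y <- y + b_eff[bkey] + e_plot

    pheno_cols[[tr_name]] <- y
    truth$g[[tr_name]] <- g_env
    truth$causal[[tr_name]] <- causal_eff
    truth$regional_var[[tr_name]] <- reg_var
  }

  tab <- data.frame(accession = plots$accession, environment = plots$environment,
                    block = plots$block, is_check = plots$is_check,
                    stringsAsFactors = FALSE)
  for (nm in names(pheno_cols)) tab[[nm]] <- pheno_cols[[nm]]
  out <- list(pheno = pheno_table(tab), truth = truth)
  if (isTRUE(cfg$hidden_causal)) {
    dropped <- unique(unlist(lapply(truth$causal, function(tr)
      unlist(lapply(tr, names)))))
    keep <- setdiff(map$marker_id, dropped)
    out$panel <- genotype_matrix(gm$values[, keep, drop = FALSE],
                                 map[map$marker_id %in% keep, , drop = FALSE])
    out$truth$dropped_markers <- dropped
  }
  out
}
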
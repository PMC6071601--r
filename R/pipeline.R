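# Orchestration: one config drives simulate/read -> adjust -> grm/ld ->
# gwas -> rhm -> comparison, with deterministic outputs and a MANIFEST.

#' Default pipeline configuration
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `simulate` (a [sim_config()] or argument list; used when
#'   no input paths are given), `genotypes`/`map`/`phenotypes` (input paths),
#'   `out_dir`, `traits` (default: all trait columns), `scopes` (default:
#'   joint plus each environment), `window` (list: `length_bp`, `step_bp`,
#'   `min_markers`), `n_perm`, `global_alpha`, `seed`, and flags
#'   `grm_scale`, `rgl_formula`, `exact_per_marker`,
#'   `exclude_region_from_G`, `run_ld`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    simulate = NULL, genotypes = NULL, map = NULL, phenotypes = NULL,
    out_dir = "beanrhm_results", traits = NULL, scopes = NULL,
    window = list(length_bp = 2e6, step_bp = 1e6, min_markers = 2L),
    n_perm = 200L, global_alpha = 0.05, seed = 1L,
    grm_scale = "2pq", rgl_formula = "correlation",
    exact_per_marker = FALSE, exclude_region_from_G = FALSE,
    run_ld = TRUE), list(...))
  stopifnot(cfg$global_alpha > 0, cfg$global_alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full two-stage mapping pipeline
#'
#' Sequences phenotype adjustment, relationship/LD construction, the
#' association scan and the regional scan, and writes one tab-separated
#' table per product plus a MANIFEST. Re-running with the same config and
#' seed reproduces the tables byte for byte.
#'
#' @param config a [pipeline_config()], a YAML path, or a plain list.
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, package_version =
                     as.character(utils::packageVersion("beanrhm")),
                   complete = FALSE, stages = character(0), files = character(0))
  write_manifest <- function() {
    con <- file(file.path(out_dir, "MANIFEST"), "w")
    on.exit(close(con))
    writeLines(c(sprintf("seed: %s", manifest$seed),
                 sprintf("package_version: %s", manifest$package_version),
                 sprintf("complete: %s", tolower(manifest$complete)),
                 sprintf("stages: %s", paste(manifest$stages, collapse = " ")),
                 "files:", paste0("  - ", sort(manifest$files))), con)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest()
      stop_format("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  # --- data ----------------------------------------------------------------
  truth <- NULL
  dat <- stage("data", {
    if (!is.null(config$genotypes)) {
      gm <- read_genotypes(config$genotypes, config$map)
      ph <- read_phenotypes(config$phenotypes)
      list(gm = gm, pheno = ph, genotyped_ids = gm$accession_ids)
    } else {
      sc <- config$simulate %||% list()
      if (!inherits(sc, "sim_config")) {
        sc$seed <- sc$seed %||% config$seed
        sc <- do.call(sim_config, sc)
      }
      sim <- simulate_genotypes(sc)
      des <- make_augmented_design(sc$n_accessions, sc$n_checks, sc$n_blocks,
                                   seed = sc$seed)
      phe <- simulate_phenotypes(sim, des, sc)
      truth <<- phe$truth
      gm_sub <- sim$genotypes
      keep <- sim$truth$genotyped_ids
      gm_sub <- genotype_matrix(gm_sub$values[keep, , drop = FALSE], gm_sub$map)
      paths <- c(write_genotypes(gm_sub, file.path(out_dir, "genotypes.tsv"),
                                 file.path(out_dir, "map.tsv")),
                 write_phenotypes(phe$pheno, file.path(out_dir, "phenotypes.tsv")))
      manifest$files <- c(manifest$files, basename(paths))
      list(gm = gm_sub, pheno = phe$pheno, genotyped_ids = keep)
    }
  })
  gm <- dat$gm
  pheno <- dat$pheno
  traits <- config$traits %||% attr(pheno, "traits")
  envs <- sort(unique(pheno$environment))
  scopes <- config$scopes %||% c(if (length(envs) > 1L) "joint", envs)

  # --- stage 1: adjustment and genetic parameters --------------------------
  adj <- stage("adjust", {
    fits <- list()
    params_rows <- list()
    adj_rows <- list()
    for (tr in traits) {
      env_fits <- lapply(envs, function(e) fit_augmented_model(pheno, tr, e))
      names(env_fits) <- envs
      joint_fit <- if (length(envs) > 1L) fit_augmented_model(pheno, tr, "joint")
                   else env_fits[[1L]]
      gp <- if (length(envs) > 1L)
        genetic_params(env_fits, joint_fit, rgl_formula = config$rgl_formula)
      else NULL
      fits[[tr]] <- list(env = env_fits, joint = joint_fit, params = gp)
      for (sc in scopes) {
        f <- if (identical(sc, "joint")) joint_fit else env_fits[[sc]]
        adj_rows[[paste(tr, sc)]] <- cbind(trait = tr, f$adjusted)
        pr <- f$params
        params_rows[[paste(tr, sc)]] <- data.frame(
          trait = tr, scope = sc, n_lines = pr$n_lines,
          phenotypic_mean = pr$phenotypic_mean,
          h2_plot = pr$h2_plot, h2_total = pr$h2_total,
          c2_int = pr$c2_int,
          c2_pct_of_h2 = if (is.na(pr$c2_int)) NA_real_
                         else interaction_pct(pr$c2_int, pr$h2_total),
          r_gl = if (!is.null(gp) && identical(sc, "joint")) gp$r_gl else NA_real_,
          accuracy = pr$accuracy, stringsAsFactors = FALSE)
      }
    }
    list(fits = fits, params = do.call(rbind, params_rows),
         adjusted = do.call(rbind, adj_rows))
  })
  manifest$files <- c(manifest$files, basename(write_results(
    list(params = adj$params, adjusted = adj$adjusted), out_dir)))

  # --- stage 2 prep: relationship matrices, windows, LD --------------------
  grm_all <- stage("grm", build_grm(gm, scale = config$grm_scale))
  windows <- stage("windows", window_grid(
    gm$map, length_bp = config$window$length_bp,
    step_bp = config$window$step_bp, min_markers = config$window$min_markers))
  wtab <- windows[, c("window_id", "chromosome", "start_bp", "end_bp", "n_markers")]
  manifest$files <- c(manifest$files, basename(write_results(
    list(windows = wtab), out_dir)))
  if (isTRUE(config$run_ld)) {
    ld <- stage("ld", {
      prs <- marker_pairs(gm$map, max_distance_bp = 10e6,
                          n_max = 50000L, seed = config$seed)
      prs <- pairwise_r2(gm, pairs = prs)
      dec <- tryCatch(fit_ld_decay(prs), error = function(e) NULL)
      list(pairs = prs, decay = dec)
    })
    ld_tab <- data.frame(
      parameter = c("r0", "lambda_per_mb", "c", "half_decay_r2", "half_decay_mb"),
      value = if (is.null(ld$decay)) rep(NA_real_, 5) else
        c(ld$decay$r0, ld$decay$lambda, ld$decay$c,
          ld$decay$half_decay_r2, ld$decay$half_decay_mb))
    manifest$files <- c(manifest$files, basename(write_results(
      list(ld_decay = ld_tab), out_dir)))
  }

  # --- stage 2: scans per trait and scope ----------------------------------
  gwas_rows <- list(); rhm_rows <- list(); comp_rows <- list()
  has_dart <- any(gm$map$marker_type == "DART")
  h2g_rows <- list()
  for (tr in traits) {
    for (sc in scopes) {
      f <- if (identical(sc, "joint")) adj$fits[[tr]]$joint else adj$fits[[tr]]$env[[sc]]
      ystar <- setNames(f$adjusted$y_star, f$adjusted$accession)
      ystar <- ystar[is.finite(ystar)]
      h2_ref <- if (identical(sc, "joint")) f$params$h2_total else f$params$h2_plot
      hg <- stage(paste0("genome_h2:", tr, ":", sc),
                  genome_h2(ystar, gm, h2_trait = h2_ref, scale = config$grm_scale))
      h2g_rows[[paste(tr, sc)]] <- cbind(trait = tr, scope = sc, hg)
      gsc <- stage(paste0("gwas:", tr, ":", sc), {
        sc_res <- gwas_scan(ystar, gm, grm_all, h2_ref = h2_ref,
                            exact_per_marker = config$exact_per_marker)
        thr <- gwas_threshold(ystar, gm, grm_all, n_perm = config$n_perm,
                              global_alpha = config$global_alpha,
                              seed = derive_seed(config$seed, 7L))
        sc_res$significant <- !is.na(sc_res$neg_log10_p) &
          sc_res$neg_log10_p >= thr$threshold_neg_log10_p
        attr(sc_res, "threshold") <- thr
        sc_res
      })
      gwas_rows[[paste(tr, sc)]] <- cbind(trait = tr, scope = sc,
                                          as.data.frame(gsc))
      rsc <- stage(paste0("rhm:", tr, ":", sc), {
        scan <- rhm_scan(ystar, gm, windows, grm_all, h2_ref = h2_ref,
                         exclude_region_from_G = config$exclude_region_from_G,
                         scale = config$grm_scale)
        thr <- rhm_threshold(ystar, gm, windows, grm_all,
                             n_perm = config$n_perm,
                             global_alpha = config$global_alpha,
                             seed = derive_seed(config$seed, 8L))
        rhm_significance(scan, thr)
      })
      rhm_rows[[paste(tr, sc)]] <- cbind(trait = tr, scope = sc,
                                         as.data.frame(rsc))
      cmp <- compare_gwas_rhm(gsc, rsc)
      comp_rows[[paste(tr, sc)]] <- data.frame(
        trait = tr, scope = sc,
        n_sig_gwas_markers = cmp$n_sig_gwas_markers,
        n_sig_windows = cmp$n_sig_windows,
        n_unique_regions = cmp$n_unique_regions,
        gwas_hits_inside_rhm = sum(cmp$gwas_hits_inside_rhm),
        explained_sum_gwas = cmp$explained_sum_gwas,
        explained_max_rhm = cmp$explained_max_rhm,
        stringsAsFactors = FALSE)
    }
  }
  gwas_tab <- do.call(rbind, gwas_rows)
  rhm_tab <- do.call(rbind, rhm_rows)
  rhm_tab$explained_pct <- round(rhm_tab$explained_pct, 1)
  comp_tab <- do.call(rbind, comp_rows)
  h2g_tab <- do.call(rbind, h2g_rows)
  manifest$files <- c(manifest$files, basename(write_results(
    list(gwas = gwas_tab, rhm = rhm_tab, comparison = comp_tab,
         genome_h2 = h2g_tab), out_dir)))

  manifest$complete <- TRUE
  write_manifest()
  manifest$files <- c(manifest$files, "MANIFEST")
  invisible(list(config = config, out_dir = out_dir, genotypes = gm,
                 pheno = pheno, truth = truth, params = adj$params,
                 gwas = gwas_tab, rhm = rhm_tab, comparison = comp_tab,
                 genome_h2 = h2g_tab, manifest = manifest))
}

#' Summarize a finished pipeline run as a text report
#'
#' Reads only the written result tables (every reported number traces to a
#' table cell; nothing is recomputed).
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
summarize_results <- function(out_dir) {
  man_path <- file.path(out_dir, "MANIFEST")
  if (!file.exists(man_path)) stop_format("no MANIFEST in '%s'", out_dir)
  man <- readLines(man_path)
  if (!any(grepl("^complete: true$", man)))
    stop_format("MANIFEST marks the run as incomplete")
  params <- read.delim(file.path(out_dir, "params.tsv"))
  gwas <- read.delim(file.path(out_dir, "gwas.tsv"))
  rhm <- read.delim(file.path(out_dir, "rhm.tsv"))
  lines <- c("beanrhm pipeline summary", "========================")
  for (tr in unique(params$trait)) {
    pj <- params[params$trait == tr & params$scope == "joint", , drop = FALSE]
    if (nrow(pj)) {
      lines <- c(lines, sprintf(
        "%s: h2_total = %.2f, c2_int = %.2f (%d%% of h2_total), r_gl = %.2f",
        tr, pj$h2_total, pj$c2_int, pj$c2_pct_of_h2, pj$r_gl))
    } else {
      pe <- params[params$trait == tr, , drop = FALSE][1L, ]
      lines <- c(lines, sprintf("%s: h2_plot = %.2f", tr, pe$h2_plot))
    }
    gs <- gwas[gwas$trait == tr & gwas$significant %in% TRUE, , drop = FALSE]
    rs <- rhm[rhm$trait == tr & rhm$significant %in% TRUE, , drop = FALSE]
    if (nrow(gs) == 0L && nrow(rs) == 0L) {
      lines <- c(lines, "  no significant associations")
    } else {
      if (nrow(gs)) lines <- c(lines, sprintf(
        "  GWAS: %d significant marker(s), max explained %.1f%%",
        nrow(gs), suppressWarnings(max(gs$explained_pct, na.rm = TRUE))))
      if (nrow(rs)) lines <- c(lines, sprintf(
        "  RHM: %d significant window(s), max explained %.1f%%",
        nrow(rs), suppressWarnings(max(rs$explained_pct, na.rm = TRUE))))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Marker panel density in kb per marker
#'
#' @param total_length_mb summed chromosome lengths in Mb.
#' @param n_markers number of markers.
#' @return kb of genome per marker, rounded to 1 decimal.
#' @export
marker_density_kb <- function(total_length_mb, n_markers) {
  round(total_length_mb * 1000 / n_markers, 1)
}

#' Fraction of markers retained after linkage-equilibrium filtering
#'
#' @param n_retained markers kept.
#' @param n_total markers evaluated.
#' @return percentage rounded to 1 decimal.
#' @export
le_fraction_pct <- function(n_retained, n_total) {
  round(100 * n_retained / n_total, 1)
}
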
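# Stage 1: augmented-block mixed model per environment and jointly,
# deregressed genotypic values, and the genetic-parameter report.
#
# Model: y = Xf + Zg + Sb + Tk + e with f the fixed check means and
# per-environment population means, g the random genotypic effects of the
# test accessions (covariance A = identity: the panel has no pedigree and
# genomic kinship is reserved for stage 2), b the random block effects,
# k the random accession-by-environment interaction (joint scope only).

incidence_partial <- function(values, levels, rows_ok) {
  j <- match(values, levels)
  use <- rows_ok & !is.na(j)
  Matrix::sparseMatrix(i = which(use), j = j[use], x = 1,
                       dims = c(length(values), length(levels)),
                       dimnames = list(NULL, levels))
}

#' Fit the augmented-block model for one trait and scope
#'
#' Checks enter as fixed effects (they calibrate the non-genetic layer);
#' test accessions are random with identity covariance. The joint scope
#' adds the accession-by-environment interaction term. Returns the
#' variance-component fit together with per-accession BLUPs, reliabilities
#' `r2 = 1 - PEV / sigma2_g` and deregressed values `y* = g_hat / r2`.
#'
#' @param pheno a [pheno_table()].
#' @param trait trait column name.
#' @param scope `"joint"` or one environment name.
#' @return list of class `augmented_fit`: `fit` (a `vc_fit`), `adjusted`
#'   (accession, g_blup, reliability, y_star), `params` (variance
#'   components, plot-level/joint heritability, interaction coefficient,
#'   selection accuracy, scope metadata).
#' @export
fit_augmented_model <- function(pheno, trait, scope = "joint") {
  stopifnot(inherits(pheno, "pheno_table"))
  traits <- attr(pheno, "traits")
  if (!trait %in% traits) stop_format("unknown trait '%s'", trait)
  dat <- as.data.frame(pheno)
  if (!identical(scope, "joint")) {
    if (!scope %in% dat$environment)
      stop_format("unknown environment '%s'", scope)
    dat <- dat[dat$environment == scope, , drop = FALSE]
  }
  dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
  if (nrow(dat) == 0L) stop_format("no observations for trait '%s' in scope '%s'", trait, scope)
  envs <- sort(unique(dat$environment))
  joint <- identical(scope, "joint") && length(envs) > 1L
  y <- dat[[trait]]
  n <- length(y)

  has_checks <- any(dat$is_check)
  varieties <- sort(unique(dat$accession[!dat$is_check]))
  if (!has_checks && !anyDuplicated(dat$accession[!dat$is_check]) && !joint)
    stop_format(paste0("design has one plot per accession and no checks: ",
                       "block and genotypic variance are confounded"))

  # fixed: per-environment population means, plus one offset per check
  X <- if (length(envs) > 1L) {
    stats::model.matrix(~ 0 + factor(environment, levels = envs), dat)
  } else matrix(1, n, 1)
  colnames(X) <- paste0("mean_", envs)
  if (has_checks) {
    checks <- sort(unique(dat$accession[dat$is_check]))
    Xc <- vapply(checks, function(ch) as.numeric(dat$accession == ch), numeric(n))
    colnames(Xc) <- paste0("check_", checks)
    X <- cbind(X, Xc)
  }

  blockf <- factor(paste(dat$environment, dat$block, sep = ":"))
  terms <- list(
    reml_term(incidence_partial(dat$accession, varieties, !dat$is_check),
              label = "genotype"),
    reml_term(blockf, label = "block"))
  if (joint) {
    klev <- as.vector(outer(varieties, envs, paste, sep = "@"))
    kval <- paste(dat$accession, dat$environment, sep = "@")
    terms <- c(terms, list(
      reml_term(incidence_partial(kval, klev, !dat$is_check), label = "gxe")))
  }

  fit <- fit_reml(y, X, terms, pev_terms = "genotype")
  s2 <- fit$sigma2
  sg <- s2[["genotype"]]; sb <- s2[["block"]]; se <- s2[["residual"]]
  sk <- if (joint) s2[["gxe"]] else 0
  tot <- sg + sk + sb + se

  rel <- fit$reliability$genotype
  gb <- fit$blup$genotype
  ystar <- deregress(gb, rel)
  adjusted <- data.frame(accession = varieties, scope = scope,
                         g_blup = as.numeric(gb),
                         reliability = as.numeric(rel),
                         y_star = as.numeric(ystar),
                         stringsAsFactors = FALSE)
  params <- list(scope = scope, trait = trait,
                 n_lines = length(varieties) + length(unique(dat$accession[dat$is_check])),
                 phenotypic_mean = mean(y),
                 sigma2 = c(genotype = sg, gxe = sk, block = sb, residual = se),
                 h2_plot = if (joint) NA_real_ else sg / tot,
                 h2_total = if (joint) (sg + sk) / tot else NA_real_,
                 c2_int = if (joint) sk / tot else NA_real_,
                 accuracy = sqrt(mean(rel)))
  structure(list(fit = fit, adjusted = adjusted, params = params),
            class = "augmented_fit")
}

#' Deregress BLUPs by their reliabilities
#'
#' `y* = g_hat / r2`. Non-positive reliabilities give a missing value with
#' a warning (those accessions carry no usable information).
#'
#' @param blups numeric BLUPs.
#' @param reliabilities numeric reliabilities in (0, 1].
#' @return numeric vector of deregressed values.
#' @export
deregress <- function(blups, reliabilities) {
  stopifnot(length(blups) == length(reliabilities))
  bad <- !is.finite(reliabilities) | reliabilities <= 0
  if (any(bad))
    warn_format("%d accession(s) with reliability <= 0: deregressed value set missing",
                sum(bad))
  out <- ifelse(bad, NA_real_, blups / reliabilities)
  names(out) <- names(blups)
  out
}

#' Genetic-parameter report across scopes
#'
#' Combines the per-environment and joint augmented-model fits into the
#' standard summary: plot-level heritabilities per site, joint heritability
#' (interaction variance in the numerator), the interaction coefficient
#' `c2_int = sigma2_k / total` with its share of the joint heritability,
#' the across-site genetic correlation and selection accuracies.
#'
#' @param fit_envs named list of per-environment `augmented_fit`s.
#' @param fit_joint the joint-scope `augmented_fit`.
#' @param rgl_formula `"correlation"` (default) computes
#'   `r_gl = sigma2_g / (sigma2_g + sigma2_k)`, the across-site genetic
#'   correlation implied by the compound-symmetric interaction model;
#'   `"paper_literal"` reproduces the printed covariance-over-sum-of-
#'   variances form `sigma_g12 / (sigma2_g1 + sigma2_g2)`, which is not a
#'   correlation (see the methods vignette).
#' @return list of class `genetic_params` with per-scope entries and the
#'   derived ratios (percentages rounded as conventionally reported).
#' @export
genetic_params <- function(fit_envs, fit_joint, rgl_formula = c("correlation", "paper_literal")) {
  rgl_formula <- match.arg(rgl_formula)
  stopifnot(inherits(fit_joint, "augmented_fit"))
  if (inherits(fit_envs, "augmented_fit")) fit_envs <- list(fit_envs)
  s2 <- fit_joint$params$sigma2
  sg <- s2[["genotype"]]; sk <- s2[["gxe"]]
  tot <- sum(s2)
  if (tot <= 0) stop_format("zero total variance: ratios undefined")
  h2_total <- (sg + sk) / tot
  c2_int <- sk / tot
  rgl <- rgl_cross_site(sg, sk, rgl_formula)
  env_tab <- lapply(fit_envs, function(f)
    list(scope = f$params$scope, h2_plot = f$params$h2_plot,
         accuracy = f$params$accuracy, n_lines = f$params$n_lines,
         phenotypic_mean = f$params$phenotypic_mean))
  structure(list(trait = fit_joint$params$trait,
                 environments = env_tab,
                 h2_total = h2_total, c2_int = c2_int,
                 c2_pct_of_h2 = interaction_pct(c2_int, h2_total),
                 r_gl = rgl, rgl_formula = rgl_formula,
                 accuracy_joint = fit_joint$params$accuracy,
                 sigma2 = s2),
            class = "genetic_params")
}

# across-site genetic correlation under the compound-symmetric G x E model
rgl_cross_site <- function(sigma2_g, sigma2_k, formula = "correlation") {
  if (sigma2_g + sigma2_k <= 0) return(NA_real_)
  if (formula == "paper_literal") sigma2_g / (2 * (sigma2_g + sigma2_k))
  else sigma2_g / (sigma2_g + sigma2_k)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("Genetic parameters for '%s'\n", x$trait))
  for (e in x$environments)
    cat(sprintf("  %s: h2 plot = %.2f, accuracy = %.2f (n = %d)\n",
                e$scope, e$h2_plot, e$accuracy, e$n_lines))
  cat(sprintf("  joint: h2_total = %.2f, c2_int = %.2f (%d%% of h2_total), r_gl = %.2f\n",
              x$h2_total, x$c2_int, x$c2_pct_of_h2, x$r_gl))
  invisible(x)
}

#' Joint heritability from variance components
#'
#' `h2_joint = (sigma2_g + sigma2_k) / (sigma2_g + sigma2_k + sigma2_b +
#' sigma2_e)`.
#'
#' @param sigma2_g,sigma2_k,sigma2_b,sigma2_e variance components
#'   (genotypic, interaction, block, residual).
#' @return the heritability ratio.
#' @export
h2_joint <- function(sigma2_g, sigma2_k, sigma2_b, sigma2_e) {
  tot <- sigma2_g + sigma2_k + sigma2_b + sigma2_e
  if (tot <= 0) stop_format("zero total variance: ratio undefined")
  (sigma2_g + sigma2_k) / tot
}

#' Interaction coefficient from variance components
#'
#' `c2_int = sigma2_k / (sigma2_g + sigma2_k + sigma2_b + sigma2_e)`.
#'
#' @inheritParams h2_joint
#' @return the interaction coefficient of determination.
#' @export
c2_interaction <- function(sigma2_g, sigma2_k, sigma2_b, sigma2_e) {
  tot <- sigma2_g + sigma2_k + sigma2_b + sigma2_e
  if (tot <= 0) stop_format("zero total variance: ratio undefined")
  sigma2_k / tot
}

#' Interaction share of the joint heritability, in percent
#'
#' The conventionally reported integer percentage `100 * c2_int /
#' h2_total`.
#'
#' @param c2_int interaction coefficient.
#' @param h2_total joint heritability.
#' @return integer percent.
#' @export
interaction_pct <- function(c2_int, h2_total) {
  if (h2_total <= 0) stop_format("h2_total must be positive")
  round(100 * c2_int / h2_total)
}

#' Explained-heritability fraction, in percent
#'
#' The headline comparison metric: the share of the trait heritability
#' captured by a genomic, marker or regional heritability estimate,
#' `100 * h2_component / h2_reference`.
#'
#' @param h2_component the component estimate (e.g. whole-genome, marker or
#'   regional heritability).
#' @param h2_reference the trait heritability it is measured against.
#' @param digits rounding of the printed percentage (default 2).
#' @return numeric percent.
#' @export
explained_pct <- function(h2_component, h2_reference, digits = 2) {
  if (h2_reference <= 0) stop_format("reference heritability must be positive")
  round(100 * h2_component / h2_reference, digits)
}
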
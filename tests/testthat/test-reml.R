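test_that("balanced one-way layouts reproduce the closed-form REML estimators", {
  interior <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    a <- 5; r <- 4
    g <- factor(rep(seq_len(a), each = r))
    y <- rnorm(a, sd = 1.2)[g] + rnorm(a * r)
    av <- anova(lm(y ~ g))
    msb <- av["g", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
    if ((msb - msw) / r <= 0) next    # boundary case: closed form not interior
    interior <- interior + 1L
    fit <- fit_reml(y, NULL, list(reml_term(g, label = "group")))
    expect_equal(fit$sigma2[["group"]], (msb - msw) / r, tolerance = 1e-6)
    expect_equal(fit$sigma2[["residual"]], msw, tolerance = 1e-6)
  }
  expect_gte(interior, 15L)
})

test_that("restricted log-likelihood and BLUPs agree with lme4 on identity-K models", {
  skip_if_not_installed("lme4")
  set.seed(7)
  n <- 120
  g <- factor(sample(letters[1:15], n, TRUE))
  b <- factor(sample(LETTERS[1:6], n, TRUE))
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(15)[g] + 0.7 * rnorm(6)[b] + rnorm(n)
  fit <- fit_reml(y, cbind(1, x), list(reml_term(g, label = "g"),
                                       reml_term(b, label = "b")))
  lf <- lme4::lmer(y ~ x + (1 | g) + (1 | b), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$logLik, as.numeric(logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$sigma2[["g"]]), vc$vcov[vc$grp == "g"], tolerance = 1e-4)
  expect_equal(unname(fit$sigma2[["b"]]), vc$vcov[vc$grp == "b"], tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$blup$g[levels(g)]),
               unname(lme4::ranef(lf)$g[levels(g), 1]), tolerance = 1e-4)
})

test_that("scaling the response scales variances by c^2 and effects by c", {
  set.seed(11)
  g <- factor(rep(1:8, each = 3))
  y <- rnorm(8)[g] + rnorm(24)
  f1 <- fit_reml(y, NULL, list(reml_term(g, label = "g")))
  f2 <- fit_reml(5 * y, NULL, list(reml_term(g, label = "g")))
  expect_equal(f2$sigma2, 25 * f1$sigma2, tolerance = 1e-5)
  expect_equal(f2$beta, 5 * f1$beta, tolerance = 1e-6)
})

test_that("general covariance K is honoured and matches the rotated fast path", {
  set.seed(13)
  n <- 60
  A <- crossprod(matrix(rnorm(n * n), n)) / n
  y <- drop(chol(A) %*% rnorm(n)) * 0.8 + rnorm(n)
  fit <- fit_reml(y, NULL, list(reml_term(Matrix::Diagonal(n), K = A, label = "g")))
  fk <- fit_kinship_reml(y, G = A)
  expect_equal(fit$logLik, fk$logLik, tolerance = 1e-5)
  expect_equal(fit$sigma2[["g"]], fk$sigma2[["genomic"]], tolerance = 1e-3)
  expect_equal(unname(fit$blup$g), unname(fk$blup$genomic), tolerance = 1e-3)
  expect_error(fit_reml(y, NULL, list(reml_term(Matrix::Diagonal(n),
                                                K = -A, label = "g"))),
               "positive semidefinite")
})

test_that("confounded random structures warn and land on a boundary", {
  set.seed(17)
  y <- rnorm(25)
  expect_warning(
    fit <- fit_reml(y, NULL, list(reml_term(factor(seq_along(y)), label = "id"))),
    "proportional")
  expect_true("id" %in% fit$boundary || fit$sigma2[["id"]] < 1e-6 ||
                fit$sigma2[["residual"]] < 1e-6)
})

test_that("solution beats random feasible parameter vectors (local optimality)", {
  set.seed(19)
  g <- factor(rep(1:10, each = 4))
  b <- factor(rep(rep(1:4, each = 1), 10))
  y <- rnorm(10)[g] + 0.5 * rnorm(4)[b] + rnorm(40)
  fit <- fit_reml(y, NULL, list(reml_term(g, label = "g"), reml_term(b, label = "b")))
  # recompute the profiled criterion through an independent dense-V evaluation
  Zg <- model.matrix(~ 0 + g); Zb <- model.matrix(~ 0 + b)
  X <- matrix(1, 40, 1)
  crit <- function(th) {
    H <- diag(40) + th[1] * tcrossprod(Zg) + th[2] * tcrossprod(Zb)
    Hi <- solve(H)
    XHX <- crossprod(X, Hi %*% X)
    P <- Hi - Hi %*% X %*% solve(XHX, crossprod(X, Hi))
    ypy <- drop(crossprod(y, P %*% y))
    np <- 39
    -0.5 * (np * log(ypy / np) + determinant(H)$modulus +
              determinant(XHX)$modulus + np * (1 + log(2 * pi)))
  }
  th_hat <- fit$sigma2[c("g", "b")] / fit$sigma2[["residual"]]
  expect_equal(crit(th_hat), fit$logLik, tolerance = 1e-4, ignore_attr = TRUE)
  for (i in 1:100) {
    th <- exp(runif(2, -3, 3))
    expect_lte(crit(th), fit$logLik + 1e-6)
  }
})

test_that("REML criterion is invariant to the fixed-effect contrast basis", {
  set.seed(23)
  f <- factor(rep(1:3, each = 10))
  g <- factor(rep(1:6, 5))
  y <- c(0, 1, 2)[f] + rnorm(6)[g] + rnorm(30)
  X1 <- model.matrix(~ f)            # treatment contrasts
  X2 <- model.matrix(~ 0 + f)        # cell means
  f1 <- fit_reml(y, X1, list(reml_term(g, label = "g")))
  f2 <- fit_reml(y, X2, list(reml_term(g, label = "g")))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
})

test_that("PEVs keep reliabilities inside [0, 1]", {
  set.seed(29)
  g <- factor(rep(1:20, each = 3))
  y <- rnorm(20, sd = 1.5)[g] + rnorm(60)
  fit <- fit_reml(y, NULL, list(reml_term(g, label = "g")))
  expect_true(all(fit$pev$g >= 0))
  expect_true(all(fit$pev$g <= fit$sigma2[["g"]] + 1e-10))
  expect_true(all(fit$reliability$g >= 0 & fit$reliability$g <= 1))
  expect_equal(mean(fit$blup$g), 0, tolerance = 1e-8)
})

test_that("likelihood ratios are floored at zero and validate nesting", {
  set.seed(31)
  g <- factor(rep(1:10, each = 3))
  y <- rnorm(10)[g] + rnorm(30)
  full <- fit_reml(y, NULL, list(reml_term(g, label = "g")))
  reduced <- fit_reml(y, NULL, list())
  lr <- likelihood_ratio(full, reduced)
  expect_gte(lr$lrt, 0)
  expect_equal(likelihood_ratio(full, full)$lrt, 0)
  y2 <- y + 1
  other <- fit_reml(y2, NULL, list())
  expect_error(likelihood_ratio(full, other), "same response")
})

test_that("null LRT distribution is a boundary mixture below chi-square(1)", {
  set.seed(37)
  lrts <- replicate(200, {
    g <- factor(rep(1:10, each = 3))
    y <- rnorm(30)                      # no group variance
    full <- fit_reml(y, NULL, list(reml_term(g, label = "g")),
                     pev_terms = FALSE, options = list(warn_identifiability = FALSE))
    reduced <- fit_reml(y, NULL, list())
    likelihood_ratio(full, reduced)$lrt
  })
  expect_gt(mean(lrts < 1e-6), 0.3)     # mass at the boundary
  # stochastically below chi2(1): empirical quantiles under the mixture
  expect_lt(quantile(lrts, 0.95), qchisq(0.95, 1) + 0.5)
  expect_lt(mean(lrts), 0.5 * 1 + 0.15) # mixture mean is 0.5
})

test_that("median LRT grows with planted regional signal", {
  med_lrt <- vapply(c(0, 0.1, 0.3), function(h2r) {
    lr <- vapply(1:6, function(s) {
      sim <- mapping_sim(n = 120, seed = 900 + 10 * s + round(100 * h2r),
                         regional_h2 = h2r, markers_per_chr = 150,
                         chr_mb = c(20, 20))
      G <- build_grm(sim$gm)
      wg <- window_grid(sim$gm$map)
      scan <- rhm_scan(sim$y, sim$gm, wg, G)
      w <- which(scan$chromosome == 1 & scan$start_bp == 8e6)
      scan$lrt[w]
    }, 0)
    median(lr)
  }, 0)
  expect_true(all(diff(med_lrt) > 0))
})
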
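test_that("cell-means fit reproduces hand-computed OLS quantities", {
  d <- default_design(2, 3)
  X <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6, dimnames = list("F1", d$sample))
  qm <- qm_from_log2(X, d)
  fit <- fit_linear_models(qm, "A_vs_B")
  expect_equal(unname(fit$beta[1, 1]), -3)
  expect_equal(fit$s2, 1)
  expect_equal(fit$df_resid, 4)
  expect_equal(unname(fit$u[1, 1]), sqrt(2 / 3))
  # constant feature has zero residual variance
  Xc <- matrix(5, 1, 6, dimnames = list("F1", d$sample))
  expect_equal(fit_linear_models(qm_from_log2(Xc, d), "A_vs_B")$s2, 0)
  expect_error(fit_linear_models(qm, "A_vs_Z"), "unknown condition")
})

test_that("fit matches an independent least-squares oracle on random data", {
  set.seed(101)
  d <- default_design(3, 3)
  X <- matrix(rnorm(500 * 9, 20, 1), 500, 9,
              dimnames = list(sprintf("F%03d", 1:500), d$sample))
  qm <- qm_from_log2(X, d)
  fit <- fit_linear_models(qm, c("A_vs_B", "B_vs_C"))
  g <- factor(d$condition)
  for (i in c(1, 57, 200, 499)) {
    lmfit <- lm(X[i, ] ~ 0 + g)
    expect_equal(unname(fit$beta[i, "A_vs_B"]),
                 unname(coef(lmfit)["gA"] - coef(lmfit)["gB"]),
                 tolerance = 1e-10)
    expect_equal(fit$s2[i], sum(residuals(lmfit)^2) / lmfit$df.residual,
                 tolerance = 1e-10)
  }
})

test_that("squeeze_var handles the zero-spread limit exactly", {
  prior <- squeeze_var(rep(0.04, 1000), rep(4, 1000))
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_2, 0.04, tolerance = 1e-10)
})

test_that("squeeze_var recovers prior parameters from simulated variances", {
  set.seed(2024)
  d0 <- 4; s0_2 <- 0.05; dg <- 4; n <- 5000
  sigma2 <- s0_2 * d0 / rchisq(n, d0)           # inverse-chi-square prior
  s2 <- sigma2 * rchisq(n, dg) / dg              # sampling distribution
  prior <- squeeze_var(s2, rep(dg, n))
  expect_gt(prior$d0, 3.2)
  expect_lt(prior$d0, 4.8)
  expect_equal(prior$s0_2, s0_2, tolerance = 0.1)
  # agreement with limma's independent moment estimator
  fd <- limma::fitFDist(s2, df1 = rep(dg, n))
  expect_equal(prior$d0, fd$df2, tolerance = 0.02)
  expect_equal(prior$s0_2, fd$scale, tolerance = 0.02)
})

test_that("the trigamma inverse agrees with a bisection oracle", {
  bisect <- function(y, lo = 1e-8, hi = 1e8) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > y) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (y in 10^seq(-5, 5, length.out = 21)) {
    x <- proteopipe:::trigamma_inverse(y)
    expect_equal(x, bisect(y), tolerance = 1e-8)
  }
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and matches the formula", {
  d <- default_design(2, 4)
  set.seed(77)
  X <- matrix(rnorm(50 * 8, 20, 0.5), 50, 8,
              dimnames = list(sprintf("F%02d", 1:50), d$sample))
  qm <- qm_from_log2(X, d)
  fit <- fit_linear_models(qm, "A_vs_B")
  p0 <- structure(list(d0 = 0, s0_2 = 1), class = "ShrinkageParams")
  res0 <- moderated_test(fit, p0)
  for (i in c(3, 20)) {
    tt <- t.test(X[i, 1:4], X[i, 5:8], var.equal = TRUE)
    expect_equal(res0$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res0$p[i], tt$p.value, tolerance = 1e-10)
  }
  # direct formula evaluation at d0 = 2
  fit1 <- structure(list(feature_id = "F1",
                         beta = matrix(0.6, 1, 1,
                                       dimnames = list("F1", "A_vs_B")),
                         u = matrix(sqrt(0.5), 1, 1),
                         s2 = 0.04, df_resid = 4,
                         contrasts = data.frame(name = "A_vs_B", a = "A",
                                                b = "B")),
                    class = "FitResult")
  pr <- structure(list(d0 = 2, s0_2 = 0.01), class = "ShrinkageParams")
  r <- moderated_test(fit1, pr)
  s2_tilde <- (2 * 0.01 + 4 * 0.04) / 6
  expect_equal(s2_tilde, 0.03)
  expect_equal(r$t_mod, 0.6 / (sqrt(0.5) * sqrt(0.03)))
  expect_equal(r$df_total, 6)
  expect_equal(r$p, 2 * pt(-abs(r$t_mod), 6))
  # d0 = Inf gives the s0-based normal reference
  prInf <- structure(list(d0 = Inf, s0_2 = 0.04), class = "ShrinkageParams")
  rInf <- moderated_test(fit1, prInf)
  expect_equal(rInf$t_mod, 0.6 / (sqrt(0.5) * 0.2))
  expect_equal(rInf$p, 2 * pnorm(-abs(rInf$t_mod)))
})

test_that("the moderated pipeline matches limma on random data", {
  set.seed(404)
  d <- default_design(2, 3)
  X <- matrix(rnorm(300 * 6, 20, 0.6), 300, 6,
              dimnames = list(sprintf("F%03d", 1:300), d$sample))
  qm <- qm_from_log2(X, d)
  fit <- fit_linear_models(qm, "B_vs_A")
  prior <- squeeze_var(fit$s2, fit$df_resid)
  res <- moderated_test(fit, prior)
  dm <- model.matrix(~ 0 + factor(d$condition, levels = c("A", "B")))
  colnames(dm) <- c("A", "B")
  lfit <- limma::lmFit(X, dm)
  cfit <- limma::contrasts.fit(lfit, limma::makeContrasts(B - A, levels = dm))
  efit <- limma::eBayes(cfit)
  expect_equal(res$log2fc, unname(efit$coefficients[, 1]), tolerance = 1e-8)
  expect_equal(res$t_mod, unname(efit$t[, 1]), tolerance = 1e-4)
  expect_equal(res$p, unname(efit$p.value[, 1]), tolerance = 1e-3)
})

test_that("variance shrinkage interpolates between feature and prior", {
  set.seed(15)
  n <- 500
  sigma2 <- 0.05 * 2 / rchisq(n, 2)       # heavy-tailed variance prior
  s2 <- sigma2 * rchisq(n, 3) / 3
  df <- rep(3, n)
  prior <- squeeze_var(s2, df)
  expect_true(is.finite(prior$d0))
  s2_tilde <- (prior$d0 * prior$s0_2 + df * s2) / (prior$d0 + df)
  expect_true(all(s2_tilde >= pmin(s2, prior$s0_2) - 1e-12))
  expect_true(all(s2_tilde <= pmax(s2, prior$s0_2) + 1e-12))
  # moderated t^2 decreases as the posterior variance grows
  t2 <- 0.5^2 / s2_tilde
  expect_true(all(diff(t2[order(s2_tilde)]) <= 0))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_bh(p), bh_bruteforce(p))
  }
})

test_that("rejection gating is the conjunction of FDR and effect size", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    contrast_name = "A_vs_B",
                    log2fc = c(2, 0.5, -1.5), t_mod = 1, df_total = 4,
                    p = c(0.001, 0.002, 0.2),
                    padj = c(0.04, 0.04, 0.3), significant = NA)
  out <- add_rejections(res, alpha = 0.05, lfc = 0)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))
  out1 <- add_rejections(res, alpha = 0.05, lfc = 1)
  expect_identical(out1$significant, c(TRUE, FALSE, FALSE))
  set.seed(66)
  tbl <- data.frame(feature_id = paste0("f", 1:200),
                    contrast_name = "x", log2fc = rnorm(200),
                    t_mod = 0, df_total = 1,
                    p = runif(200), padj = runif(200), significant = NA)
  out2 <- add_rejections(tbl, alpha = 0.1, lfc = 0.5)
  expect_equal(sum(out2$significant),
               sum(tbl$padj <= 0.1 & abs(tbl$log2fc) >= 0.5))
})
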
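test_that("Wald ratios follow the first-order ratio/se form", {
  h <- harmonized_set(beta_x = c(0.1, 0.2, -0.1),
                      se_x = rep(0.01, 3),
                      beta_y = c(0.05, 0, 0.05),
                      se_y = c(0.01, 0.02, 0.01))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0, -0.5))
  expect_equal(wr$se, c(0.1, 0.1, 0.1))
  # second-order SE adds the exposure-side variance
  wr2 <- wald_ratios(h, se_order = 2L)
  expect_equal(wr2$se[1], sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  # zero-beta_x SNPs are excluded with a record
  h0 <- harmonized_set(beta_x = c(0.1, 0), se_x = rep(0.01, 2),
                       beta_y = c(0.05, 0.05), se_y = rep(0.01, 2))
  wr0 <- wald_ratios(h0)
  expect_equal(nrow(wr0), 1L)
  expect_equal(attr(wr0, "excluded"), "snp2")
  hz <- harmonized_set(beta_x = c(0, 0), se_x = rep(0.01, 2),
                       beta_y = c(0.05, 0.05), se_y = rep(0.01, 2))
  expect_error(wald_ratios(hz), "zero exposure effect")
})

test_that("IVW reduces to the consensus ratio with unit dispersion when all
          ratios agree", {
  r <- 0.37
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h <- harmonized_set(beta_x = bx, se_x = rep(0.01, 4), beta_y = r * bx,
                      se_y = c(0.01, 0.03, 0.02, 0.05))
  est <- mr_ivw(h)
  expect_equal(est$beta, r)
  expect_equal(cochran_q(h)$q_stat, 0)
  # phi = 1: the SE equals the fixed-effect SE
  w <- 1 / c(0.01, 0.03, 0.02, 0.05)^2
  expect_equal(est$se, sqrt(1 / sum(w * bx^2)))
})

test_that("IVW matches the normal-equations oracle on a fixture", {
  h <- fixture_h4()
  est <- mr_ivw(h)
  o <- oracle_ivw(h$snps$beta_x, h$snps$beta_y, h$snps$se_y)
  expect_equal(est$beta, o$beta, tolerance = 1e-10)
  expect_equal(est$se, o$se, tolerance = 1e-10)
  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.02)
  expect_error(mr_ivw(h1), "at least 2")
})

test_that("single-SNP IVW equals the Wald ratio through the internal core", {
  core <- mrscreen:::ivw_core(0.1, 0.07, 0.02)
  expect_equal(core$beta, 0.7)
  expect_equal(core$q, 0)
})

test_that("MR-Egger recovers an exact affine relation and matches the
          oracle on a fixture", {
  a <- 0.02; b <- 0.6
  bx <- c(0.05, 0.08, 0.12, 0.16, 0.2)
  h <- harmonized_set(beta_x = bx, se_x = rep(0.01, 5),
                      beta_y = a + b * bx, se_y = rep(0.02, 5))
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, b, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, a, tolerance = 1e-12)

  h5 <- fixture_h5()
  eg5 <- mr_egger(h5)
  o <- oracle_egger(h5$snps$beta_x, h5$snps$beta_y, h5$snps$se_y)
  expect_equal(eg5$slope$beta, o$slope, tolerance = 1e-10)
  expect_equal(eg5$intercept$estimate, o$intercept, tolerance = 1e-10)
  expect_equal(eg5$slope$se, o$se_slope, tolerance = 1e-10)
  expect_equal(eg5$intercept$se, o$se_intercept, tolerance = 1e-10)
  h2 <- fixture_h4()
  h2$snps <- h2$snps[1:2, ]
  expect_error(mr_egger(h2), "at least 3")
})

test_that("the weighted median interpolates the cumulative weights and
          hits the middle ratio for odd J with equal weights", {
  bx <- rep(0.1, 5)
  h <- harmonized_set(beta_x = bx, se_x = rep(0.01, 5),
                      beta_y = c(0.03, 0.01, 0.05, 0.02, 0.04),
                      se_y = rep(0.02, 5))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.3)  # middle of 0.1..0.5

  h4 <- fixture_h4()
  est4 <- mr_weighted_median(h4, n_boot = 200, seed = 1)
  o <- oracle_weighted_median(h4$snps$beta_y / h4$snps$beta_x,
                              h4$snps$beta_x^2 / h4$snps$se_y^2)
  expect_equal(est4$beta, o, tolerance = 1e-12)
  # the bootstrap is reproducible under the seed
  est4b <- mr_weighted_median(h4, n_boot = 200, seed = 1)
  expect_identical(est4$se, est4b$se)
})

test_that("mode estimators locate the dominant ratio cluster", {
  h <- harmonized_set(beta_x = rep(0.1, 4), se_x = rep(0.01, 4),
                      beta_y = rep(0.025, 4), se_y = rep(0.02, 4))
  md <- mr_modes(h, n_boot = 100, seed = 2)
  expect_equal(md$beta, c(0.25, 0.25))  # degenerate cloud: both modes exact

  # bimodal: 7 SNPs near ratio 0, 3 near ratio 1
  set.seed(5)
  bx <- rep(0.2, 10)
  ratios <- c(rnorm(7, 0, 0.02), rnorm(3, 1, 0.02))
  se_y <- c(rep(0.1, 7), rep(0.004, 3))  # weight mass on the ratio-1 trio
  h2 <- harmonized_set(beta_x = bx, se_x = rep(0.01, 10),
                       beta_y = ratios * bx, se_y = se_y)
  md2 <- mr_modes(h2, n_boot = 100, seed = 3)
  simple <- md2$beta[md2$method == "simple_mode"]
  weighted <- md2$beta[md2$method == "weighted_mode"]
  expect_lt(abs(simple - 0), 0.15)
  expect_lt(abs(weighted - 1), 0.15)
})

test_that("estimates are scale-equivariant in the outcome units", {
  h <- fixture_h5()
  c_ <- 3.7
  h2 <- h
  h2$snps$beta_y <- h$snps$beta_y * c_
  h2$snps$se_y <- h$snps$se_y * c_
  f1 <- mr_fit(h, seed = 11, n_boot = 200)
  f2 <- mr_fit(h2, seed = 11, n_boot = 200)
  expect_equal(f2$estimates$beta, f1$estimates$beta * c_, tolerance = 1e-8)
  expect_equal(f2$estimates$se, f1$estimates$se * c_, tolerance = 1e-8)
})

test_that("estimates are invariant to joint instrument re-orientation", {
  h <- fixture_h5()
  h2 <- h
  flip <- c(-1, 1, -1, -1, 1)
  h2$snps$beta_x <- h$snps$beta_x * flip
  h2$snps$beta_y <- h$snps$beta_y * flip
  f1 <- mr_fit(h, seed = 13, n_boot = 200)
  f2 <- mr_fit(h2, seed = 13, n_boot = 200)
  expect_equal(f2$estimates$beta, f1$estimates$beta, tolerance = 1e-10)
  expect_equal(f2$estimates$se, f1$estimates$se, tolerance = 1e-10)
  expect_equal(f2$egger_intercept$estimate, f1$egger_intercept$estimate,
               tolerance = 1e-10)
})

test_that("odds-ratio columns are consistent with the log-odds estimates", {
  f <- mr_fit(fixture_h5(), seed = 17, n_boot = 200)
  est <- f$estimates
  expect_equal(est$or_, exp(est$beta))
  expect_equal(est$ci_low, exp(est$beta - 1.96 * est$se))
  expect_equal(est$ci_high, exp(est$beta + 1.96 * est$se))
  expect_true(all(est$ci_low < est$or_ & est$or_ < est$ci_high))
  expect_true(all(est$pval > 0 & est$pval <= 1))
})

test_that("the fit object supports the standard modelling accessors", {
  f <- mr_fit(fixture_h5(), seed = 19, n_boot = 200)
  expect_named(coef(f), c("ivw", "egger", "weighted_median", "simple_mode",
                          "weighted_mode"))
  ci <- confint(f)
  expect_equal(dim(ci), c(5L, 2L))
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))
  r <- residuals(f, "ivw")
  expect_length(r, 5L)
  expect_equal(sum((1 / f$harmonized$snps$se_y) * 0 + r *
                     (f$harmonized$snps$beta_x / f$harmonized$snps$se_y)),
               0, tolerance = 1e-8)  # weighted orthogonality of IVW residuals
  expect_output(print(f), "Two-sample MR fit")
  expect_output(print(summary(f)), "Wald ratios")
})
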
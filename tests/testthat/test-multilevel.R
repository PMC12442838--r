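test_that("ICC is the exact variance ratio with guarded domain", {
  expect_equal(round(icc(0.058, 0.084), 3), 0.408)
  expect_equal(round(icc(0.193, 0.425), 3), 0.312)
  expect_equal(icc(0, 0.5), 0)
  expect_equal(icc(0.5, 0), 1)
  expect_error(icc(0, 0), class = "emadiff_domain_error")
  expect_error(icc(-0.1, 0.5), class = "emadiff_domain_error")
})

test_that("null model ML matches lme4 and REML matches ANOVA closed forms", {
  set.seed(2)
  J <- 150; n <- 6
  d <- data.frame(
    p = rep(seq_len(J), each = n),
    y = 1.4 + rep(rnorm(J, 0, sqrt(0.06)), each = n) +
      rnorm(J * n, 0, sqrt(0.09)))
  f <- fit_null_model(d, y, p)
  m <- lme4::lmer(y ~ 1 + (1 | p), d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(f$delta, unname(lme4::fixef(m))[1], tolerance = 1e-5)

  # balanced one-way ANOVA estimators are the REML solution
  fr <- fit_null_model(d, y, p, method = "REML")
  msb <- n * var(tapply(d$y, d$p, mean))
  msw <- sum((d$y - ave(d$y, d$p))^2) / (J * (n - 1))
  expect_equal(fr$tau2, (msb - msw) / n, tolerance = 1e-6)
  expect_equal(fr$sigma2, msw, tolerance = 1e-6)
  expect_equal(fr$icc, icc((msb - msw) / n, msw), tolerance = 1e-6)
})

test_that("degenerate grouping structures are rejected or collapse to ICC 0", {
  d1 <- data.frame(p = 1:80, y = rnorm(80))
  expect_error(fit_null_model(d1, y, p),
               class = "emadiff_precondition_error")

  set.seed(3)
  J <- 100; n <- 6
  y <- rnorm(J * n)
  d2 <- data.frame(p = rep(seq_len(J), each = n),
                   y = y - rep(tapply(y, rep(seq_len(J), each = n), mean),
                               each = n))
  f <- fit_null_model(d2, y, p)
  expect_lt(f$icc, 0.02)
})

test_that("latent regression recovers level-specific standardized paths", {
  d <- make_latent_reg_data(seed = 10, J = 300, n = 10)
  lr <- fit_latent_regression(d, y, x, z, person)
  # a loose recovery bound at this size; the tight claim at 500 x 20 sits in
  # the acceptance suite
  expect_true(all(abs(lr$within$std - c(-0.7, 0.6)) < 0.1))
  expect_true(all(abs(lr$between$std - c(-0.6, 0.75)) < 0.12))
  expect_true(lr$within$r2 >= 0 && lr$within$r2 <= 1)
  expect_true(lr$between$r2 >= 0 && lr$between$r2 <= 1)

  d$z2 <- d$x
  expect_error(fit_latent_regression(d, y, x, z2, person),
               class = "emadiff_collinearity_error")
})

test_that("multilevel correlations recover level-specific structure", {
  set.seed(4)
  J <- 500; n <- 10
  ab <- rnorm(J); bb <- 0.66 * ab + sqrt(1 - 0.66^2) * rnorm(J)
  cb <- rnorm(J)
  aw <- rnorm(J * n); bw <- 0.39 * aw + sqrt(1 - 0.39^2) * rnorm(J * n)
  cw <- rnorm(J * n)
  d <- data.frame(p = rep(seq_len(J), each = n),
                  v1 = rep(ab, each = n) + aw,
                  v2 = rep(bb, each = n) + bw,
                  v3 = rep(cb, each = n) + cw)
  mc <- multilevel_correlations(d, c("v1", "v2", "v3"), p)
  expect_equal(mc$within["v1", "v2"], 0.39, tolerance = 0.05)
  expect_equal(mc$between["v1", "v2"], 0.66, tolerance = 0.05)
  # independent pair is near zero at both levels
  expect_lt(abs(mc$within["v1", "v3"]), 0.05)
  expect_lt(abs(mc$between["v1", "v3"]), 0.05)
  expect_equal(mc$fisher_z$within["v1", "v2"], atanh(mc$within["v1", "v2"]))

  # duplicated variable correlates 1 at both levels
  d$v4 <- d$v1
  mc2 <- multilevel_correlations(d[, c("p", "v1", "v4")], c("v1", "v4"), p)
  expect_equal(mc2$within["v1", "v4"], 1, tolerance = 1e-3)
  expect_equal(mc2$between["v1", "v4"], 1, tolerance = 1e-3)
})

test_that("dependent-correlation test is null for identical pairs and powered for distinct ones", {
  set.seed(4)
  J <- 500; n <- 8
  ab <- rnorm(J)
  aw <- rnorm(J * n)
  d <- data.frame(p = rep(seq_len(J), each = n))
  d$v1 <- rep(ab, each = n) + aw
  d$v2 <- 0.6 * d$v1 + sqrt(1 - 0.36) * (rep(rnorm(J), each = n) * 0 +
                                           rnorm(J * n))
  d$v3 <- rnorm(J * n)
  mc <- multilevel_correlations(d, c("v1", "v2", "v3"), p)

  same <- compare_dependent_correlations(mc, c("v1", "v2"), c("v2", "v1"),
                                         level = "within", n_boot = 199)
  expect_equal(same$p_value, 1)
  expect_equal(same$diff_z, 0)

  diff <- compare_dependent_correlations(mc, c("v1", "v2"), c("v1", "v3"),
                                         level = "within", n_boot = 999,
                                         seed = 5)
  expect_lt(diff$p_value, 0.001)

  small <- d[d$p <= 30, ]
  mcs <- multilevel_correlations(small, c("v1", "v2", "v3"), p)
  expect_warning(
    compare_dependent_correlations(mcs, c("v1", "v2"), c("v1", "v3"),
                                   level = "within", n_boot = 99, seed = 1),
    "Fewer than 50 persons")
})

test_that("1-1-1 mediation recovers constructed paths and the exact decomposition", {
  md <- make_mediation_data(seed = 20, J = 300, n = 10)
  mf <- fit_mediation(md$data, w, c("m1", "m2"), y, person,
                      predictor_level = "occasion", mc_draws = 5000,
                      seed = 21)
  expect_true(all(abs(mf$indirect$estimate - md$truth$indirect_std) < 0.02))
  p <- mf$paths
  expect_equal(p$total_raw, p$cprime_raw + sum(p$indirect_raw),
               tolerance = 1e-10)
  expect_equal(p$total_std, p$cprime_std + sum(p$indirect_std),
               tolerance = 1e-10)
})

test_that("2-1-1 mediation places all paths at the between level", {
  set.seed(22)
  J <- 300; n <- 8
  nr <- rnorm(J)
  m1b <- -0.3 * nr + rnorm(J, 0, 0.5)
  m2b <- -0.2 * nr + rnorm(J, 0, 0.5)
  yb <- -0.4 * m1b + 0.5 * m2b + rnorm(J, 0, 0.3)
  pid <- rep(seq_len(J), each = n)
  d <- data.frame(person = pid, nr = rep(nr, each = n),
                  m1 = rep(m1b, each = n) + rnorm(J * n, 0, 0.6),
                  m2 = rep(m2b, each = n) + rnorm(J * n, 0, 0.6),
                  y = rep(yb, each = n) + rnorm(J * n, 0, 0.5))
  mf <- fit_mediation(d, nr, c("m1", "m2"), y, person,
                      predictor_level = "person", mc_draws = 5000, seed = 23)
  expect_equal(mf$level, "between")
  expect_true(all(abs(mf$paths$indirect_raw -
                        c(-0.3 * -0.4, -0.2 * 0.5)) < 0.05))
  expect_equal(mf$paths$total_raw,
               mf$paths$cprime_raw + sum(mf$paths$indirect_raw),
               tolerance = 1e-10)
})

test_that("mediation level declarations and degenerate predictors are validated", {
  md <- make_mediation_data(seed = 30, J = 60, n = 6)
  d <- md$data
  expect_error(fit_mediation(d, w, c("m1", "m2"), y, person,
                             predictor_level = "person"),
               class = "emadiff_level_error")
  d$wconst <- 1
  expect_error(fit_mediation(d, wconst, c("m1", "m2"), y, person,
                             predictor_level = "occasion"),
               class = "emadiff_precondition_error")
  d$wp <- rep(rbinom(60, 1, 0.5), each = 6)
  expect_error(fit_mediation(d, wp, c("m1", "m2"), y, person,
                             predictor_level = "occasion"),
               class = "emadiff_level_error")
})
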
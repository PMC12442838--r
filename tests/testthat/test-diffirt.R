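# shared small study: 100 persons x 8 completed prompts, no covariate
# effects or practice trends, continuous RTs (cleanest measurement-model case)
diffirt_cfg <- synthetic_config(
  n_persons = 100, days = 2, prompts_per_day = 4, completion_rate = 1,
  effect_work = c(theta = 0, lgamma = 0),
  effect_recovery = c(theta = 0, lgamma = 0),
  loading_neuroticism = c(theta = 0, lgamma = 0),
  loading_depression = c(theta = 0, lgamma = 0),
  gain_theta_z = 0, gain_lgamma_z = 0,
  # fast RT scale: keeps quantile sampling noise (in seconds) well inside
  # the Q-Q diagnostic bound at this fixture size
  mean_lgamma = 1.1,
  integer_rounding = FALSE)
diffirt_sim <- generate_dataset(diffirt_cfg, seed = 31)
diffirt_pp <- preprocess_ema(diffirt_sim$records,
                             diffirt_cfg$items$affect$item_id)
diffirt_fit <- fit_diffusion_irt(diffirt_pp, n_quad = 7)

test_that("item parameters are recovered up to the anchoring transformation", {
  truth <- diffirt_cfg$items$affect
  expect_gt(cor(diffirt_fit$item_params$v, truth$v), 0.9)
  expect_gt(cor(diffirt_fit$item_params$a, truth$a), 0.9)
  expect_equal(diffirt_fit$convergence$code, 0)
  expect_lt(diffirt_fit$convergence$gradient_norm, 1)
})

test_that("fitted likelihood is at least the likelihood at the generator truth", {
  mats <- emadiff:::build_diffirt_matrices(
    diffirt_pp$items, diffirt_fit$item_params$item_id, kappa = diffirt_fit$kappa)
  gh <- emadiff:::gauss_hermite_normal(7)
  truth <- diffirt_cfg$items$affect
  # truth re-expressed in the fit's anchoring (mean log gamma absorbed into a)
  sd_th <- sqrt(diffirt_cfg$sd_theta_between^2 + diffirt_cfg$sd_theta_within^2)
  sd_lg <- sqrt(diffirt_cfg$sd_lgamma_between^2 +
                  diffirt_cfg$sd_lgamma_within^2)
  nll_truth <- emadiff:::.diffirt_nll_cpp(
    mats$X, mats$TD, truth$v, truth$a * exp(-diffirt_cfg$mean_lgamma),
    sd_th, sd_lg, gh$nodes, gh$weights)
  expect_lte(-diffirt_fit$loglik, nll_truth + 1e-6)
})

test_that("EAP identification constraints hold on a converged fit", {
  sc <- score_occasions(diffirt_pp, diffirt_fit)
  expect_lt(abs(mean(sc$theta, na.rm = TRUE)), 0.1)
  expect_lt(abs(mean(sc$log_gamma, na.rm = TRUE)), 0.1)
})

test_that("per-occasion scores track the generating person parameters", {
  sc <- score_occasions(diffirt_pp, diffirt_fit)
  tr <- dplyr::inner_join(sc, diffirt_sim$truth$occasions,
                          by = c("person_id", "occasion_id"))
  expect_gt(cor(tr$theta.x, tr$theta.y, use = "complete.obs"), 0.5)
  expect_gt(cor(tr$log_gamma, tr$lgamma, use = "complete.obs"), 0.3)
})

test_that("estimates are invariant to row order and item relabeling", {
  set.seed(1)
  shuffled <- diffirt_pp$items[sample(nrow(diffirt_pp$items)), ]
  fit2 <- fit_diffusion_irt(shuffled,
                            item_set = diffirt_fit$item_params$item_id,
                            n_quad = 7)
  expect_equal(fit2$item_params$v, diffirt_fit$item_params$v,
               tolerance = 1e-6)
  expect_equal(fit2$item_params$a, diffirt_fit$item_params$a,
               tolerance = 1e-6)

  rev_set <- rev(diffirt_fit$item_params$item_id)
  fit3 <- fit_diffusion_irt(diffirt_pp$items, item_set = rev_set, n_quad = 7)
  expect_equal(fit3$item_params$v, rev(diffirt_fit$item_params$v),
               tolerance = 1e-6)
})

test_that("preconditions are enforced", {
  two_items <- diffirt_pp$items[diffirt_pp$items$item_id %in%
                                  c("angry", "lonely"), ]
  expect_error(fit_diffusion_irt(two_items),
               class = "emadiff_precondition_error")
  bad <- diffirt_pp$items
  bad$response <- bad$response + 1L
  expect_error(fit_diffusion_irt(bad),
               class = "emadiff_precondition_error")
})

test_that("absolute drift is the mean absolute deviation from the difficulties", {
  fake_fit <- structure(
    list(item_params = tibble::tibble(item_id = paste0("i", 1:5),
                                      v = c(-1, -0.5, 0, 0.5, 1),
                                      a = rep(1, 5)),
         sd_theta = 1e-6, sd_log_gamma = 0.3, n_quad = 7, kappa = 0.9),
    class = "diffirt_fit")
  rows <- tibble::tibble(
    person_id = "A", occasion_id = 1L, item_id = paste0("i", 1:5),
    response = c(0L, 1L, 0L, 1L, 0L), rt_seconds = c(2, 3, 4, 2.5, 3.5))
  sc <- score_occasions(rows, fake_fit, outlier_iqr = Inf)
  # prior variance ~ 0 pins theta at 0, so abs_drift = mean |0 - v_h| = 0.6
  expect_equal(sc$abs_drift, 0.6, tolerance = 1e-4)
})

test_that("extreme response patterns still get finite shrunken scores", {
  rows <- tibble::tibble(
    person_id = "A", occasion_id = 1L,
    item_id = diffirt_fit$item_params$item_id,
    response = 1L, rt_seconds = c(1.1, 1.0, 1.2, 1.0, 1.1))
  sc <- score_occasions(rows, diffirt_fit, outlier_iqr = Inf)
  expect_true(is.finite(sc$theta))
  expect_true(is.finite(sc$log_gamma))
})

test_that("Q-Q diagnostic is near the identity for model-consistent data and flags shifts", {
  set.seed(5)
  qq <- qq_diagnostic(diffirt_pp, diffirt_fit)
  med <- qq[qq$prob == 0.5, ]
  expect_lt(max(abs(med$observed - med$model)), 0.25)
  expect_true(all(tapply(qq$observed, qq$item_id,
                         function(v) all(diff(v) >= 0))))
  expect_true(all(tapply(qq$model, qq$item_id,
                         function(v) all(diff(v) >= 0))))

  # against the fit-time scores a constant RT shift is a visible offset
  shifted <- diffirt_pp$items
  shifted$rt_seconds <- shifted$rt_seconds + 2
  set.seed(6)
  qq2 <- qq_diagnostic(shifted, diffirt_fit,
                       scores = score_occasions(diffirt_pp, diffirt_fit,
                                                outlier_iqr = Inf))
  med2 <- qq2[qq2$prob == 0.5, ]
  expect_gt(stats::median(med2$observed - med2$model), 1)
  expect_s3_class(ggplot2::autoplot(qq), "ggplot")
})

test_that("one-factor diagnostic separates unidimensional from independent items", {
  ud <- check_unidimensionality(diffirt_pp$items)
  expect_gt(ud$ratio, 3)
  expect_true(all(ud$loadings > 0))

  set.seed(8)
  indep <- matrix(rbinom(2000 * 4, 1, 0.4), ncol = 4,
                  dimnames = list(NULL, paste0("i", 1:4)))
  ud2 <- check_unidimensionality(indep)
  expect_lt(ud2$ratio, 1.5)

  dup <- cbind(i1 = indep[, 1], i2 = indep[, 1], i3 = indep[, 1])
  ud3 <- check_unidimensionality(dup)
  expect_equal(unname(ud3$loadings), rep(1, 3), tolerance = 1e-6)

  const <- cbind(indep, i5 = 1L)
  expect_warning(check_unidimensionality(const), "single observed category")
})
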
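test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_persons = 25, days = 2, prompts_per_day = 3)
  s1 <- generate_dataset(cfg, seed = 99)
  s2 <- generate_dataset(cfg, seed = 99)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$occasions, s2$truth$occasions)
  s3 <- generate_dataset(cfg, seed = 100)
  expect_false(identical(s1$records, s2$records) &&
                 identical(s1$records$rt_seconds, s3$records$rt_seconds))
  expect_error(generate_dataset(cfg), "seed")
})

test_that("config validation rejects impossible generative settings", {
  expect_error(synthetic_config(completion_rate = 0), "completion_rate")
  expect_error(synthetic_config(sd_theta_between = -1), "non-negative")
  bad_items <- list(affect = tibble::tibble(
    item_id = c("a", "b", "c"), v = 0, a = c(1, -1, 1), binary = FALSE))
  expect_error(synthetic_config(items = bad_items),
               class = "emadiff_domain_error")
})

test_that("the study-shape preset reproduces the design counts", {
  sim <- emulate_paper_shape(seed = 7)
  expect_equal(sim$truth$scheduled, 954 * 42)
  expect_equal(sim$truth$scheduled, 40068)
  # completion is binomial around 75% of scheduled
  expect_lt(abs(sim$truth$completed - 0.75 * 40068) / (0.75 * 40068), 0.05)
  occ_per_person <- table(unique(sim$records[, c("person_id",
                                                 "occasion_id")])$person_id)
  expect_lte(max(occ_per_person), 42)
})

test_that("item choice frequencies match the logistic response function", {
  sim <- generate_dataset(
    synthetic_config(n_persons = 300, days = 3, prompts_per_day = 4,
                     completion_rate = 1), seed = 13)
  tr <- dplyr::inner_join(
    sim$records,
    sim$truth$occasions[, c("person_id", "occasion_id", "theta", "gamma")],
    by = c("person_id", "occasion_id"))
  tr <- dplyr::inner_join(tr, sim$truth$items[, c("item_id", "v", "a")],
                          by = "item_id")
  binary_items <- sim$truth$items$item_id[sim$truth$items$binary]
  tr$x <- ifelse(tr$item_id %in% binary_items, tr$rating,
                 as.integer(tr$rating >= 50))
  agg <- tr |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(obs = mean(.data$x),
                     pred = mean(plogis((.data$gamma / .data$a) *
                                          (.data$theta - .data$v))),
                     n = dplyr::n())
  se <- sqrt(agg$pred * (1 - agg$pred) / agg$n)
  expect_true(all(abs(agg$obs - agg$pred) < 4 * se + 0.005))
})

test_that("generated latent components reproduce the configured ICCs", {
  cfg <- synthetic_config(
    n_persons = 500, days = 5, prompts_per_day = 6, completion_rate = 1,
    effect_work = c(theta = 0, lgamma = 0),
    effect_recovery = c(theta = 0, lgamma = 0),
    loading_neuroticism = c(theta = 0, lgamma = 0),
    loading_depression = c(theta = 0, lgamma = 0),
    gain_theta_z = 0, gain_lgamma_z = 0)
  sim <- generate_dataset(cfg, seed = 17)
  icc_theta <- fit_null_model(sim$truth$occasions, theta, person_id)$icc
  icc_lg <- fit_null_model(sim$truth$occasions, lgamma, person_id)$icc
  expect_lt(abs(icc_theta - icc(0.193, 0.425)), 0.05)
  expect_lt(abs(icc_lg - icc(0.062, 0.096)), 0.05)
})

test_that("integer-second rounding barely moves the boundary scores", {
  base <- synthetic_config(n_persons = 100, days = 2, prompts_per_day = 4,
                           completion_rate = 1, integer_rounding = FALSE)
  rounded <- base
  rounded$integer_rounding <- TRUE
  s_cont <- generate_dataset(base, seed = 23)
  s_int <- generate_dataset(rounded, seed = 23)
  # identical latent draws; only the recorded RTs differ
  expect_identical(s_cont$truth$occasions, s_int$truth$occasions)

  pp_int <- preprocess_ema(s_int$records, base$items$affect$item_id)
  pp_cont <- preprocess_ema(s_cont$records, base$items$affect$item_id)
  fit <- fit_diffusion_irt(pp_int, n_quad = 7)
  sc_int <- score_occasions(pp_int, fit, outlier_iqr = Inf)
  sc_cont <- score_occasions(pp_cont, fit, outlier_iqr = Inf)
  both <- dplyr::inner_join(sc_int, sc_cont,
                            by = c("person_id", "occasion_id"))
  expect_lt(mean(abs(both$log_gamma.x - both$log_gamma.y), na.rm = TRUE),
            0.05)
})

test_that("the full pipeline recovers the work mediation signs", {
  # Scaled-down replicates; signs, not magnitudes. Practice trends are
  # zeroed to isolate the work mechanism: the default trend parks
  # early-study drifts right at the item difficulties, where the
  # absolute-drift folding scrambles small activity shifts.
  for (s in c(7, 8)) {
    cfg <- synthetic_config(n_persons = 200, days = 3, prompts_per_day = 4,
                            completion_rate = 0.85,
                            gain_theta_z = 0, gain_lgamma_z = 0)
    sim <- generate_dataset(cfg, seed = s)
    pp <- preprocess_ema(sim$records, cfg$items$affect$item_id)
    fit <- fit_diffusion_irt(pp, n_quad = 7)
    sc <- score_occasions(pp, fit)
    mf <- fit_mediation(sc, work, c("log_abs_drift", "log_gamma"),
                        mean_log_rt, person_id,
                        predictor_level = "occasion", mc_draws = 2000,
                        seed = s)
    expect_gt(mf$indirect$estimate[1], 0)   # via drift: work slows access
    expect_lt(mf$indirect$estimate[2], 0)   # via boundary: work cuts caution
  }
})

test_that("simulation CSVs round-trip and carry the seed header", {
  sim <- generate_dataset(
    synthetic_config(n_persons = 10, days = 1, prompts_per_day = 2),
    seed = 3)
  rp <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(sim, rp, tp)
  expect_match(readLines(rp, n = 1), "seed 3")
  back <- read_ema_long(rp, item_set = sim$truth$items$item_id)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$rt_seconds, sim$records$rt_seconds)
})
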
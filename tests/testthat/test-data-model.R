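test_that("long-format round trip preserves all fields and row order", {
  recs <- make_tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ema_long(recs, path)
  back <- read_ema_long(path, item_set = c("angry", "lonely"))
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("reader rejects malformed files with informative errors", {
  recs <- make_tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")

  write_ema_long(recs[, setdiff(names(recs), "rt_seconds")], path)
  expect_error(read_ema_long(path, c("angry", "lonely")),
               "rt_seconds", class = "emadiff_schema_error")

  bad <- recs
  bad$rt_seconds <- as.character(bad$rt_seconds)
  bad$rt_seconds[2] <- "abc"
  write_ema_long(bad, path)
  expect_error(read_ema_long(path, c("angry", "lonely")),
               "row\\(s\\) 2", class = "emadiff_parse_error")

  write_ema_long(recs, path)
  expect_error(read_ema_long(path, c("angry")), "lonely",
               class = "emadiff_schema_error")
})

test_that("midpoint dichotomization splits 49/50 and is monotone", {
  expect_identical(dichotomize_rating(c(0, 49, 50, 100)), c(0L, 0L, 1L, 1L))
  expect_true(all(diff(dichotomize_rating(0:100)) >= 0))
  expect_error(dichotomize_rating(101), class = "emadiff_domain_error")
  expect_error(dichotomize_rating(-1), class = "emadiff_domain_error")
})

test_that("RT cap removes strictly-greater records and is idempotent", {
  recs <- make_tiny_records()
  recs$rt_seconds <- c(31, 30, 2)
  out <- apply_rt_filter(recs, cap = 30)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(out$rt_seconds, c(30, 2))
  again <- apply_rt_filter(out, cap = 30)
  expect_equal(attr(again, "n_removed"), 0L)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)

  all_ok <- apply_rt_filter(make_tiny_records(), cap = 30)
  expect_equal(as.data.frame(all_ok), as.data.frame(make_tiny_records()),
               ignore_attr = TRUE)
})

test_that("occasions without RT variation or enough items are dropped", {
  recs <- tibble::tibble(
    person_id = rep(c("A", "B", "C"), each = 5),
    occasion_id = 1L,
    item_id = rep(paste0("i", 1:5), 3),
    response = 0L,
    rt_seconds = c(rep(3, 5),            # invariant -> dropped
                   c(3, 3, 3, 3, 4),     # varies -> kept
                   c(2, 4, 3, 5, 6))     # varies -> kept
  )
  out <- drop_invariant_rt_occasions(recs)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(attr(out, "n_invariant"), 1L)
  expect_setequal(unique(out$person_id), c("B", "C"))

  empty <- drop_invariant_rt_occasions(recs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_removed"), 0L)

  single <- recs[recs$person_id == "B", ][1, ]
  out2 <- drop_invariant_rt_occasions(single, min_items = 2)
  expect_equal(attr(out2, "n_too_few"), 1L)
  expect_equal(nrow(out2), 0L)
})

test_that("forcing a fraction of invariant occasions is reported by the filter", {
  cfg <- synthetic_config(n_persons = 150, days = 3, prompts_per_day = 4,
                          completion_rate = 1, integer_rounding = FALSE,
                          invariant_frac = 0.03)
  sim <- generate_dataset(cfg, seed = 42)
  pp <- preprocess_ema(sim$records, cfg$items$affect$item_id, rt_cap = Inf)
  frac <- pp$counts$n_invariant / pp$counts$n_input_occasions
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.045)
})

test_that("activity checklists code work and recovery independently", {
  out <- code_activities(c("work;eating", "leisure", "chores;drinking",
                           "work;on the telephone"))
  expect_equal(out$work, c(1L, 0L, 0L, 1L))
  expect_equal(out$recovery, c(0L, 1L, 0L, 1L))
  expect_error(code_activities("napping"), "napping",
               class = "emadiff_vocabulary_error")
})

test_that("mean log RT uses natural logs and capped items are excluded", {
  expect_equal(occasion_mean_log_rt(rep(exp(1), 4)), 1)
  expect_equal(occasion_mean_log_rt(numeric(0)), NA_real_)
  # natural-log convention reproduces the usual back-transforms
  expect_equal(exp(1.86), 6.42, tolerance = 2e-3)
  expect_equal(exp(1.40), 4.06, tolerance = 2e-3)

  recs <- tibble::tibble(
    person_id = "A", occasion_id = 1L,
    item_id = paste0("i", 1:3), rating = c(0, 0, 0),
    rt_seconds = c(2, 40, 2.5)
  )
  pp <- preprocess_ema(recs, paste0("i", 1:3), rt_cap = 30)
  expect_equal(pp$occasions$mean_log_rt, mean(log(c(2, 2.5))))
})

test_that("preprocessing accounting is internally consistent", {
  cfg <- synthetic_config(n_persons = 40, days = 2, prompts_per_day = 3)
  sim <- generate_dataset(cfg, seed = 5)
  pp <- preprocess_ema(sim$records, cfg$items$affect$item_id)
  expect_equal(pp$counts$n_retained_occasions,
               pp$counts$n_input_occasions - pp$counts$n_occasions_removed)
  expect_true(all(pp$items$rt_seconds <= 30))
  expect_true(all(pp$occasions$n_items >= 2))
  expect_true(all(c("work", "recovery") %in% names(pp$occasions)))
})
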
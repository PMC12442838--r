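#' Configuration of the synthetic EMA generator
#'
#' Builds the generative configuration the simulator draws from. The defaults
#' emulate a one-week EMA burst study in a large adult panel: 954 persons
#' prompted up to 6 times daily for 7 days with ~75% completion, 5 binary
#' "affect" items (dichotomized 0-100 ratings) plus 3 binary "event" items,
#' integer-second response times, between/within variance components giving
#' test-retest ICCs near 0.31 (drift) and 0.39 (boundary), momentary work and
#' recovery activities shifting drift and boundary in opposite directions,
#' person-level neuroticism/depression loadings on the person means, and
#' negative-exponential practice trends (drift rising, boundary falling, each
#' about three quarters of a standard deviation).
#'
#' Effect sizes are expressed in SD units: activity effects and practice
#' gains relative to each parameter's total (between + within) SD, covariate
#' loadings relative to the between-person SD. Drift-side effects (`theta`
#' components) are stated on the drift-rate axis, i.e. the absolute deviation
#' `|theta - v|` the scoring pipeline reports; because endorsement is a
#' minority phenomenon under the default difficulties, the generator maps a
#' drift-rate decrease to an increase in signed `theta` (and vice versa).
#'
#' @param n_persons,days,prompts_per_day Study design (default 954 x 7 x 6).
#' @param completion_rate Probability a scheduled prompt is completed.
#' @param items Named list of item tables (`item_id`, `v`, `a`, `binary`).
#' @param sd_theta_between,sd_theta_within SDs of person-mean drift and
#'   occasion drift deviations.
#' @param sd_lgamma_between,sd_lgamma_within Same for log boundary.
#' @param mean_lgamma Population mean of log boundary; sets the RT scale
#'   (the default reproduces the study-typical mean log RT of ~1.4 and ~1%
#'   of RTs beyond 30 s).
#' @param ter_range Range of the uniform person nondecision time (seconds).
#' @param p_work,p_recovery Occasion probabilities of work/recovery activity.
#' @param effect_work,effect_recovery Named vectors `c(theta=, lgamma=)` of
#'   activity effects in total-SD units.
#' @param loading_neuroticism,loading_depression Named vectors of covariate
#'   loadings on the person means, in between-SD units.
#' @param covariate_cor Correlation between neuroticism and depression.
#' @param gain_theta_z,gain_lgamma_z Practice gains (change from initial
#'   level to asymptote) in total-SD units.
#' @param trend_rate Rate of the practice trend.
#' @param integer_rounding Round RTs to whole seconds (as momentary survey
#'   software logs them)?
#' @param invariant_frac Fraction of completed occasions whose RTs are forced
#'   constant (to exercise the no-variation filter); default 0.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_persons = 954, days = 7, prompts_per_day = 6, completion_rate = 0.75,
    items = list(
      affect = tibble(
        item_id = c("angry", "dejected", "frustrated", "lonely", "stressed"),
        v = seq(-0.5, 1.5, length.out = 5),
        # time pressure deliberately not aligned with difficulty, so the two
        # item parameters stay separately identifiable
        a = c(1.05, 0.8, 1.25, 0.9, 1.15),
        binary = FALSE),
      events = tibble(
        item_id = c("stress_event", "money_worry", "argument"),
        v = c(0.1, 0.7, 1.3),
        a = c(1.15, 0.85, 1.05),
        binary = TRUE)),
    sd_theta_between = sqrt(0.193), sd_theta_within = sqrt(0.425),
    sd_lgamma_between = sqrt(0.062), sd_lgamma_within = sqrt(0.096),
    mean_lgamma = 1.5,
    ter_range = c(0.5, 2),
    p_work = 0.25, p_recovery = 0.5,
    effect_work = c(theta = -0.254, lgamma = -0.133),
    effect_recovery = c(theta = 0.106, lgamma = 0.075),
    loading_neuroticism = c(theta = -0.317, lgamma = -0.197),
    loading_depression = c(theta = -0.371, lgamma = -0.195),
    covariate_cor = 0.5,
    gain_theta_z = 0.752, gain_lgamma_z = -0.825, trend_rate = 0.2,
    integer_rounding = TRUE, invariant_frac = 0) {
  cfg <- list(
    n_persons = n_persons, days = days, prompts_per_day = prompts_per_day,
    completion_rate = completion_rate, items = items,
    sd_theta_between = sd_theta_between, sd_theta_within = sd_theta_within,
    sd_lgamma_between = sd_lgamma_between, sd_lgamma_within = sd_lgamma_within,
    mean_lgamma = mean_lgamma, ter_range = ter_range,
    p_work = p_work, p_recovery = p_recovery,
    effect_work = effect_work, effect_recovery = effect_recovery,
    loading_neuroticism = loading_neuroticism,
    loading_depression = loading_depression,
    covariate_cor = covariate_cor,
    gain_theta_z = gain_theta_z, gain_lgamma_z = gain_lgamma_z,
    trend_rate = trend_rate, integer_rounding = integer_rounding,
    invariant_frac = invariant_frac)
  sds <- c(sd_theta_between, sd_theta_within, sd_lgamma_between,
           sd_lgamma_within)
  if (any(sds < 0)) abort("Population SDs must be non-negative.")
  if (!(completion_rate > 0 && completion_rate <= 1)) {
    abort("completion_rate must be in (0, 1].")
  }
  for (tab in items) {
    if (any(tab$a <= 0)) {
      abort("Item boundary parameters `a` must be positive (alpha = gamma / a would not be).",
            class = "emadiff_domain_error")
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# person means shifted by correlated covariate loadings, rescaled so the
# total between-person SD stays at its configured value
person_level_draws <- function(n, sd_b, load_n, load_d, rho, covs) {
  expl <- load_n^2 + load_d^2 + 2 * rho * load_n * load_d
  if (expl > 1) {
    abort("Covariate loadings imply more than 100% of between-person variance.")
  }
  sd_b * (load_n * covs$neuroticism + load_d * covs$depression +
            sqrt(1 - expl) * rnorm(n))
}

build_activities <- function(work, recovery) {
  other_pool <- c("chores", "eating", "drinking", "other")
  vapply(seq_along(work), function(i) {
    acts <- character(0)
    if (work[i] == 1) acts <- "work"
    if (recovery[i] == 1) acts <- c(acts, sample(recovery_labels, 1))
    extra <- other_pool[runif(length(other_pool)) < 0.2]
    acts <- c(acts, extra)
    if (length(acts) == 0) acts <- "other"
    paste(acts, collapse = ";")
  }, character(1))
}

#' Generate a synthetic EMA dataset with known ground truth
#'
#' Simulates the full generative structure the analysis pipeline assumes:
#' person-mean drift and log boundary (shifted by correlated
#' neuroticism/depression), occasion deviations, momentary work/recovery
#' shifts, negative-exponential practice trends, and item responses and RTs
#' drawn from the Wiener first-passage process with `mu = theta - v_h`,
#' `alpha = gamma / a_h` plus a person nondecision time. Prompts are missed
#' at random per the completion rate; missed prompts are simply absent rows.
#' Deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (mandatory).
#' @return A list of class `ema_simulation`: `records` (long tibble as read
#'   by [read_ema_long()]), and `truth` with per-occasion latent parameters,
#'   item parameters, person covariates and the config.
#' @export
generate_dataset <- function(config = synthetic_config(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  cfg <- config
  n <- cfg$n_persons
  person_id <- sprintf("P%04d", seq_len(n))
  # correlated person covariates
  zn <- rnorm(n)
  zd <- cfg$covariate_cor * zn + sqrt(1 - cfg$covariate_cor^2) * rnorm(n)
  covs <- tibble(person_id = person_id, neuroticism = zn, depression = zd)
  # Effect sizes on the drift side are specified on the (absolute) drift-rate
  # axis. Endorsement is a minority phenomenon here (person drifts sit below
  # the item difficulties), so a DECREASE in drift rate |theta - v| maps to
  # an INCREASE in signed theta: theta-axis effects enter with flipped sign.
  theta_b <- person_level_draws(n, cfg$sd_theta_between,
                                -cfg$loading_neuroticism["theta"],
                                -cfg$loading_depression["theta"],
                                cfg$covariate_cor, covs)
  lgamma_b <- cfg$mean_lgamma +
    person_level_draws(n, cfg$sd_lgamma_between,
                       cfg$loading_neuroticism["lgamma"],
                       cfg$loading_depression["lgamma"],
                       cfg$covariate_cor, covs)
  ter_p <- runif(n, cfg$ter_range[1], cfg$ter_range[2])

  n_occ <- cfg$days * cfg$prompts_per_day
  occ <- tidyr::expand_grid(pidx = seq_len(n), occasion_id = seq_len(n_occ))
  occ$person_id <- person_id[occ$pidx]
  occ$day <- (occ$occasion_id - 1) %/% cfg$prompts_per_day + 1L
  occ$completed <- rbinom(nrow(occ), 1, cfg$completion_rate) == 1
  occ$work <- rbinom(nrow(occ), 1, cfg$p_work)
  occ$recovery <- rbinom(nrow(occ), 1, cfg$p_recovery)
  sd_theta_tot <- sqrt(cfg$sd_theta_between^2 + cfg$sd_theta_within^2)
  sd_lg_tot <- sqrt(cfg$sd_lgamma_between^2 + cfg$sd_lgamma_within^2)
  occ0 <- occ$occasion_id - 1
  occ$theta <- theta_b[occ$pidx] +
    cfg$sd_theta_within * rnorm(nrow(occ)) -
    sd_theta_tot * (cfg$effect_work["theta"] * occ$work +
                      cfg$effect_recovery["theta"] * occ$recovery) +
    cfg$gain_theta_z * sd_theta_tot * exp(-cfg$trend_rate * occ0)
  occ$lgamma <- lgamma_b[occ$pidx] +
    cfg$sd_lgamma_within * rnorm(nrow(occ)) +
    sd_lg_tot * (cfg$effect_work["lgamma"] * occ$work +
                   cfg$effect_recovery["lgamma"] * occ$recovery) -
    cfg$gain_lgamma_z * sd_lg_tot * exp(-cfg$trend_rate * occ0)
  occ$gamma <- exp(occ$lgamma)
  occ$ter <- ter_p[occ$pidx]
  occ$activities <- build_activities(occ$work, occ$recovery)

  done <- occ[occ$completed, , drop = FALSE]
  item_tab <- dplyr::bind_rows(lapply(names(cfg$items), function(s) {
    tb <- cfg$items[[s]]
    tb$set <- s
    tb
  }))
  rows <- tidyr::expand_grid(ridx = seq_len(nrow(done)),
                             hidx = seq_len(nrow(item_tab)))
  rows$mu <- done$theta[rows$ridx] - item_tab$v[rows$hidx]
  rows$alpha <- done$gamma[rows$ridx] / item_tab$a[rows$hidx]
  draw <- sample_response(nrow(rows), mu = rows$mu, alpha = rows$alpha,
                          ter = done$ter[rows$ridx])
  rt <- draw$t
  if (cfg$integer_rounding) rt <- pmax(1, round(rt))
  if (cfg$invariant_frac > 0) {
    flat <- which(runif(nrow(done)) < cfg$invariant_frac)
    fix <- rows$ridx %in% flat
    first_rt <- tapply(rt[fix], rows$ridx[fix], function(v) v[1])
    rt[fix] <- first_rt[as.character(rows$ridx[fix])]
  }
  binary <- item_tab$binary[rows$hidx]
  rating <- ifelse(binary, draw$x,
                   ifelse(draw$x == 1,
                          sample(50:100, nrow(rows), replace = TRUE),
                          sample(0:49, nrow(rows), replace = TRUE)))
  records <- tibble(
    person_id = done$person_id[rows$ridx],
    occasion_id = done$occasion_id[rows$ridx],
    day = done$day[rows$ridx],
    item_id = item_tab$item_id[rows$hidx],
    rating = rating,
    rt_seconds = rt,
    activities = done$activities[rows$ridx],
    neuroticism = covs$neuroticism[match(done$person_id[rows$ridx],
                                         covs$person_id)],
    depression = covs$depression[match(done$person_id[rows$ridx],
                                       covs$person_id)]
  )
  structure(
    list(
      records = records,
      truth = list(
        occasions = as_tibble(occ[, c("person_id", "occasion_id", "day",
                                      "completed", "work", "recovery",
                                      "theta", "lgamma", "gamma", "ter")]),
        items = as_tibble(item_tab),
        persons = tibble(person_id = person_id, neuroticism = zn,
                         depression = zd, theta_between = theta_b,
                         lgamma_between = lgamma_b, ter = ter_p),
        scheduled = n * n_occ,
        completed = nrow(done),
        config = cfg, seed = seed)),
    class = "ema_simulation"
  )
}

#' @export
print.ema_simulation <- function(x, ...) {
  cat("Synthetic EMA dataset:", length(unique(x$records$person_id)),
      "persons,", x$truth$completed, "completed of", x$truth$scheduled,
      "scheduled occasions,", nrow(x$records), "item records (seed",
      paste0(x$truth$seed, ")\n"))
  invisible(x)
}

#' Generate a dataset with the reference study's shape
#'
#' Convenience preset: 954 persons, 7 days x 6 prompts (40,068 scheduled
#' occasions), 75% completion, 5 affect + 3 event items, default effect
#' sizes.
#'
#' @param seed Integer seed.
#' @return An `ema_simulation` (see [generate_dataset()]).
#' @export
emulate_paper_shape <- function(seed) {
  generate_dataset(synthetic_config(), seed = seed)
}

#' Write a synthetic dataset and its ground truth to CSV
#'
#' Both files carry the seed in a `#` header comment line.
#'
#' @param sim An `ema_simulation`.
#' @param records_path,truth_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_simulation_csv <- function(sim, records_path, truth_path) {
  hdr <- paste0("# emadiff synthetic dataset, seed ", sim$truth$seed)
  writeLines(hdr, records_path)
  suppressWarnings(readr::write_csv(sim$records, records_path, append = TRUE,
                                    col_names = TRUE, progress = FALSE))
  writeLines(hdr, truth_path)
  suppressWarnings(readr::write_csv(sim$truth$occasions, truth_path,
                                    append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(c(records_path, truth_path))
}
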
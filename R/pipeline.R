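#' Run the full EMA response-process analysis pipeline
#'
#' Chains the stages end to end: load (or simulate) long-format EMA records,
#' preprocess per item set, fit the D-diffusion IRT model and score
#' person-occasions per item set, then run the requested analyses -
#' test-retest ICCs, the latent covariate RT regression, cross-item-set
#' correspondence, within- and between-person mediation, and the
#' negative-exponential practice-effect models. Writes scored CSVs, one JSON
#' report per analysis and a run manifest with the filter accounting
#' (`retained = scheduled - missed - filtered` for synthetic runs) when
#' `out_dir` is given. All randomness flows from the single `seed`: each
#' stochastic stage draws from a fixed offset of it, so toggling one analysis
#' never perturbs another's results.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `input` (CSV path) or `synthetic` (`"paper-shape"` or a
#'   [synthetic_config()]); `item_sets` (named list of item-label vectors;
#'   defaults to the synthetic sets); `rt_cap` (30); `min_items` (2);
#'   `n_quad` (15); `kappa` (0.9); `analyses` (subset of `"icc"`,
#'   `"regression"`, `"correspondence"`, `"mediation"`, `"growth"`; default
#'   all; empty vector = preprocess only); `out_dir` (optional); `seed`.
#' @return A list of class `ema_pipeline` with elements `preprocessed`,
#'   `fits`, `scores`, `analyses` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(rt_cap = 30, min_items = 2, n_quad = 15, kappa = 0.6,
                   analyses = c("icc", "regression", "correspondence",
                                "mediation", "growth"),
                   out_dir = NULL, seed = 1)
  config <- utils::modifyList(defaults, config)
  seed <- config$seed
  manifest <- list(seed = seed, stages = list())

  # --- load / simulate ------------------------------------------------------
  if (!is.null(config$input)) {
    if (is.null(config$item_sets)) {
      abort("`item_sets` must be given when reading from a file.")
    }
    records <- read_ema_long(config$input,
                             item_set = unlist(config$item_sets))
    scheduled <- NA_integer_
    completed <- nrow(unique(records[, c("person_id", "occasion_id")]))
  } else if (!is.null(config$synthetic)) {
    scfg <- if (identical(config$synthetic, "paper-shape")) synthetic_config()
            else config$synthetic
    sim <- generate_dataset(scfg, seed = seed)
    records <- sim$records
    scheduled <- sim$truth$scheduled
    completed <- sim$truth$completed
    if (is.null(config$item_sets)) {
      config$item_sets <- lapply(scfg$items, function(tb) tb$item_id)
    }
  } else {
    abort("Config needs either `input` or `synthetic`.",
          class = "emadiff_schema_error")
  }
  manifest$stages$load <- list(
    scheduled_occasions = scheduled, completed_occasions = completed,
    missed_occasions = if (is.na(scheduled)) NA_integer_ else
      scheduled - completed,
    n_records = nrow(records))

  # --- preprocess / fit / score per item set --------------------------------
  prep <- list(); fits <- list(); scores <- list()
  for (set in names(config$item_sets)) {
    pp <- preprocess_ema(records, config$item_sets[[set]],
                         rt_cap = config$rt_cap, min_items = config$min_items)
    prep[[set]] <- pp
    manifest$stages[[paste0("preprocess_", set)]] <- pp$counts
    if (length(config$analyses) == 0) next
    set.seed(seed + 1000)   # estimation substream
    fits[[set]] <- fit_diffusion_irt(pp, n_quad = config$n_quad,
                                     kappa = config$kappa)
    scores[[set]] <- score_occasions(pp, fits[[set]],
                                     min_items = config$min_items)
    manifest$stages[[paste0("fit_", set)]] <- list(
      loglik = fits[[set]]$loglik,
      convergence = fits[[set]]$convergence$code,
      n_rows = fits[[set]]$n_rows)
  }

  analyses <- list()
  primary <- names(config$item_sets)[1]
  sc <- scores[[primary]]

  if ("icc" %in% config$analyses) {
    iccs <- lapply(c(mean_log_rt = "mean_log_rt",
                     log_abs_drift = "log_abs_drift",
                     log_gamma = "log_gamma"),
                   function(v) fit_null_model(sc, !!v, person_id))
    analyses$icc <- iccs
  }
  if ("regression" %in% config$analyses) {
    analyses$regression <- fit_latent_regression(
      sc, mean_log_rt, log_abs_drift, log_gamma, person_id)
  }
  if ("correspondence" %in% config$analyses && length(scores) >= 2) {
    second <- names(config$item_sets)[2]
    merged <- dplyr::inner_join(
      sc[, c("person_id", "occasion_id", "log_abs_drift", "log_gamma")],
      scores[[second]][, c("person_id", "occasion_id", "log_abs_drift",
                           "log_gamma")],
      by = c("person_id", "occasion_id"),
      suffix = c("_a", "_b"))
    corr <- multilevel_correlations(
      merged, c("log_abs_drift_a", "log_gamma_a", "log_abs_drift_b",
                "log_gamma_b"), person_id)
    set.seed(seed + 2000)   # bootstrap substream
    tests <- lapply(c("within", "between"), function(lvl) {
      compare_dependent_correlations(
        corr, c("log_abs_drift_a", "log_abs_drift_b"),
        c("log_abs_drift_a", "log_gamma_a"), level = lvl)
    })
    analyses$correspondence <- list(correlations = corr,
                                    drift_correspondence_tests = tests)
  }
  if ("mediation" %in% config$analyses) {
    med <- list()
    for (pred in intersect(c("work", "recovery"), names(sc))) {
      med[[pred]] <- fit_mediation(
        sc, !!pred, c("log_abs_drift", "log_gamma"), mean_log_rt,
        person_id, predictor_level = "occasion", seed = seed + 3000)
    }
    for (pred in intersect(c("neuroticism", "depression"), names(sc))) {
      med[[pred]] <- fit_mediation(
        sc, !!pred, c("log_abs_drift", "log_gamma"), mean_log_rt,
        person_id, predictor_level = "person", seed = seed + 3000)
    }
    analyses$mediation <- med
  }
  if ("growth" %in% config$analyses) {
    gdat <- sc
    gdat$occ0 <- gdat$occasion_id - 1
    gr <- lapply(c(mean_log_rt = "mean_log_rt",
                   log_abs_drift = "log_abs_drift",
                   log_gamma = "log_gamma"),
                 function(v) fit_negative_exponential(gdat, !!v, person_id,
                                                      occ0))
    gz <- gdat
    gz$drift_z <- zscore(gz$log_abs_drift)
    gz$boundary_z <- zscore(gz$log_gamma)
    cmp <- compare_gains(
      fit_negative_exponential(gz, drift_z, person_id, occ0),
      fit_negative_exponential(gz, boundary_z, person_id, occ0))
    analyses$growth <- list(fits = gr, gain_comparison = cmp)
  }

  # --- manifest accounting --------------------------------------------------
  if (!is.na(scheduled)) {
    filtered <- manifest$stages[[paste0("preprocess_", primary)]]
    manifest$accounting <- list(
      scheduled = scheduled,
      missed = scheduled - completed,
      filtered = completed - filtered$n_retained_occasions,
      retained = filtered$n_retained_occasions,
      identity_holds = (filtered$n_retained_occasions ==
                          scheduled - (scheduled - completed) -
                          (completed - filtered$n_retained_occasions)))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (set in names(scores)) {
      write_scores_csv(scores[[set]],
                       file.path(config$out_dir,
                                 paste0("scores_", set, ".csv")))
      write_diffirt_json(fits[[set]],
                         file.path(config$out_dir, paste0("fit_", set, ".json")),
                         seed = seed)
    }
    for (an in names(analyses)) {
      jsonlite::write_json(serialize_analysis(analyses[[an]]),
                           file.path(config$out_dir, paste0(an, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(list(preprocessed = prep, fits = fits, scores = scores,
                 analyses = analyses, manifest = manifest, config = config),
            class = "ema_pipeline")
}

# flatten fitted objects to plain lists for JSON reports
serialize_analysis <- function(x) {
  if (inherits(x, "icc_fit")) return(as.list(tidy(x) |> tidyr::pivot_wider(
    names_from = "term", values_from = c("estimate", "std.error"))))
  if (inherits(x, "latent_reg_fit")) {
    return(list(paths = tidy(x), fit = as.list(glance(x))))
  }
  if (inherits(x, "mediation_fit")) {
    return(list(paths = tidy(x), indirect = x$indirect,
                total = x$total, c_prime = x$cprime, level = x$level))
  }
  if (inherits(x, "growth_fit")) return(as.list(glance(x)))
  if (inherits(x, "mlcorr_fit")) return(list(pairs = tidy(x)))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, serialize_analysis))
  x
}

#' @export
print.ema_pipeline <- function(x, ...) {
  cat("EMA diffusion pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  item sets:", paste(names(x$config$item_sets), collapse = ", "), "\n")
  cat("  analyses:", if (length(x$analyses)) paste(names(x$analyses),
                                                   collapse = ", ")
      else "(preprocess only)", "\n")
  if (!is.null(x$manifest$accounting)) {
    a <- x$manifest$accounting
    cat(sprintf("  occasions: %d scheduled - %d missed - %d filtered = %d retained\n",
                a$scheduled, a$missed, a$filtered, a$retained))
  }
  invisible(x)
}
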
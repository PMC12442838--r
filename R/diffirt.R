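# Gauss-Hermite quadrature for a standard normal latent variable
gauss_hermite_normal <- function(n) {
  q <- statmod::gauss.quad.prob(n, dist = "normal", mu = 0, sigma = 1)
  list(nodes = q$nodes, weights = q$weights)
}

# Build response/decision-time matrices (rows = person-occasions, columns =
# items) plus profiled per-row nondecision times ter = kappa * min retained RT
build_diffirt_matrices <- function(items, item_set, kappa) {
  keys <- unique(items[, c("person_id", "occasion_id")])
  keys$row <- seq_len(nrow(keys))
  items <- dplyr::left_join(items, keys, by = c("person_id", "occasion_id"))
  hcol <- match(items$item_id, item_set)
  N <- nrow(keys)
  H <- length(item_set)
  X <- matrix(NA_integer_, N, H)
  RT <- matrix(NA_real_, N, H)
  X[cbind(items$row, hcol)] <- as.integer(items$response)
  RT[cbind(items$row, hcol)] <- items$rt_seconds
  ter <- kappa * apply(RT, 1, min, na.rm = TRUE)
  TD <- RT - ter
  list(X = X, TD = TD, RT = RT, ter = ter, keys = keys[, c("person_id", "occasion_id")])
}

#' Fit the D-diffusion IRT model by marginal maximum likelihood
#'
#' Estimates item drift difficulties `v_h`, item boundary ("time pressure")
#' parameters `a_h` and the population variances of the person drift `theta`
#' and log person boundary `log gamma` from binary responses and response
#' times, treating each person-occasion row as an exchangeable unit. The
#' per-occasion diffusion parameters are `mu = theta - v_h` and
#' `alpha = gamma / a_h`; the marginal likelihood integrates the joint Wiener
#' first-passage density over independent normal distributions of `theta` and
#' `log gamma` (population means fixed at 0 for identification) using a
#' tensor Gauss-Hermite grid. Nondecision time is profiled per row as
#' `kappa` times the row's smallest retained RT.
#'
#' @param data An `ema_preprocessed` object or an item-level tibble with
#'   columns `person_id`, `occasion_id`, `item_id`, `response` (0/1) and
#'   `rt_seconds`.
#' @param item_set Item labels defining the column order; defaults to the
#'   items present (preprocessed input carries its own).
#' @param n_quad Gauss-Hermite nodes per latent dimension (default 15).
#' @param kappa Fraction of the row-minimum RT used as nondecision time
#'   (default 0.6). Values much above 0.7 start consuming genuine decision
#'   time of the row's fastest item and bias the item boundary parameters;
#'   the marginal likelihood is nearly flat over 0.5-0.7.
#' @param max_iter Maximum BFGS iterations (default 300).
#' @return An object of class `diffirt_fit` with item parameters, population
#'   SDs, log-likelihood and convergence information. Supports [tidy()],
#'   [glance()] and [score_occasions()].
#' @export
fit_diffusion_irt <- function(data, item_set = NULL, n_quad = 15, kappa = 0.6,
                              max_iter = 300) {
  if (inherits(data, "ema_preprocessed")) {
    if (is.null(item_set)) item_set <- data$item_set
    items <- data$items
  } else {
    items <- data
    if (is.null(item_set)) item_set <- sort(unique(items$item_id))
  }
  item_set <- intersect(item_set, unique(items$item_id))
  if (length(item_set) < 3) {
    abort("At least 3 items are required to fit the D-diffusion model.",
          class = "emadiff_precondition_error")
  }
  if (!all(items$response %in% c(0L, 1L))) {
    abort("`response` must be binary 0/1.", class = "emadiff_precondition_error")
  }
  mats <- build_diffirt_matrices(items, item_set, kappa)
  N <- nrow(mats$X)
  if (N < 50) {
    warn(paste0("Only ", N, " person-occasion rows; item parameter estimates",
                " may be unstable (>= 50 recommended)."))
  }
  degenerate <- character(0)
  phat <- colMeans(mats$X, na.rm = TRUE)
  for (h in seq_along(item_set)) {
    if (phat[h] %in% c(0, 1)) {
      degenerate <- c(degenerate, item_set[h])
      warn(paste0("Item '", item_set[h], "' has all-identical responses; its",
                  " difficulty estimate sits at a boundary."))
    }
  }
  gh <- gauss_hermite_normal(n_quad)
  H <- length(item_set)
  # starting values: difficulty from endorsement rates under a provisional
  # boundary, unit time pressure, unit/0.4 population SDs
  v0 <- -qlogis(pmin(pmax(phat, 0.02), 0.98)) / 1.5
  par0 <- c(v0, rep(0, H), 0, log(0.4))
  nll <- function(par) {
    .diffirt_nll_cpp(mats$X, mats$TD, par[1:H], exp(par[(H + 1):(2 * H)]),
                     exp(par[2 * H + 1]), exp(par[2 * H + 2]),
                     gh$nodes, gh$weights)
  }
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-10))
  if (opt$convergence != 0) {
    warn(paste0("BFGS did not report clean convergence (code ",
                opt$convergence, "); inspect the fit."))
  }
  # numerical gradient norm at the solution
  eps <- 1e-5
  gr <- vapply(seq_along(opt$par), function(j) {
    pp <- pm <- opt$par
    pp[j] <- pp[j] + eps
    pm[j] <- pm[j] - eps
    (nll(pp) - nll(pm)) / (2 * eps)
  }, numeric(1))
  structure(
    list(
      item_params = tibble(item_id = item_set, v = opt$par[1:H],
                           a = exp(opt$par[(H + 1):(2 * H)])),
      sd_theta = exp(opt$par[2 * H + 1]),
      sd_log_gamma = exp(opt$par[2 * H + 2]),
      loglik = -opt$value,
      n_rows = N,
      n_items = H,
      convergence = list(code = opt$convergence, counts = opt$counts,
                         gradient_norm = sqrt(sum(gr^2)),
                         degenerate_items = degenerate),
      n_quad = n_quad,
      kappa = kappa,
      par = opt$par
    ),
    class = "diffirt_fit"
  )
}

#' @export
print.diffirt_fit <- function(x, ...) {
  cat("D-diffusion IRT fit:", x$n_items, "items,", x$n_rows,
      "person-occasion rows\n")
  cat(sprintf("  log-likelihood %.2f | sd(theta) = %.3f, sd(log gamma) = %.3f\n",
              x$loglik, x$sd_theta, x$sd_log_gamma))
  print(x$item_params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.diffirt_fit <- function(x, ...) x$item_params

#' @exportS3Method generics::glance
glance.diffirt_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sd_theta = x$sd_theta,
         sd_log_gamma = x$sd_log_gamma, n_rows = x$n_rows,
         n_items = x$n_items, n_quad = x$n_quad, kappa = x$kappa,
         convergence = x$convergence$code,
         gradient_norm = x$convergence$gradient_norm)
}

#' Serialize a diffusion IRT fit to JSON
#'
#' @param fit A `diffirt_fit`.
#' @param path Output path.
#' @param seed Optional seed to record alongside the estimates.
#' @return `path`, invisibly.
#' @export
write_diffirt_json <- function(fit, path, seed = NULL) {
  jsonlite::write_json(
    list(item_params = fit$item_params,
         population = list(sd_theta = fit$sd_theta,
                           sd_log_gamma = fit$sd_log_gamma),
         loglik = fit$loglik, convergence = fit$convergence,
         n_quad = fit$n_quad, kappa = fit$kappa, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score person-occasions under a fitted D-diffusion model
#'
#' Computes expected a-posteriori (EAP) estimates of the person drift `theta`
#' and log boundary `log gamma` for every person-occasion row, given the
#' fitted item parameters and population distributions, then derives the
#' score variables used downstream: the absolute drift
#' `abs_drift = mean_h |theta - v_h|` (speed of information access regardless
#' of response direction), its natural log, the log boundary score, and the
#' occasion's mean log RT. Boundary scores more than `outlier_iqr`
#' interquartile ranges below the median log gamma are set missing
#' (`flag = "boundary_outlier"`).
#'
#' @param data The `ema_preprocessed` object or item-level tibble the model
#'   applies to (need not be the fitting data).
#' @param fit A `diffirt_fit`.
#' @param min_items Rows with fewer retained items score `NA` (default 2).
#' @param outlier_iqr IQR multiplier of the low-boundary outlier rule
#'   (default 5; `Inf` disables it).
#' @return A tibble with one row per person-occasion: `theta`, `gamma`,
#'   `ter`, `abs_drift`, `log_abs_drift`, `log_gamma`, `mean_log_rt`,
#'   `n_items`, `flag`.
#' @export
score_occasions <- function(data, fit, min_items = 2, outlier_iqr = 5) {
  if (inherits(data, "ema_preprocessed")) {
    items <- data$items
    occasions <- data$occasions
  } else {
    items <- data
    occasions <- NULL
  }
  item_set <- fit$item_params$item_id
  items <- items[items$item_id %in% item_set, , drop = FALSE]
  mats <- build_diffirt_matrices(items, item_set, fit$kappa)
  gh <- gauss_hermite_normal(fit$n_quad)
  eap <- .diffirt_eap_cpp(mats$X, mats$TD, fit$item_params$v,
                          fit$item_params$a, fit$sd_theta, fit$sd_log_gamma,
                          gh$nodes, gh$weights)
  n_items_row <- rowSums(!is.na(mats$X))
  theta <- eap[, 1]
  log_gamma <- eap[, 2]
  too_few <- n_items_row < min_items
  theta[too_few] <- NA_real_
  log_gamma[too_few] <- NA_real_
  abs_drift <- vapply(theta, function(th) {
    if (is.na(th)) NA_real_ else mean(abs(th - fit$item_params$v))
  }, numeric(1))
  out <- mats$keys
  out$theta <- theta
  out$gamma <- exp(log_gamma)
  out$ter <- mats$ter
  out$abs_drift <- abs_drift
  out$log_abs_drift <- ifelse(abs_drift > 0, log(abs_drift), NA_real_)
  out$log_gamma <- log_gamma
  out$mean_log_rt <- apply(mats$RT, 1, occasion_mean_log_rt)
  out$n_items <- n_items_row
  out$flag <- ifelse(too_few, "too_few_items", "ok")
  if (is.finite(outlier_iqr)) {
    med <- median(out$log_gamma, na.rm = TRUE)
    iqr <- stats::IQR(out$log_gamma, na.rm = TRUE)
    low <- !is.na(out$log_gamma) & out$log_gamma < med - outlier_iqr * iqr
    out$gamma[low] <- NA_real_
    out$log_gamma[low] <- NA_real_
    out$flag[low] <- "boundary_outlier"
  }
  if (!is.null(occasions)) {
    meta_cols <- setdiff(names(occasions),
                         c(names(mats$keys), "n_items", "mean_log_rt"))
    out <- dplyr::left_join(
      out, occasions[, c("person_id", "occasion_id", meta_cols)],
      by = c("person_id", "occasion_id"))
  }
  as_tibble(out)
}

#' Observed versus model-implied response-time quantiles
#'
#' For each item, pairs the observed RT quantiles with quantiles simulated
#' from the fitted model at matched sample size, using each row's EAP person
#' parameters and profiled nondecision time. Points on the identity line
#' indicate that the diffusion model reproduces the RT distribution.
#'
#' @param data The `ema_preprocessed` object or item-level tibble.
#' @param fit A `diffirt_fit`.
#' @param probs Quantile levels (default percentiles 1-99).
#' @param scores Optional precomputed occasion scores (from
#'   [score_occasions()]) supplying the per-row posterior-mean parameters and
#'   nondecision times; by default they are computed from `data`. Passing the
#'   fit-time scores makes the diagnostic sensitive to shifts in `data` that
#'   per-row re-profiling would otherwise absorb.
#' @return A tibble of class `diffirt_qq` with columns `item_id`, `prob`,
#'   `observed`, `model`.
#' @export
qq_diagnostic <- function(data, fit, probs = (1:99) / 100, scores = NULL) {
  items <- if (inherits(data, "ema_preprocessed")) data$items else data
  item_set <- fit$item_params$item_id
  items <- items[items$item_id %in% item_set, , drop = FALSE]
  if (is.null(scores)) scores <- score_occasions(data, fit, outlier_iqr = Inf)
  dat <- dplyr::left_join(
    items,
    scores[, c("person_id", "occasion_id", "theta", "gamma", "ter")],
    by = c("person_id", "occasion_id"))
  dat <- dat[!is.na(dat$theta) & !is.na(dat$gamma), , drop = FALSE]
  h <- match(dat$item_id, item_set)
  mu <- dat$theta - fit$item_params$v[h]
  alpha <- dat$gamma / fit$item_params$a[h]
  sim <- sample_response(nrow(dat), mu = mu, alpha = alpha, ter = dat$ter)
  out <- purrr::map_dfr(seq_along(item_set), function(j) {
    sel <- h == j
    tibble(item_id = item_set[j], prob = probs,
           observed = as.numeric(quantile(dat$rt_seconds[sel], probs)),
           model = as.numeric(quantile(sim$t[sel], probs)))
  })
  class(out) <- c("diffirt_qq", class(out))
  out
}

# ---- tetrachoric correlations and the one-factor diagnostic ----------------

# pairwise tetrachoric correlation by two-step ML: thresholds from the
# margins, rho by maximizing the 2x2 multinomial likelihood under a bivariate
# normal with those thresholds
tetrachoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  if ((n10 + n01) == 0) return(1)
  if ((n11 + n00) == 0) return(-1)
  th1 <- qnorm(1 - mean(x)); th2 <- qnorm(1 - mean(y))
  negll <- function(rho) {
    s <- matrix(c(1, rho, rho, 1), 2)
    p11 <- mvtnorm::pmvnorm(lower = c(th1, th2), upper = c(Inf, Inf), sigma = s)
    p1x <- 1 - pnorm(th1); px1 <- 1 - pnorm(th2)
    p10 <- pmax(p1x - p11, 1e-12); p01 <- pmax(px1 - p11, 1e-12)
    p00 <- pmax(1 - p11 - p10 - p01, 1e-12)
    -(n11 * log(pmax(p11, 1e-12)) + n10 * log(p10) + n01 * log(p01) +
        n00 * log(p00))
  }
  optimize(negll, c(-0.999, 0.999))$minimum
}

#' Tetrachoric correlation matrix of binary items
#'
#' @param x A 0/1 matrix or item-level tibble (`person_id`, `occasion_id`,
#'   `item_id`, `response`) to be pivoted to wide format.
#' @return A symmetric correlation matrix.
#' @export
tetrachoric_matrix <- function(x) {
  if (!is.matrix(x)) {
    wide <- tidyr::pivot_wider(x[, c("person_id", "occasion_id", "item_id",
                                     "response")],
                               names_from = "item_id",
                               values_from = "response")
    x <- as.matrix(wide[, setdiff(names(wide), c("person_id", "occasion_id"))])
  }
  H <- ncol(x)
  R <- diag(1, H)
  dimnames(R) <- list(colnames(x), colnames(x))
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      R[i, j] <- R[j, i] <- tetrachoric_pair(x[, i], x[, j])
    }
  }
  R
}

#' One-factor diagnostic of essential unidimensionality
#'
#' Computes the tetrachoric correlation matrix of the binary item responses
#' and summarizes its first principal factor: the first/second eigenvalue
#' ratio and the first-factor loadings. A large ratio (conventionally > 3)
#' supports treating the items as indicators of a single dimension, the key
#' measurement assumption of the diffusion IRT model. Advisory output only;
#' it gates nothing.
#'
#' @inheritParams tetrachoric_matrix
#' @return A list of class `unidim_check`: `eigenvalues`, `ratio`,
#'   `loadings`, `tetrachoric`, `excluded` (items with a single observed
#'   category, dropped with a warning).
#' @export
check_unidimensionality <- function(x) {
  if (!is.matrix(x)) {
    wide <- tidyr::pivot_wider(x[, c("person_id", "occasion_id", "item_id",
                                     "response")],
                               names_from = "item_id",
                               values_from = "response")
    x <- as.matrix(wide[, setdiff(names(wide), c("person_id", "occasion_id"))])
  }
  single <- vapply(seq_len(ncol(x)), function(j) {
    length(unique(na.omit(x[, j]))) < 2
  }, logical(1))
  excluded <- colnames(x)[single]
  if (length(excluded) > 0) {
    warn(paste0("Item(s) with a single observed category excluded: ",
                paste(excluded, collapse = ", ")))
    x <- x[, !single, drop = FALSE]
  }
  if (ncol(x) < 3) {
    abort("At least 3 two-category items are required.",
          class = "emadiff_precondition_error")
  }
  R <- tetrachoric_matrix(x)
  ev <- eigen(R, symmetric = TRUE)
  loadings <- sqrt(max(ev$values[1], 0)) * ev$vectors[, 1]
  if (sum(loadings) < 0) loadings <- -loadings
  structure(
    list(eigenvalues = ev$values, ratio = ev$values[1] / ev$values[2],
         loadings = setNames(loadings, colnames(R)), tetrachoric = R,
         excluded = excluded),
    class = "unidim_check"
  )
}

#' @export
print.unidim_check <- function(x, ...) {
  cat("One-factor diagnostic (tetrachoric):\n")
  cat(sprintf("  eigenvalue ratio lambda1/lambda2 = %.2f\n", x$ratio))
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.unidim_check <- function(x, ...) {
  tibble(item_id = names(x$loadings), loading = as.numeric(x$loadings))
}
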
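# ---- two-level multivariate normal ML (the latent covariate engine) --------
#
# Model: y_ij = mu + u_j + r_ij with u_j ~ N(0, Sigma_b), r_ij ~ N(0, Sigma_w)
# (Sigma_w rows/cols are structurally zero for person-level variables). The
# likelihood factorizes into the pooled within-cluster scatter against Sigma_w
# and the cluster means against V_n = Sigma_b + Sigma_w / n, so one evaluation
# costs O(#distinct cluster sizes) small-matrix operations whatever N is.

lower_tri_n <- function(p) p * (p + 1) / 2

par_to_chol <- function(par, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L
}

chol_to_par <- function(Sigma) {
  p <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-6 * max(ev$values, 1e-6))
  S <- ev$vectors %*% diag(vals, p) %*% t(ev$vectors)
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# per-cluster sufficient statistics
twolevel_stats <- function(Y, g) {
  g <- factor(g)
  n_j <- as.numeric(table(g))
  M <- rowsum(Y, g) / n_j
  S_w <- crossprod(Y) - crossprod(sqrt(n_j) * M)
  # per-cluster scatters, stored flat for bootstrap reuse
  p <- ncol(Y)
  Yc <- Y - M[as.integer(g), , drop = FALSE]
  S_flat <- rowsum(do.call(cbind, lapply(seq_len(p), function(i)
    Yc[, i] * Yc)), g)
  list(M = M, n_j = n_j, S_w = (S_w + t(S_w)) / 2, S_flat = S_flat,
       N = nrow(Y), J = length(n_j), p = p)
}

# MANOVA-type moment estimator (starting values; bootstrap workhorse)
twolevel_moment <- function(stats) {
  with(stats, {
    Sw <- S_w / max(N - J, 1)
    ybar <- colSums(M * n_j) / N
    Mc <- sweep(M, 2, ybar)
    B <- crossprod(sqrt(n_j) * Mc) / max(J - 1, 1)
    n0 <- (N - sum(n_j^2) / N) / max(J - 1, 1)
    Sb <- (B - Sw) / n0
    list(Sigma_w = Sw, Sigma_b = (Sb + t(Sb)) / 2, mu = ybar)
  })
}

#' Fit a two-level multivariate normal model by maximum likelihood
#'
#' Decomposes a set of occasion-level variables into latent between-person and
#' within-person components, estimating the level-specific covariance matrices
#' `Sigma_b` and `Sigma_w` by (RE)ML with unbalanced cluster sizes. This is
#' the computational core of the latent covariate approach: between-person
#' regressions read off `Sigma_b` are free of the bias incurred by treating
#' manifest person means as error-free predictors. Person-level variables
#' (constant within person) are declared via `between_only` and contribute no
#' within-person variance.
#'
#' @param data A data frame with one row per person-occasion.
#' @param vars Character vector of variable names to decompose.
#' @param group Name of the person (cluster) identifier column.
#' @param between_only Subset of `vars` that are person-constant.
#' @param method `"ML"` (default) or `"REML"`.
#' @return An object of class `twolevel_mvn` with elements `mu`, `Sigma_w`,
#'   `Sigma_b`, `loglik`, cluster statistics and the objective (for standard
#'   errors via the observed information).
#' @export
fit_twolevel_mvn <- function(data, vars, group, between_only = character(0),
                             method = c("ML", "REML")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(data[, c(vars, group)])
  data <- data[keep, , drop = FALSE]
  Y <- as.matrix(data[, vars, drop = FALSE])
  storage.mode(Y) <- "double"
  st <- twolevel_stats(Y, data[[group]])
  p <- st$p
  widx <- which(!(vars %in% between_only))
  pw <- length(widx)
  if (st$J < 2) abort("At least 2 persons are required.")
  if (max(st$n_j) < 2 && pw > 0) {
    abort("Every person has a single occasion; within- and between-person variance are not separable.",
          class = "emadiff_precondition_error")
  }
  sizes <- sort(unique(st$n_j))
  by_size <- lapply(sizes, function(n) {
    idx <- which(st$n_j == n)
    list(n = n, count = length(idx),
         sum_m = colSums(st$M[idx, , drop = FALSE]),
         cross_m = crossprod(st$M[idx, , drop = FALSE]))
  })
  S_ww <- st$S_w[widx, widx, drop = FALSE]
  nw <- lower_tri_n(pw)
  nb <- lower_tri_n(p)
  mom <- twolevel_moment(st)
  par0 <- c(if (pw > 0) chol_to_par(mom$Sigma_w[widx, widx, drop = FALSE]),
            chol_to_par(mom$Sigma_b))
  ldet <- function(S) determinant(S, logarithm = TRUE)$modulus[1]

  nll <- function(par) {
    Sw_full <- matrix(0, p, p)
    if (pw > 0) {
      Lw <- par_to_chol(par[seq_len(nw)], pw)
      Sw_full[widx, widx] <- tcrossprod(Lw)
    }
    Lb <- par_to_chol(par[nw + seq_len(nb)], p)
    Sb <- tcrossprod(Lb)
    ll <- 0
    if (pw > 0) {
      Sww <- Sw_full[widx, widx, drop = FALSE]
      iSww <- tryCatch(solve(Sww), error = function(e) NULL)
      if (is.null(iSww)) return(1e10)
      ll <- ll - 0.5 * ((st$N - st$J) * ldet(Sww) + sum(iSww * S_ww))
    }
    Vinv <- vector("list", length(by_size))
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (k in seq_along(by_size)) {
      V <- Sb + Sw_full / by_size[[k]]$n
      iV <- tryCatch(solve(V), error = function(e) NULL)
      if (is.null(iV)) return(1e10)
      Vinv[[k]] <- list(iV = iV, ld = ldet(V))
      A <- A + by_size[[k]]$count * iV
      bvec <- bvec + iV %*% by_size[[k]]$sum_m
    }
    mu <- tryCatch(as.numeric(solve(A, bvec)), error = function(e) NULL)
    if (is.null(mu)) return(1e10)
    for (k in seq_along(by_size)) {
      bs <- by_size[[k]]
      Cmu <- bs$cross_m - outer(bs$sum_m, mu) - outer(mu, bs$sum_m) +
        bs$count * outer(mu, mu)
      ll <- ll - 0.5 * (bs$count * Vinv[[k]]$ld + sum(Vinv[[k]]$iV * Cmu))
    }
    if (method == "REML") ll <- ll - 0.5 * ldet(A)
    ll <- ll - 0.5 * log(2 * pi) * ((st$N - st$J) * pw + st$J * p)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  Sw_full <- matrix(0, p, p, dimnames = list(vars, vars))
  if (pw > 0) {
    Lw <- par_to_chol(opt$par[seq_len(nw)], pw)
    Sw_full[widx, widx] <- tcrossprod(Lw)
  }
  Sb <- tcrossprod(par_to_chol(opt$par[nw + seq_len(nb)], p))
  dimnames(Sb) <- list(vars, vars)
  # profiled GLS mean at the solution
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  for (k in seq_along(by_size)) {
    iV <- solve(Sb + Sw_full / by_size[[k]]$n)
    A <- A + by_size[[k]]$count * iV
    bvec <- bvec + iV %*% by_size[[k]]$sum_m
  }
  mu <- setNames(as.numeric(solve(A, bvec)), vars)
  structure(
    list(mu = mu, Sigma_w = Sw_full, Sigma_b = Sb, loglik = -opt$value,
         par = opt$par, nll = nll, vars = vars, between_only = between_only,
         widx = widx, method = method, stats = st,
         convergence = opt$convergence, n_persons = st$J, n_obs = st$N),
    class = "twolevel_mvn"
  )
}

#' @export
print.twolevel_mvn <- function(x, ...) {
  cat("Two-level multivariate normal fit (", x$method, "): ",
      x$n_obs, " occasions in ", x$n_persons, " persons\n", sep = "")
  cat("Between-person covariance:\n"); print(round(x$Sigma_b, 4))
  cat("Within-person covariance:\n"); print(round(x$Sigma_w, 4))
  invisible(x)
}

# ---- null model / ICC ------------------------------------------------------

#' Intraclass correlation from variance components
#'
#' `icc = tau2 / (tau2 + sigma2)`: the share of total variance due to stable
#' between-person differences, i.e. the expected correlation between any two
#' randomly chosen occasions of the same person (test-retest stability).
#'
#' @param tau2 Between-person variance (>= 0).
#' @param sigma2 Within-person variance (>= 0).
#' @return The exact ratio.
#' @examples
#' icc(0.058, 0.084) # 0.408
#' @export
icc <- function(tau2, sigma2) {
  if (any(tau2 < 0) || any(sigma2 < 0)) {
    abort("Variance components must be non-negative.",
          class = "emadiff_domain_error")
  }
  if (any(tau2 + sigma2 <= 0)) {
    abort("tau2 + sigma2 must be positive.", class = "emadiff_domain_error")
  }
  tau2 / (tau2 + sigma2)
}

#' Fit a multilevel null model and its intraclass correlation
#'
#' Estimates the unconditional two-level model
#' `y_ij = delta + u_j + e_ij`, `u_j ~ N(0, tau2)`, `e_ij ~ N(0, sigma2)`,
#' and reports the intraclass correlation `tau2 / (tau2 + sigma2)` as a
#' test-retest stability measure. Standard errors come from the observed
#' information with the delta method.
#'
#' @param data A data frame with one row per person-occasion.
#' @param value Name of the score column (string or bare name).
#' @param person Name of the person identifier column.
#' @param method `"ML"` (default) or `"REML"`; on balanced data REML equals
#'   the one-way ANOVA closed forms.
#' @return An object of class `icc_fit` with `delta`, `tau2`, `sigma2`,
#'   `icc` and their standard errors. Supports [tidy()] and [glance()].
#' @export
fit_null_model <- function(data, value, person, method = c("ML", "REML")) {
  method <- match.arg(method)
  value <- rlang::as_name(rlang::ensym(value))
  person <- rlang::as_name(rlang::ensym(person))
  fit <- fit_twolevel_mvn(data, value, person, method = method)
  tau2 <- fit$Sigma_b[1, 1]
  sigma2 <- fit$Sigma_w[1, 1]
  # observed-information SEs in the log-sd parameterization, delta method to
  # the variance/ICC scale
  H <- optimHess(fit$par, fit$nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  grad_tau2 <- c(0, 2 * tau2)
  grad_sigma2 <- c(2 * sigma2, 0)
  tot <- tau2 + sigma2
  grad_icc <- c(-2 * sigma2 * tau2 / tot^2, 2 * tau2 * sigma2 / tot^2)
  se <- function(g) sqrt(pmax(drop(t(g) %*% V %*% g), 0))
  se_delta <- sqrt(1 / sum(fit$stats$n_j / (sigma2 + fit$stats$n_j * tau2)))
  structure(
    list(delta = unname(fit$mu), tau2 = tau2, sigma2 = sigma2,
         icc = icc(tau2, sigma2),
         se = list(delta = se_delta, tau2 = se(grad_tau2),
                   sigma2 = se(grad_sigma2), icc = se(grad_icc)),
         loglik = fit$loglik, method = method, n_persons = fit$n_persons,
         n_obs = fit$n_obs, variable = value),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "Multilevel null model for '%s' (%s): delta = %.3f, tau2 = %.3f, sigma2 = %.3f\n",
    x$variable, x$method, x$delta, x$tau2, x$sigma2))
  cat(sprintf("  ICC = %.3f (SE %.3f), %d persons, %d occasions\n",
              x$icc, x$se$icc, x$n_persons, x$n_obs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.icc_fit <- function(x, ...) {
  tibble(term = c("delta", "tau2", "sigma2", "icc"),
         estimate = c(x$delta, x$tau2, x$sigma2, x$icc),
         std.error = c(x$se$delta, x$se$tau2, x$se$sigma2, x$se$icc))
}

#' @exportS3Method generics::glance
glance.icc_fit <- function(x, ...) {
  tibble(icc = x$icc, tau2 = x$tau2, sigma2 = x$sigma2, logLik = x$loglik,
         n_persons = x$n_persons, n_obs = x$n_obs, method = x$method)
}

# ---- latent covariate regression -------------------------------------------

level_regression <- function(Sigma, yi, xi) {
  b <- solve(Sigma[xi, xi, drop = FALSE], Sigma[xi, yi])
  resid_var <- Sigma[yi, yi] - drop(crossprod(b, Sigma[xi, yi]))
  r2 <- 1 - resid_var / Sigma[yi, yi]
  sds <- sqrt(diag(Sigma))
  list(raw = drop(b), std = drop(b) * sds[xi] / sds[yi],
       r2 = max(min(r2, 1), 0), resid_var = resid_var)
}

#' Latent covariate regression of response times on the diffusion scores
#'
#' Regresses observed (log) RTs on the drift and boundary scores
#' simultaneously at the within- and the between-person level, using the
#' latent decomposition of all three variables: between-person coefficients
#' are computed from the ML between-person covariance matrix rather than from
#' manifest person means, which avoids the attenuation bias of computed
#' cluster means. Reports raw and standardized coefficients plus the
#' level-specific R-squared.
#'
#' @param data A data frame with one row per person-occasion.
#' @param y,x,z Column names (bare or string) of the outcome and the two
#'   predictors.
#' @param person Person identifier column.
#' @return An object of class `latent_reg_fit`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_latent_regression <- function(data, y, x, z, person) {
  y <- rlang::as_name(rlang::ensym(y))
  x <- rlang::as_name(rlang::ensym(x))
  z <- rlang::as_name(rlang::ensym(z))
  person <- rlang::as_name(rlang::ensym(person))
  vars <- c(y, x, z)
  fit <- fit_twolevel_mvn(data, vars, person)
  for (lvl in c("within", "between")) {
    S <- if (lvl == "within") fit$Sigma_w else fit$Sigma_b
    r <- S[x, z] / sqrt(S[x, x] * S[z, z])
    if (!is.finite(r) || abs(r) > 0.999) {
      abort(paste0("Predictors '", x, "' and '", z, "' are collinear at the ",
                   lvl, "-person level."), class = "emadiff_collinearity_error")
    }
  }
  wi <- level_regression(fit$Sigma_w, y, c(x, z))
  be <- level_regression(fit$Sigma_b, y, c(x, z))
  structure(
    list(within = wi, between = be, y = y, predictors = c(x, z), fit = fit),
    class = "latent_reg_fit"
  )
}

#' @export
print.latent_reg_fit <- function(x, ...) {
  cat("Latent covariate regression of", x$y, "on",
      paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  within : beta_std = (%s), R2 = %.3f\n",
              paste(sprintf("%.3f", x$within$std), collapse = ", "),
              x$within$r2))
  cat(sprintf("  between: beta_std = (%s), R2 = %.3f\n",
              paste(sprintf("%.3f", x$between$std), collapse = ", "),
              x$between$r2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.latent_reg_fit <- function(x, ...) {
  tibble(
    level = rep(c("within", "between"), each = length(x$predictors)),
    term = rep(x$predictors, 2),
    estimate = c(x$within$raw, x$between$raw),
    std_estimate = c(x$within$std, x$between$std)
  )
}

#' @exportS3Method generics::glance
glance.latent_reg_fit <- function(x, ...) {
  tibble(r2_within = x$within$r2, r2_between = x$between$r2,
         logLik = x$fit$loglik, n_persons = x$fit$n_persons,
         n_obs = x$fit$n_obs)
}

# ---- multilevel correlations and dependent-correlation tests ---------------

safe_cov2cor <- function(S) {
  d <- diag(S)
  bad <- !(d > 0)
  if (any(bad)) {
    warn(paste0("Variable(s) with no variance at this level: ",
                paste(colnames(S)[bad], collapse = ", ")))
  }
  R <- S / sqrt(outer(d, d))
  R[bad, ] <- NA_real_
  R[, bad] <- NA_real_
  diag(R) <- ifelse(bad, NA_real_, 1)
  R
}

#' Within- and between-person correlation matrices
#'
#' Level-specific correlation matrices of a set of occasion-level scores from
#' the two-level ML covariance fit, with their Fisher z transforms.
#'
#' @param data A data frame with one row per person-occasion.
#' @param vars Character vector (>= 2) of score columns.
#' @param person Person identifier column name.
#' @return An object of class `mlcorr_fit` with `within`, `between`,
#'   `fisher_z` (list of both levels) and the underlying fit.
#' @export
multilevel_correlations <- function(data, vars, person) {
  if (length(vars) < 2) abort("Need at least 2 variables.")
  person <- rlang::as_name(rlang::ensym(person))
  fit <- fit_twolevel_mvn(data, vars, person)
  within <- safe_cov2cor(fit$Sigma_w)
  between <- safe_cov2cor(fit$Sigma_b)
  structure(
    list(within = within, between = between,
         fisher_z = list(within = atanh(pmin(pmax(within, -1), 1)),
                         between = atanh(pmin(pmax(between, -1), 1))),
         fit = fit, vars = vars),
    class = "mlcorr_fit"
  )
}

#' @export
print.mlcorr_fit <- function(x, ...) {
  cat("Within-person correlations:\n"); print(round(x$within, 3))
  cat("Between-person correlations:\n"); print(round(x$between, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mlcorr_fit <- function(x, ...) {
  pairs <- which(upper.tri(x$within), arr.ind = TRUE)
  tibble(
    var1 = rep(x$vars[pairs[, 1]], 2),
    var2 = rep(x$vars[pairs[, 2]], 2),
    level = rep(c("within", "between"), each = nrow(pairs)),
    estimate = c(x$within[pairs], x$between[pairs]),
    fisher_z = c(x$fisher_z$within[pairs], x$fisher_z$between[pairs])
  )
}

# moment-estimator correlation at one level for one bootstrap resample
boot_level_cor <- function(st, idx, level, i1, j1, i2, j2) {
  n_j <- st$n_j[idx]
  N <- sum(n_j)
  J <- length(idx)
  p <- st$p
  Sw <- matrix(colSums(st$S_flat[idx, , drop = FALSE]), p, p) / max(N - J, 1)
  if (level == "within") {
    R <- Sw
  } else {
    M <- st$M[idx, , drop = FALSE]
    ybar <- colSums(M * n_j) / N
    Mc <- sweep(M, 2, ybar)
    B <- crossprod(sqrt(n_j) * Mc) / max(J - 1, 1)
    n0 <- (N - sum(n_j^2) / N) / max(J - 1, 1)
    R <- (B - Sw) / n0
  }
  c(R[i1, j1] / sqrt(R[i1, i1] * R[j1, j1]),
    R[i2, j2] / sqrt(R[i2, i2] * R[j2, j2]))
}

#' Test the difference between two dependent correlations
#'
#' Compares two correlations estimated at the same level of the same
#' multilevel fit (e.g. the drift-drift correspondence across two item sets
#' against a drift-boundary correlation). The difference is taken on the
#' Fisher z scale; its standard error comes from a person-resampling
#' (cluster) bootstrap, because dependent multilevel correlations have no
#' clean closed-form sampling covariance.
#'
#' @param object An `mlcorr_fit`.
#' @param pair_a,pair_b Character vectors of length 2 naming the variables of
#'   each correlation.
#' @param level `"within"` or `"between"`.
#' @param n_boot Bootstrap replicates (default 1999).
#' @param seed Optional integer seed for the resampling.
#' @return A one-row tibble: the two correlations, the Fisher-z difference,
#'   its bootstrap SE, z statistic and two-sided p value.
#' @export
compare_dependent_correlations <- function(object, pair_a, pair_b,
                                           level = c("within", "between"),
                                           n_boot = 1999, seed = NULL) {
  level <- match.arg(level)
  st <- object$fit$stats
  if (st$J < 50) {
    warn("Fewer than 50 persons; the cluster bootstrap may be unstable.")
  }
  R <- if (level == "within") object$within else object$between
  i1 <- match(pair_a[1], object$vars); j1 <- match(pair_a[2], object$vars)
  i2 <- match(pair_b[1], object$vars); j2 <- match(pair_b[2], object$vars)
  if (anyNA(c(i1, j1, i2, j2))) abort("Pair variables not found in the fit.")
  r_a <- R[i1, j1]; r_b <- R[i2, j2]
  diff_z <- atanh(r_a) - atanh(r_b)
  if (identical(sort(c(i1, j1)), sort(c(i2, j2)))) {
    return(tibble(r_a = r_a, r_b = r_b, diff_z = 0, se = 0, statistic = 0,
                  p_value = 1, level = level, n_boot = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  zdiffs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(st$J, st$J, replace = TRUE)
    rs <- boot_level_cor(st, idx, level, i1, j1, i2, j2)
    if (any(!is.finite(rs)) || any(abs(rs) >= 1)) return(NA_real_)
    atanh(rs[1]) - atanh(rs[2])
  }, numeric(1))
  se <- sd(zdiffs, na.rm = TRUE)
  stat <- diff_z / se
  tibble(r_a = r_a, r_b = r_b, diff_z = diff_z, se = se, statistic = stat,
         p_value = 2 * pnorm(-abs(stat)), level = level,
         n_boot = sum(is.finite(zdiffs)))
}

# ---- multilevel mediation --------------------------------------------------

mediation_paths <- function(S, std_predictor) {
  # variable order: predictor, m1, m2, y
  a <- unname(S[1, 2:3] / S[1, 1])
  bidx <- c(2, 3, 1)
  bc <- unname(solve(S[bidx, bidx], S[bidx, 4]))
  b <- bc[1:2]
  cprime <- bc[3]
  total <- unname(S[1, 4] / S[1, 1])
  sds <- unname(sqrt(diag(S)))
  sp <- if (std_predictor) sds[1] else 1
  list(
    a_raw = a, b_raw = b, cprime_raw = cprime, total_raw = total,
    indirect_raw = a * b,
    a_std = a * sp / sds[2:3],
    b_std = b * sds[2:3] / sds[4],
    cprime_std = cprime * sp / sds[4],
    total_std = total * sp / sds[4],
    indirect_std = a * b * sp / sds[4]
  )
}

#' Multilevel mediation with drift and boundary as simultaneous mediators
#'
#' Fits a 1-1-1 (occasion-level predictor) or 2-1-1 (person-level predictor)
#' mediation model on the latent two-level decomposition of predictor,
#' mediators and outcome. Paths are read off the covariance matrix of the
#' predictor's level; indirect effects are products of same-level paths, and
#' the total effect decomposes exactly as `total = c' + sum(a*b)`. 95%
#' intervals for the indirect effects come from Monte-Carlo sampling of the
#' joint asymptotic distribution of the fitted covariance parameters, which,
#' like bootstrapping, respects the non-normal sampling distribution of a
#' product of coefficients. Binary predictors are standardized with respect
#' to the dependent variable only; continuous predictors with respect to
#' both.
#'
#' @param data A data frame with one row per person-occasion.
#' @param predictor Predictor column (bare name or string).
#' @param mediators Character vector of exactly 2 mediator columns
#'   (drift and boundary scores).
#' @param outcome Outcome column (observed mean log RT).
#' @param person Person identifier column.
#' @param predictor_level `"occasion"` (1-1-1) or `"person"` (2-1-1).
#' @param mc_draws Monte-Carlo draws for the intervals (default 100000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Optional integer seed for the Monte-Carlo draws.
#' @return An object of class `mediation_fit`. Supports [tidy()].
#' @export
fit_mediation <- function(data, predictor, mediators, outcome, person,
                          predictor_level = c("occasion", "person"),
                          mc_draws = 1e5, conf = 0.95, seed = NULL) {
  predictor_level <- match.arg(predictor_level)
  predictor <- rlang::as_name(rlang::ensym(predictor))
  outcome <- rlang::as_name(rlang::ensym(outcome))
  person <- rlang::as_name(rlang::ensym(person))
  if (length(mediators) != 2) abort("Exactly 2 mediators are required.")
  pv <- data[[predictor]]
  if (length(unique(na.omit(pv))) < 2) {
    abort("Predictor is constant.", class = "emadiff_precondition_error")
  }
  within_var <- any(tapply(pv, data[[person]],
                           function(v) length(unique(na.omit(v)))) > 1)
  if (predictor_level == "person" && within_var) {
    abort("Predictor varies within persons but was declared person-level.",
          class = "emadiff_level_error")
  }
  if (predictor_level == "occasion" && !within_var) {
    abort("Predictor is person-constant but was declared occasion-level.",
          class = "emadiff_level_error")
  }
  vars <- c(predictor, mediators, outcome)
  between_only <- if (predictor_level == "person") predictor else character(0)
  fit <- fit_twolevel_mvn(data, vars, person, between_only = between_only)
  level <- if (predictor_level == "occasion") "within" else "between"
  S <- if (level == "within") fit$Sigma_w else fit$Sigma_b
  binary <- all(na.omit(pv) %in% c(0, 1))
  paths <- mediation_paths(S, std_predictor = !binary)

  # Monte-Carlo interval: sample the covariance parameters from their
  # asymptotic normal distribution and push each draw through the path
  # computation
  H <- optimHess(fit$par, fit$nll)
  Vp <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(Vp)) {
    warn("Observed information is singular; Monte-Carlo intervals unavailable.")
    ci <- matrix(NA_real_, 2, 2)
  } else {
    ev <- eigen((Vp + t(Vp)) / 2, symmetric = TRUE)
    Vh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
    if (!is.null(seed)) set.seed(seed)
    Z <- matrix(rnorm(mc_draws * length(fit$par)), mc_draws)
    draws <- Z %*% t(Vh)
    draws <- sweep(draws, 2, fit$par, "+")
    p <- length(vars)
    pw <- length(fit$widx)
    nw <- lower_tri_n(pw)
    nb <- lower_tri_n(p)
    ind <- matrix(NA_real_, mc_draws, 2)
    for (d in seq_len(mc_draws)) {
      Sw_full <- matrix(0, p, p)
      if (pw > 0) {
        Lw <- par_to_chol(draws[d, seq_len(nw)], pw)
        Sw_full[fit$widx, fit$widx] <- tcrossprod(Lw)
      }
      Sb <- tcrossprod(par_to_chol(draws[d, nw + seq_len(nb)], p))
      Sd <- if (level == "within") Sw_full else Sb
      pd <- tryCatch(mediation_paths(Sd, std_predictor = !binary),
                     error = function(e) NULL)
      if (!is.null(pd)) ind[d, ] <- pd$indirect_std
    }
    alpha <- (1 - conf) / 2
    ci <- t(apply(ind, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(predictor = predictor, predictor_level = predictor_level,
         predictor_binary = binary, mediators = mediators, outcome = outcome,
         level = level, paths = paths,
         indirect = tibble(
           mediator = mediators,
           estimate = paths$indirect_std,
           ci_lower = ci[, 1], ci_upper = ci[, 2],
           raw_estimate = paths$indirect_raw),
         total = paths$total_std, cprime = paths$cprime_std,
         fit = fit, mc_draws = mc_draws, conf = conf),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Multilevel mediation (%s predictor '%s', %s level)\n",
              if (x$predictor_binary) "binary" else "continuous",
              x$predictor, x$level))
  cat(sprintf("  total = %.3f, direct c' = %.3f\n", x$total, x$cprime))
  cat("  indirect effects (standardized):\n")
  print(as.data.frame(x$indirect), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mediation_fit <- function(x, ...) {
  p <- x$paths
  tibble(
    term = c(paste0("a_", x$mediators), paste0("b_", x$mediators),
             "c_prime", "total", paste0("indirect_", x$mediators)),
    estimate = c(p$a_raw, p$b_raw, p$cprime_raw, p$total_raw, p$indirect_raw),
    std_estimate = c(p$a_std, p$b_std, p$cprime_std, p$total_std,
                     p$indirect_std)
  )
}
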
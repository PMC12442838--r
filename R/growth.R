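#' Negative exponential trajectory
#'
#' Evaluates `asymptote - gain * exp(-rate * occasion)`, where `gain` is the
#' signed change from the initial level (`asymptote - gain` at occasion 0) to
#' the asymptote: a negative gain describes a variable that starts high and
#' falls toward its asymptote (practice effects in response times), a
#' positive gain one that rises. Change is steepest initially and slows at
#' rate `rate`.
#'
#' @param asymptote Level approached with unlimited practice.
#' @param gain Signed change from the initial level to the asymptote.
#' @param rate Rate of approach (> 0).
#' @param occasion 0-based occasion index (scheduled prompt order).
#' @return Trajectory values.
#' @examples
#' negexp_trajectory(1.42, gain = -0.44, rate = 0.2, occasion = 0:10)
#' @export
negexp_trajectory <- function(asymptote, gain, rate, occasion) {
  asymptote - gain * exp(-rate * occasion)
}

#' Fit a negative exponential growth model
#'
#' Fits `y_ij = a_j - g_j exp(-r * occasion_ij) + e_ij` with bivariate normal
#' person random effects on the asymptote `a_j` and gain `g_j` and a common
#' rate `r`, by maximum likelihood: for fixed `r` the model is linear in
#' `(a_j, g_j)`, so the rate is profiled over linear mixed-model fits
#' (`lme4`). Occasions should be coded 0, 1, 2, ... in scheduled prompt
#' order (missed prompts leave gaps). A person-varying (log-normal) rate is
#' available through `random_rate = TRUE` (via `nlme`), but is fragile with
#' few occasions per person and off by default.
#'
#' @param data A data frame with one row per person-occasion.
#' @param value Score column (bare name or string).
#' @param person Person identifier column.
#' @param occasion 0-based occasion index column.
#' @param rate_bounds Search interval for the rate (default `c(0.01, 3)`).
#' @param random_rate Model the rate as person-varying? Default `FALSE`.
#' @return An object of class `growth_fit` with population means, random
#'   effect variances, the rate and fit diagnostics. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_negative_exponential <- function(data, value, person, occasion,
                                     rate_bounds = c(0.01, 3),
                                     random_rate = FALSE) {
  value <- rlang::as_name(rlang::ensym(value))
  person <- rlang::as_name(rlang::ensym(person))
  occasion <- rlang::as_name(rlang::ensym(occasion))
  df <- data.frame(y = data[[value]], person = factor(data[[person]]),
                   occ = data[[occasion]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$occ)) < 2) {
    abort("No time variation in the occasion index.",
          class = "emadiff_precondition_error")
  }
  enough <- mean(tapply(df$occ, df$person, function(o) length(unique(o))) >= 3)
  if (enough < 0.5) {
    warn("Fewer than half the persons have >= 3 occasions; the growth model may be weakly identified.")
  }
  if (random_rate) {
    return(fit_negexp_random_rate(df, value))
  }
  dev_at <- function(r) {
    df$x <- exp(-r * df$occ)
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 + x | person), data = df, REML = FALSE)))
    -2 * as.numeric(logLik(m))
  }
  opt <- optimize(dev_at, rate_bounds, tol = 1e-4)
  r <- opt$minimum
  if (r < rate_bounds[1] + 1e-3) {
    warn("Rate collapsed to its lower bound; the model degenerates toward a linear trend.")
  }
  df$x <- exp(-r * df$occ)
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 + x | person), data = df, REML = FALSE)))
  fe <- lme4::fixef(m)
  vc <- as.data.frame(lme4::VarCorr(m))
  se <- sqrt(diag(as.matrix(vcov(m))))
  var_a <- vc$vcov[vc$grp == "person" & vc$var1 == "(Intercept)" &
                     is.na(vc$var2)]
  var_g <- vc$vcov[vc$grp == "person" & vc$var1 == "x" & is.na(vc$var2)]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  # profile curvature of the deviance gives an approximate SE for the rate
  hr <- max(1e-3, r * 1e-2)
  d2 <- (dev_at(r + hr) - 2 * opt$objective + dev_at(max(r - hr, 1e-4))) / hr^2
  se_rate <- if (is.finite(d2) && d2 > 0) sqrt(2 / d2) else NA_real_
  obs_means <- aggregate(y ~ occ, df, mean)
  structure(
    list(asymptote = unname(fe[1]), gain = -unname(fe[2]), rate = r,
         se = list(asymptote = se[1], gain = se[2], rate = se_rate),
         var_asymptote = var_a, var_gain = var_g, resid_var = resid_var,
         loglik = as.numeric(logLik(m)), deviance = opt$objective,
         n_persons = length(unique(df$person)), n_obs = nrow(df),
         variable = value, data = df,
         occasion_means = tibble(
           occasion = obs_means$occ, observed = obs_means$y,
           fitted = negexp_trajectory(unname(fe[1]), -unname(fe[2]), r,
                                      obs_means$occ))),
    class = "growth_fit"
  )
}

# person-varying rate via nonlinear mixed model; exploratory option
fit_negexp_random_rate <- function(df, value) {
  if (!requireNamespace("nlme", quietly = TRUE)) {
    abort("Package 'nlme' is required for random_rate = TRUE.")
  }
  start <- c(a = mean(df$y[df$occ > median(df$occ)]),
             c = mean(df$y[df$occ == min(df$occ)]) -
               mean(df$y[df$occ > median(df$occ)]),
             lr = log(0.2))
  m <- nlme::nlme(y ~ a + c * exp(-exp(lr) * occ),
                  fixed = a + c + lr ~ 1,
                  random = a + c ~ 1 | person,
                  data = df, start = start,
                  control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200))
  fe <- nlme::fixef(m)
  vc <- nlme::VarCorr(m)
  structure(
    list(asymptote = unname(fe["a"]), gain = -unname(fe["c"]),
         rate = exp(unname(fe["lr"])),
         se = list(asymptote = NA_real_, gain = NA_real_, rate = NA_real_),
         var_asymptote = as.numeric(vc["a", "Variance"]),
         var_gain = as.numeric(vc["c", "Variance"]),
         resid_var = m$sigma^2, loglik = as.numeric(logLik(m)),
         deviance = -2 * as.numeric(logLik(m)),
         n_persons = length(unique(df$person)), n_obs = nrow(df),
         variable = value, data = df,
         occasion_means = NULL),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Negative exponential growth fit for '%s':\n", x$variable))
  cat(sprintf("  asymptote = %.3f (SE %.3f), gain = %.3f (SE %.3f), rate = %.3f\n",
              x$asymptote, x$se$asymptote, x$gain, x$se$gain, x$rate))
  cat(sprintf("  person variances: asymptote %.4f, gain %.4f; residual %.4f\n",
              x$var_asymptote, x$var_gain, x$resid_var))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("asymptote", "gain", "rate"),
         estimate = c(x$asymptote, x$gain, x$rate),
         std.error = c(x$se$asymptote, x$se$gain, x$se$rate))
}

#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble(asymptote = x$asymptote, gain = x$gain, rate = x$rate,
         var_asymptote = x$var_asymptote, var_gain = x$var_gain,
         resid_var = x$resid_var, logLik = x$loglik,
         n_persons = x$n_persons, n_obs = x$n_obs)
}

#' Z-score a vector
#'
#' Centers and scales to unit sample variance, ignoring missing values; used
#' to place variables on a common scale before comparing growth gains.
#'
#' @param x Numeric vector.
#' @return The standardized vector.
#' @export
zscore <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)

#' Compare the gains of two growth models on a common scale
#'
#' Jointly refits the two (z-scored) variables as a bivariate negative
#' exponential model with per-variable residual variances and correlated
#' person random effects (`glmmTMB`), with each rate fixed at its
#' single-variable profile estimate, and Wald-tests the equality of the
#' absolute gain parameters (chi-squared, 1 df). Both inputs must be fits of
#' z-scored variables (variance 1 within 0.01).
#'
#' @param fit_1,fit_2 `growth_fit` objects for the two z-scored variables.
#' @return A one-row tibble with both gains, the absolute-gain difference,
#'   the Wald chi-squared statistic and p value.
#' @export
compare_gains <- function(fit_1, fit_2) {
  for (f in list(fit_1, fit_2)) {
    if (abs(sd(f$data$y) - 1) > 0.01) {
      abort(paste0("Variable '", f$variable, "' is not z-scored (sd = ",
                   round(sd(f$data$y), 3), ")."),
            class = "emadiff_precondition_error")
    }
  }
  d1 <- fit_1$data; d1$d1 <- 1; d1$d2 <- 0
  d1$e1 <- exp(-fit_1$rate * d1$occ); d1$e2 <- 0
  d1$vf <- "v1"
  d2 <- fit_2$data; d2$d1 <- 0; d2$d2 <- 1
  d2$e1 <- 0; d2$e2 <- exp(-fit_2$rate * d2$occ)
  d2$vf <- "v2"
  dd <- rbind(d1, d2)
  dd$vf <- factor(dd$vf)
  joint <- function(full) {
    re <- if (full) "(0 + d1 + d2 + e1 + e2 | person)" else
      "(0 + d1 + e1 | person) + (0 + d2 + e2 | person)"
    glmmTMB::glmmTMB(
      as.formula(paste("y ~ 0 + d1 + d2 + e1 + e2 +", re)),
      dispformula = ~ 0 + vf, data = dd, REML = FALSE)
  }
  m <- tryCatch(suppressWarnings(joint(TRUE)), error = function(e) NULL)
  V <- if (!is.null(m)) tryCatch(vcov(m)$cond, error = function(e) NULL) else NULL
  if (is.null(m) || is.null(V) || anyNA(V[c("e1", "e2"), c("e1", "e2")])) {
    warn("Full cross-variable random-effect structure did not converge; using the blocked structure.")
    m <- suppressWarnings(joint(FALSE))
    V <- vcov(m)$cond
  }
  fe <- glmmTMB::fixef(m)$cond
  g1 <- -unname(fe["e1"]); g2 <- -unname(fe["e2"])
  w <- abs(g1) - abs(g2)
  gr <- c(sign(fe["e1"]), -sign(fe["e2"]))   # d|g|/d(coef): |g| = |coef|
  vw <- drop(t(gr) %*% V[c("e1", "e2"), c("e1", "e2")] %*% gr)
  stat <- if (vw > 0) w^2 / vw else 0
  tibble(gain_1 = g1, gain_2 = g2, abs_diff = w, statistic = stat, df = 1,
         p_value = pchisq(stat, 1, lower.tail = FALSE),
         rate_1 = fit_1$rate, rate_2 = fit_2$rate)
}
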
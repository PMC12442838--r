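# Constructed datasets with known population structure, shared across the
# multilevel, mediation and growth tests.

# two-level trivariate scores with specified standardized level betas
make_latent_reg_data <- function(seed, J = 500, n = 20,
                                 beta_w = c(-0.7, 0.6),
                                 beta_b = c(-0.6, 0.75)) {
  set.seed(seed)
  resw <- 1 - sum(beta_w^2)
  resb <- 1 - sum(beta_b^2)
  stopifnot(resw > 0, resb > 0)
  xb <- rnorm(J); zb <- rnorm(J)
  yb <- beta_b[1] * xb + beta_b[2] * zb + rnorm(J, 0, sqrt(resb))
  xw <- rnorm(J * n); zw <- rnorm(J * n)
  yw <- beta_w[1] * xw + beta_w[2] * zw + rnorm(J * n, 0, sqrt(resw))
  data.frame(
    person = rep(seq_len(J), each = n),
    x = rep(xb, each = n) + xw,
    z = rep(zb, each = n) + zw,
    y = rep(yb, each = n) + yw
  )
}

# 1-1-1 mediation data built from raw paths; returns the data frame plus the
# population within-level covariance matrix and the implied true paths
make_mediation_data <- function(seed, J = 400, n = 12, p_w = 0.3,
                                a = c(-0.2, -0.1), b = c(-0.25, 0.25),
                                cprime = 0,
                                sd_m = c(0.6, 0.6), sd_e = 0.5,
                                sd_between = 0.3) {
  set.seed(seed)
  N <- J * n
  w <- rbinom(N, 1, p_w)
  m1 <- a[1] * w + rnorm(N, 0, sd_m[1])
  m2 <- a[2] * w + rnorm(N, 0, sd_m[2])
  y <- b[1] * m1 + b[2] * m2 + cprime * w + rnorm(N, 0, sd_e)
  person <- rep(seq_len(J), each = n)
  u <- rnorm(J, 0, sd_between)
  dat <- data.frame(person = person, w = w, m1 = m1, m2 = m2,
                    y = y + u[person])
  # population within covariance (w, m1, m2, y)
  vw <- p_w * (1 - p_w)
  S <- matrix(0, 4, 4)
  S[1, 1] <- vw
  S[2, 2] <- a[1]^2 * vw + sd_m[1]^2
  S[3, 3] <- a[2]^2 * vw + sd_m[2]^2
  S[1, 2] <- S[2, 1] <- a[1] * vw
  S[1, 3] <- S[3, 1] <- a[2] * vw
  S[2, 3] <- S[3, 2] <- a[1] * a[2] * vw
  cy <- c(b[1] * S[1, 2] + b[2] * S[1, 3] + cprime * vw,
          b[1] * S[2, 2] + b[2] * S[2, 3] + cprime * S[1, 2],
          b[1] * S[2, 3] + b[2] * S[3, 3] + cprime * S[1, 3])
  S[1:3, 4] <- S[4, 1:3] <- cy
  S[4, 4] <- b[1]^2 * S[2, 2] + b[2]^2 * S[3, 3] +
    2 * b[1] * b[2] * S[2, 3] + cprime^2 * vw + sd_e^2 +
    2 * cprime * (b[1] * S[1, 2] + b[2] * S[1, 3])
  truth <- emadiff:::mediation_paths(S, std_predictor = FALSE)
  list(data = dat, Sigma_w = S, truth = truth)
}

# negative exponential person series; gain is the change initial -> asymptote
make_growth_data <- function(seed, J = 500, n_occ = 30, mean_a = 1.35,
                             mean_g = -0.44, rate = 0.25, sd_a = 0.15,
                             sd_g = 0.15, sd_e = 0.25) {
  set.seed(seed)
  a_j <- rnorm(J, mean_a, sd_a)
  g_j <- rnorm(J, mean_g, sd_g)
  pid <- rep(seq_len(J), each = n_occ)
  occ <- rep(seq_len(n_occ) - 1, J)
  data.frame(
    person = pid, occ = occ,
    y = negexp_trajectory(a_j[pid], g_j[pid], rate, occ) +
      rnorm(J * n_occ, 0, sd_e)
  )
}

# Two z-scored variables with specified gains, for compare_gains. Equal
# rates and noise keep the two total variances equal, so z-scoring preserves
# the intended gap between the absolute gains.
make_gain_pair <- function(seed, g1, g2, J = 400, n_occ = 30,
                           rate = c(0.25, 0.25), gain_sd = 0.45) {
  set.seed(seed)
  pid <- rep(seq_len(J), each = n_occ)
  occ <- rep(seq_len(n_occ) - 1, J)
  mk <- function(gm, r) {
    a_j <- rnorm(J, 0, 0.6)
    g_j <- rnorm(J, gm, gain_sd)
    negexp_trajectory(a_j[pid], g_j[pid], r, occ) + rnorm(J * n_occ, 0, 0.5)
  }
  data.frame(person = pid, occ = occ,
             v1 = zscore(mk(g1, rate[1])), v2 = zscore(mk(g2, rate[2])))
}

# small EMA record table for parser tests
make_tiny_records <- function() {
  tibble::tibble(
    person_id = c("A", "A", "B"),
    occasion_id = c(1L, 1L, 1L),
    day = c(1L, 1L, 1L),
    item_id = c("angry", "lonely", "angry"),
    rating = c(10, 80, 55),
    rt_seconds = c(3, 5, 2),
    activities = c("work;eating", "work;eating", "leisure"),
    neuroticism = c(0.3, 0.3, -1),
    depression = c(0.1, 0.1, 0.5)
  )
}
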
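# Independent oracles: deliberate brute-force implementations that share
# no code with the package internals they check.

# Efron log partial likelihood by direct term-by-term evaluation.
naive_efron_loglik <- function(time, event, group, beta) {
  r <- exp(beta * group)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    tied <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(tied)
    D0 <- sum(r[tied])
    S0 <- sum(r[risk])
    ll <- ll + beta * sum(group[tied])
    for (l in seq_len(d) - 1) ll <- ll - log(S0 - (l / d) * D0)
  }
  ll
}

# Exact (no-ties) Cox log partial likelihood: one risk-set term per event.
naive_exact_cox_loglik <- function(time, event, group, beta) {
  r <- exp(beta * group)
  sum(vapply(which(event == 1), function(i) {
    beta * group[i] - log(sum(r[time >= time[i]]))
  }, numeric(1)))
}

# Product-limit survival curve and median by direct arithmetic.
naive_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (j in seq_along(ts)) {
    n_risk <- sum(time >= ts[j])
    d <- sum(time == ts[j] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[j] <- s
  }
  median <- if (any(surv <= 0.5)) ts[which(surv <= 0.5)[1L]] else NA_real_
  list(time = ts, surv = surv, median = median)
}

# Dense trapezoid-grid marginal likelihood over beta_hat +/- 10 SE
# (intersected with the prior support), independent of the adaptive
# quadrature path.
grid_bf10 <- function(data, prior, n_grid = 8001L) {
  cph <- survival::coxph(survival::Surv(time, event) ~ group,
                         data = data, ties = "efron")
  bh <- unname(stats::coef(cph))
  se <- sqrt(stats::vcov(cph)[1L, 1L])
  lo <- max(bh - 10 * se, prior$lower)
  hi <- min(bh + 10 * se, prior$upper)
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, function(b) efron_loglik(data, b), numeric(1))
  lp <- stats::dnorm(grid, prior$mu, prior$sigma, log = TRUE) -
    prior$log_mass
  g <- ll + lp
  m <- max(g)
  h <- grid[2L] - grid[1L]
  v <- exp(g - m)
  log_marg <- m + log(h * (sum(v) - (v[1L] + v[n_grid]) / 2))
  exp(log_marg - efron_loglik(data, prior$beta0))
}

# Savage-Dickey oracle via conjugate-Normal posterior ordinates; the
# one-sided truncation masses come from numerical integration rather
# than pnorm.
sd_oracle_bf10 <- function(beta_hat, se, prior) {
  post_var <- 1 / (1 / se^2 + 1 / prior$sigma^2)
  post_mean <- post_var * (beta_hat / se^2 + prior$mu / prior$sigma^2)
  b0 <- prior$beta0
  if (prior$side == "two_sided") {
    prior_ord <- stats::dnorm(b0, prior$mu, prior$sigma)
    post_ord <- stats::dnorm(b0, post_mean, sqrt(post_var))
  } else {
    # finite integration windows that always contain the density peak,
    # so the truncation masses stay accurate far in a tail
    mass <- function(m, s) {
      if (prior$side == "greater") {
        stats::integrate(stats::dnorm, b0, max(b0, m) + 12 * s,
                         mean = m, sd = s, rel.tol = 1e-12)$value
      } else {
        stats::integrate(stats::dnorm, min(b0, m) - 12 * s, b0,
                         mean = m, sd = s, rel.tol = 1e-12)$value
      }
    }
    zp <- mass(prior$mu, prior$sigma)
    zq <- mass(post_mean, sqrt(post_var))
    prior_ord <- stats::dnorm(b0, prior$mu, prior$sigma) / zp
    post_ord <- stats::dnorm(b0, post_mean, sqrt(post_var)) / zq
  }
  prior_ord / post_ord
}

# Small tied-time dataset used across tests.
toy_tied_data <- function() {
  survival_data(
    time = c(1, 2, 2, 3, 4, 5),
    event = c(1, 1, 1, 0, 1, 0),
    group = c(0, 1, 0, 1, 0, 1)
  )
}

# Random survival dataset with ties induced by rounding.
random_tied_data <- function(n = 30L, beta = 0.5, round_digits = 0L) {
  group <- rep(c(0, 1), length.out = n)
  t_ev <- stats::rexp(n, 0.2 * exp(beta * group))
  t_c <- stats::rexp(n, 0.08)
  time <- round(pmin(t_ev, t_c), round_digits) + 1
  survival_data(time, as.numeric(t_ev <= t_c), group)
}
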
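test_that("survival_data validates its invariants", {
  expect_s3_class(survival_data(c(1, 2), c(0, 1), c(0, 1)), "survival_data")
  expect_error(survival_data(1, 1, 1), class = "coxbf_invalid_argument")
  expect_error(survival_data(c(0, 2), c(0, 1), c(0, 1)),
               class = "coxbf_invalid_argument")
  expect_error(survival_data(c(1, Inf), c(0, 1), c(0, 1)),
               class = "coxbf_invalid_argument")
  expect_error(survival_data(c(1, 2), c(0, 2), c(0, 1)),
               class = "coxbf_invalid_argument")
  expect_error(survival_data(c(1, 2), c(0, 1), c(0, 3)),
               class = "coxbf_invalid_argument")
  expect_error(survival_data(c(1, 2, 3), c(0, 1), c(0, 1)),
               class = "coxbf_invalid_argument")
})

test_that("Efron log partial likelihood matches hand evaluation", {
  # no events: empty product
  d0 <- survival_data(c(1, 2, 3), c(0, 0, 0), c(0, 1, 0))
  expect_identical(efron_loglik(d0, 1.3), 0)
  # one event among 4 distinct-time subjects at beta = 0: -log(4)
  d1 <- survival_data(c(1, 2, 3, 4), c(1, 0, 0, 0), c(0, 1, 0, 1))
  expect_equal(efron_loglik(d1, 0), -log(4), tolerance = 1e-12)
  # tied-pair toy set, value frozen from a scripted term-by-term oracle
  expect_equal(efron_loglik(toy_tied_data(), 0.5), -6.211608257132,
               tolerance = 1e-9)
  # property: agreement with the naive oracle on random tied datasets
  set.seed(42)
  for (rep in 1:10) {
    d <- random_tied_data(n = 25L)
    for (b in c(-1, 0, 0.7)) {
      expect_equal(efron_loglik(d, b),
                   naive_efron_loglik(d$time, d$event, d$group, b),
                   tolerance = 1e-10)
    }
  }
  expect_error(efron_loglik(toy_tied_data(), Inf),
               class = "coxbf_invalid_argument")
})

test_that("Efron equals the exact Cox partial likelihood without ties", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 20L
    d <- survival_data(sample(seq_len(100), n), rbinom(n, 1, 0.7),
                       rep(c(0, 1), length.out = n))
    for (b in c(-0.8, 0, 1.2)) {
      expect_equal(efron_loglik(d, b),
                   naive_exact_cox_loglik(d$time, d$event, d$group, b),
                   tolerance = 1e-13)
    }
  }
})

test_that("fit_cox agrees with survival::coxph and is symmetric", {
  # perfectly symmetric groups: beta_hat = 0, hr = 1
  sym <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                       c(0, 0, 0, 1, 1, 1))
  fsym <- fit_cox(sym)
  expect_equal(fsym$beta_hat, 0, tolerance = 1e-9)
  expect_equal(fsym$hr, 1, tolerance = 1e-9)
  # independent implementation cross-check on simulated data
  for (seed in c(3, 14)) {
    d <- simulate_survival(simulation_spec(40, 40, 0.5,
                                           censor_rate = 0.03,
                                           seed = seed))
    fit <- fit_cox(d)
    cph <- survival::coxph(survival::Surv(time, event) ~ group,
                           data = d, ties = "efron")
    expect_equal(fit$beta_hat, unname(coef(cph)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(vcov(cph)[1, 1]), tolerance = 1e-6)
    expect_equal(fit$loglik_at_mle, cph$loglik[2], tolerance = 1e-6)
    expect_equal(fit$loglik_at_null, cph$loglik[1], tolerance = 1e-8)
    expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
    expect_gte(fit$loglik_at_mle, fit$loglik_at_null)
  }
})

test_that("fit_cox flags no-information and monotone-likelihood inputs", {
  no_events <- survival_data(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 0, 1, 1))
  expect_error(fit_cox(no_events), class = "coxbf_no_information")
  one_group <- survival_data(c(1, 2, 3), c(1, 1, 0), c(0, 0, 0))
  expect_error(fit_cox(one_group), class = "coxbf_invalid_argument")
  # complete separation: every experimental subject fails before any
  # control is at risk of being beaten -> monotone likelihood
  sep <- survival_data(c(1, 2, 3, 4, 10, 11, 12, 13),
                       c(1, 1, 1, 1, 0, 0, 0, 0),
                       c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(fit_cox(sep), class = "coxbf_divergence")
})

test_that("partial likelihood depends on time ranks only", {
  d <- simulate_survival(simulation_spec(30, 30, 0.4, censor_rate = 0.05,
                                         seed = 21))
  fit <- fit_cox(d)
  for (c_scale in c(7, 0.01)) {
    ds <- survival_data(d$time * c_scale, d$event, d$group)
    fs <- fit_cox(ds)
    expect_equal(fs$beta_hat, fit$beta_hat, tolerance = 1e-8)
    expect_equal(fs$se, fit$se, tolerance = 1e-8)
    expect_equal(efron_loglik(ds, 0.3), efron_loglik(d, 0.3),
                 tolerance = 1e-8)
  }
})

test_that("swapping group labels negates beta_hat and inverts the HR", {
  d <- simulate_survival(simulation_spec(35, 30, 0.6, censor_rate = 0.04,
                                         seed = 5))
  fit <- fit_cox(d)
  swapped <- survival_data(d$time, d$event, 1 - d$group)
  fsw <- fit_cox(swapped)
  expect_equal(fsw$beta_hat, -fit$beta_hat, tolerance = 1e-8)
  expect_equal(fsw$hr, 1 / fit$hr, tolerance = 1e-8)
  expect_equal(fsw$se, fit$se, tolerance = 1e-8)
})

test_that("log partial likelihood is unimodal with its peak at the MLE", {
  d <- simulate_survival(simulation_spec(40, 40, 0.3, censor_rate = 0.03,
                                         seed = 9))
  fit <- fit_cox(d)
  grid <- seq(fit$beta_hat - 2, fit$beta_hat + 2, length.out = 81)
  ll <- vapply(grid, function(b) efron_loglik(d, b), numeric(1))
  expect_equal(grid[which.max(ll)], fit$beta_hat,
               tolerance = diff(grid[1:2]) + 1e-9)
  # increasing up to the peak, decreasing after
  peak <- which.max(ll)
  expect_true(all(diff(ll[seq_len(peak)]) > 0))
  expect_true(all(diff(ll[peak:length(ll)]) < 0))
})

test_that("km_summary matches product-limit arithmetic", {
  # all events at times 1..5: S(3) = 0.4 is the first value <= 0.5
  km <- km_summary(1:5, rep(1, 5))
  expect_equal(km$median, 3)
  # all censored: the curve never leaves 1, the median is undefined
  kc <- km_summary(1:5, rep(0, 5))
  expect_true(is.na(kc$median))
  # censored toy sample against direct product-limit computation
  t <- c(2, 3, 3, 5, 6, 8, 9, 12)
  e <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km2 <- km_summary(t, e)
  or <- naive_km(t, e)
  surv_at <- km2$curve$surv[match(or$time, km2$curve$time)]
  expect_equal(surv_at, or$surv, tolerance = 1e-12)
  expect_equal(km2$median, or$median)
  expect_true(all(diff(km2$curve$surv) <= 1e-12))
  expect_true(all(km2$curve$surv >= 0 & km2$curve$surv <= 1))
})
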
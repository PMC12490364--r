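test_that("summary_stats enforces its invariants", {
  expect_error(summary_stats(nc = 2, ne = 2, vc = 3, ve = 1, hr = 1.2),
               class = "coxbf_invalid_argument")
  expect_error(summary_stats(nc = 5, ne = 5, vc = 2, ve = 2,
                             hr = 1.2, hr_ci_lower = 1.3),
               class = "coxbf_invalid_argument")
  expect_error(summary_stats(nc = 5, ne = 5, vc = 2, ve = 2),
               class = "coxbf_invalid_argument")
  # KM statistics require tmax
  expect_error(summary_stats(nc = 5, ne = 5, vc = 2, ve = 2, km_c = 10),
               class = "coxbf_invalid_argument")
  s <- summary_stats(nc = 5, ne = 5, vc = 2, ve = 2, km_c = 10,
                     tmax = 100)
  expect_s3_class(s, "summary_stats")
})

test_that("initialize_dataset lays out the event and group blocks", {
  s <- summary_stats(nc = 2, ne = 2, vc = 1, ve = 1, hr = 1.5)
  d <- initialize_dataset(s, seed = 3)
  expect_equal(d$event, c(0, 1, 0, 1))
  expect_equal(d$group, c(0, 0, 1, 1))
  expect_true(all(d$time >= 1 & d$time <= 1000))
  # no events anywhere
  s0 <- summary_stats(nc = 3, ne = 2, vc = 0, ve = 0, hr = 1.1)
  expect_equal(initialize_dataset(s0, seed = 1)$event, rep(0, 5))
  # determinism under the seed
  expect_identical(initialize_dataset(s, seed = 9),
                   initialize_dataset(s, seed = 9))
  # a reported tmax bounds the uniform draw
  st <- summary_stats(nc = 30, ne = 30, vc = 10, ve = 10, hr = 1.5,
                      tmax = 50)
  expect_true(all(initialize_dataset(st, seed = 2)$time <= 50))
})

test_that("compute_observed_stats delegates to the fitting machinery", {
  sym <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                       c(0, 0, 0, 1, 1, 1))
  o <- compute_observed_stats(sym, loss_spec(targets = "hr", weights = 1))
  expect_equal(unname(o), 1, tolerance = 1e-9)
  d <- simulate_survival(simulation_spec(30, 30, 0.4, censor_rate = 0.04,
                                         seed = 4))
  fit <- fit_cox(d)
  o3 <- compute_observed_stats(d, loss_spec())
  expect_equal(unname(o3), c(fit$hr, fit$ci_lower, fit$ci_upper),
               tolerance = 1e-12)
  # KM entries equal km_summary on the same group
  all_ev <- survival_data(c(1:5, 1:5), rep(1, 10), rep(c(0, 1), each = 5))
  okm <- compute_observed_stats(
    all_ev, loss_spec(targets = "km_c", weights = 1)
  )
  expect_equal(unname(okm), 3)
})

test_that("the loss is the log mean squared weighted relative deviation", {
  raw <- simulate_survival(simulation_spec(25, 25, 0.3, censor_rate = 0.04,
                                           seed = 31))
  # shift times into [1, tmax]: the bounded adjustments are defined there
  d <- survival_data(raw$time + 1, raw$event, raw$group)
  spec <- loss_spec()
  # targets straight from the data: a zero adjustment is a perfect match
  s_self <- summarize_survival(d)
  expect_equal(reconstruction_loss(rep(0, 50), d, s_self, spec),
               log(spec$epsilon_floor))
  # hand evaluation with mismatched published statistics
  s_other <- summary_stats(nc = 25, ne = 25, vc = 20, ve = 20,
                           hr = 1.312, hr_ci_lower = 1.136,
                           hr_ci_upper = 1.514)
  O <- compute_observed_stats(d, spec)
  E <- c(1.312, 1.136, 1.514)
  phi_hand <- log(mean(((O - E) / E * spec$weights)^2))
  expect_equal(reconstruction_loss(rep(0, 50), d, s_other, spec),
               phi_hand, tolerance = 1e-12)
  # doubling every weight shifts the loss by exactly log 4
  spec2 <- loss_spec(weights = c(4, 2, 2))
  expect_equal(reconstruction_loss(rep(0, 50), d, s_other, spec2),
               phi_hand + log(4), tolerance = 1e-12)
  # out-of-bounds adjustments are rejected on direct calls
  expect_error(
    reconstruction_loss(rep(-50, 50), d, s_other, spec),
    class = "coxbf_invalid_argument"
  )
})

test_that("pso_minimize solves a smooth box-constrained problem", {
  set.seed(8)
  target <- c(0.3, -0.2, 0.5, 0, -0.4)
  fn <- function(x) sum((x - target)^2)
  res <- pso_minimize(fn, rep(-1, 5), rep(1, 5), max_iter = 200)
  expect_lt(res$value, 1e-4)
  expect_equal(res$par, target, tolerance = 0.05)
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(res$par >= -1 & res$par <= 1))
})

test_that("reconstruction preserves counts and never worsens the start", {
  src <- simulate_survival(simulation_spec(20, 20, 0.5, censor_rate = 0.05,
                                           seed = 15))
  stats <- summarize_survival(src)
  set.seed(1)
  rec <- reconstruct(stats, n_datasets = 3, max_iter = 60, seed = 2)
  for (r in 1:3) {
    d <- rec$datasets[[r]]
    expect_equal(sum(d$group == 0), stats$nc)
    expect_equal(sum(d$group == 1), stats$ne)
    expect_equal(sum(d$event == 1 & d$group == 0), stats$vc)
    expect_equal(sum(d$event == 1 & d$group == 1), stats$ve)
    expect_true(all(d$time >= 1 - 1e-9 & d$time <= 1000 + 1e-9))
    expect_true(all(diff(rec$traces[[r]]) <= 0))
    # the swarm evaluated the unadjusted start, so it cannot end worse
    base <- initialize_dataset(stats, rec$child_seeds[r])
    expect_lte(rec$losses[r],
               reconstruction_loss(rep(0, 40), base, stats, loss_spec()))
  }
  # fixed master seed: fully deterministic
  rec2 <- reconstruct(stats, n_datasets = 3, max_iter = 60, seed = 2)
  expect_identical(rec$log_bf10, rec2$log_bf10)
  expect_identical(rec$losses, rec2$losses)
})

test_that("weight_sweep reports bias/variance per configuration", {
  src <- simulate_survival(simulation_spec(20, 20, 0.5, censor_rate = 0.05,
                                           seed = 23))
  sets <- list(loss_spec(), loss_spec(weights = c(1, 0, 0)))
  tab <- weight_sweep(src, sets, n_reps = 2, seed = 4, max_iter = 40)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$log_bf_bias)))
  expect_true(all(tab$log_bf_var >= 0))
  # identical per-replicate seeds give identical replicates: zero variance
  tab0 <- weight_sweep(src, sets[1], n_reps = 2, seed = 4, max_iter = 30,
                       child_seeds = c(11, 11))
  expect_equal(tab0$log_bf_var, 0)
})

test_that("KM-inclusive targets add variance over HR-only targets", {
  # censoring-heavy source; compare reconstructed log-BF spread
  src <- simulate_survival(simulation_spec(25, 25, 0.6,
                                           censor_rate = 0.12,
                                           seed = 33))
  stats <- summarize_survival(src, include_km = TRUE)
  hr_spec <- loss_spec()
  km_spec <- loss_spec(
    targets = c("hr", "hr_ci_lower", "hr_ci_upper", "km_c", "km_e"),
    weights = c(2, 1, 1, 1, 1)
  )
  vars <- vapply(list(hr_spec, km_spec), function(sp) {
    rec <- reconstruct(stats, n_datasets = 4, spec = sp, max_iter = 60,
                       seed = 6)
    stats::var(rec$log_bf10, na.rm = TRUE)
  }, numeric(1))
  expect_lte(vars[1], vars[2])
})
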
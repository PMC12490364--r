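#' Specification for a synthetic two-group survival study
#'
#' Ground-truth generator used for testing, parameter recovery and
#' fixtures: exponential event times with baseline hazard
#' `baseline_rate` in the control group and
#' `baseline_rate * exp(beta_true)` in the experimental group, so
#' proportional hazards holds by construction, plus optional independent
#' exponential censoring and an administrative cutoff.
#'
#' @param n_control,n_experimental Group sizes (>= 1).
#' @param beta_true Generating log hazard ratio.
#' @param baseline_rate Exponential baseline hazard (> 0).
#' @param censor_rate Independent exponential censoring hazard (0 for
#'   none).
#' @param admin_cutoff Administrative censoring time (`NA` for none).
#' @param seed Integer seed; the resulting dataset is reproducible.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_control, n_experimental, beta_true,
                            baseline_rate = 0.1, censor_rate = 0,
                            admin_cutoff = NA_real_, seed = 1L) {
  if (n_control < 1 || n_experimental < 1) {
    stop_invalid("group sizes must be at least 1")
  }
  if (!is.finite(beta_true)) {
    stop_invalid("beta_true must be finite")
  }
  if (!is.finite(baseline_rate) || baseline_rate <= 0) {
    stop_invalid("baseline_rate must be positive (an all-zero hazard generates no data)")
  }
  if (!is.finite(censor_rate) || censor_rate < 0) {
    stop_invalid("censor_rate must be non-negative")
  }
  if (!is.na(admin_cutoff) && (!is.finite(admin_cutoff) || admin_cutoff <= 0)) {
    stop_invalid("admin_cutoff must be positive or NA")
  }
  structure(
    list(n_control = as.integer(n_control),
         n_experimental = as.integer(n_experimental),
         beta_true = beta_true, baseline_rate = baseline_rate,
         censor_rate = censor_rate, admin_cutoff = admin_cutoff,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a two-group survival dataset with known log hazard ratio
#'
#' @param spec A [simulation_spec].
#'
#' @return A [survival_data] object; observed time is the minimum of the
#'   event time, the censoring time and the administrative cutoff, with
#'   the event indicator set when the event time is the minimum.
#'
#' @examples
#' d <- simulate_survival(simulation_spec(30, 30, beta_true = 0, seed = 7))
#' mean(d$event)
#' @export
simulate_survival <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop_invalid("spec must be a simulation_spec object")
  }
  set.seed(spec$seed)
  n <- spec$n_control + spec$n_experimental
  group <- rep(c(0, 1), c(spec$n_control, spec$n_experimental))
  rate <- spec$baseline_rate * exp(spec$beta_true * group)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (spec$censor_rate > 0) {
    stats::rexp(n, spec$censor_rate)
  } else {
    rep(Inf, n)
  }
  cutoff <- if (is.na(spec$admin_cutoff)) Inf else spec$admin_cutoff
  obs <- pmin(t_event, t_cens, cutoff)
  event <- as.numeric(t_event <= pmin(t_cens, cutoff))
  survival_data(obs, event, group)
}

#' Synthetic stand-ins for classic survival benchmark datasets
#'
#' Generates datasets whose overall shape (total sample size, two groups,
#' moderate censoring) emulates three well-known survival-package
#' examples: catheter-infection times in kidney patients (n = 76),
#' advanced lung cancer survival (n = 228), and adjuvant colon cancer
#' therapy (n = 929). These are synthetic emulations of the sample-size
#' profiles only, not the real datasets; effect sizes and censoring
#' fractions are this package's own choices.
#'
#' @param profile One of `"kidney_like"`, `"lung_like"`, `"colon_like"`.
#' @param seed Integer seed.
#'
#' @return A [survival_data] object.
#' @export
make_fixture <- function(profile = c("kidney_like", "lung_like",
                                     "colon_like"),
                         seed = 1L) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    # group splits mirror roughly balanced vs male/female-style splits;
    # censor rates target the 30-60% censoring band
    kidney_like = simulation_spec(38, 38, beta_true = -0.6,
                                  baseline_rate = 0.008,
                                  censor_rate = 0.004, seed = seed),
    lung_like = simulation_spec(138, 90, beta_true = -0.5,
                                baseline_rate = 0.003,
                                censor_rate = 0.002, seed = seed),
    colon_like = simulation_spec(465, 464, beta_true = -0.1,
                                 baseline_rate = 0.0004,
                                 censor_rate = 0.0004, seed = seed)
  )
  simulate_survival(spec)
}
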
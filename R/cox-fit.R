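#' Fit the two-group Cox model by maximum partial likelihood
#'
#' Maximizes the Efron log partial likelihood over the scalar log hazard
#' ratio \eqn{\beta} by Newton-Raphson with analytic score and observed
#' information, starting at 0. The standard error is the inverse square
#' root of the observed information at the maximum, and the Wald interval
#' for the hazard ratio is \eqn{\exp(\hat\beta \pm z \cdot SE)}.
#'
#' @param data A [survival_data] object with both groups present and at
#'   least one event.
#' @param conf_level Confidence level for the Wald interval, in (0, 1).
#'
#' @return An object of class `cox_fit` with components `beta_hat`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `conf_level`, `loglik_at_mle`,
#'   `loglik_at_null`, `iterations`.
#'
#' @details A dataset with no events carries no information about
#'   \eqn{\beta} and raises a no-information error. A monotone partial
#'   likelihood (all events ordered so that \eqn{\hat\beta} diverges) is
#'   declared when the estimate exceeds 20 in absolute value --
#'   \eqn{e^{20}} is far beyond any interpretable hazard ratio -- and
#'   raises a divergence error.
#'
#' @examples
#' d <- simulate_survival(simulation_spec(50, 50, beta_true = 0.5, seed = 1))
#' fit_cox(d)
#' @export
fit_cox <- function(data, conf_level = 0.95) {
  if (!inherits(data, "survival_data")) {
    stop_invalid("data must be a survival_data object")
  }
  check_two_group(data)
  if (!is.numeric(conf_level) || length(conf_level) != 1L ||
      conf_level <= 0 || conf_level >= 1) {
    stop_invalid("conf_level must be in (0, 1)")
  }
  st <- efron_structure(data$time, data$event, data$group)
  if (st$n_events == 0L) {
    stop_no_information("no events observed: beta is not identified")
  }
  fit <- cox_newton(st)
  ll0 <- efron_eval(st, 0)$loglik
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      beta_hat = fit$beta, se = fit$se, hr = exp(fit$beta),
      ci_lower = exp(fit$beta - z * fit$se),
      ci_upper = exp(fit$beta + z * fit$se),
      conf_level = conf_level,
      loglik_at_mle = fit$loglik, loglik_at_null = ll0,
      iterations = fit$iterations
    ),
    class = "cox_fit"
  )
}

# Newton-Raphson on the scalar beta; start 0, converge when |score| < 1e-9
# or |step| < 1e-10, hard cap 50 iterations, step halving when a step
# fails to increase the log likelihood. |beta| > 20 declares divergence.
cox_newton <- function(st) {
  beta <- 0
  ev <- efron_eval(st, beta)
  for (it in seq_len(50L)) {
    if (abs(ev$score) < 1e-9) break
    if (ev$info <= 0) {
      stop_numerical("non-positive observed information during fitting")
    }
    step <- ev$score / ev$info
    cand <- beta + step
    ev_cand <- efron_eval(st, cand)
    halvings <- 0L
    while (ev_cand$loglik < ev$loglik && halvings < 30L) {
      step <- step / 2
      cand <- beta + step
      ev_cand <- efron_eval(st, cand)
      halvings <- halvings + 1L
    }
    if (abs(cand) > 20) {
      stop_divergence(sprintf(
        "monotone partial likelihood: |beta| exceeded 20 at iteration %d (beta = %.2f); the MLE does not exist",
        it, cand
      ))
    }
    conv <- abs(step) < 1e-10
    beta <- cand
    ev <- ev_cand
    if (conv) break
  }
  if (abs(ev$score) > 1e-6 * max(1, ev$info)) {
    stop_numerical(sprintf(
      "Newton-Raphson did not converge (final |score| = %.3g)", abs(ev$score)
    ))
  }
  if (ev$info <= 0) {
    stop_numerical("non-positive observed information at the maximum")
  }
  list(beta = beta, se = 1 / sqrt(ev$info), loglik = ev$loglik,
       iterations = it)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Two-group Cox proportional hazards fit (Efron ties)\n")
  cat(sprintf("  log HR (beta): %.6g  (SE %.6g)\n", x$beta_hat, x$se))
  cat(sprintf("  HR: %.6g  %g%% CI [%.6g, %.6g]\n",
              x$hr, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  cat(sprintf("  log partial likelihood: %.6g (MLE), %.6g (beta = 0)\n",
              x$loglik_at_mle, x$loglik_at_null))
  invisible(x)
}
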
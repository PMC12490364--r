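#' Bayes factor for the two-group Cox model from full data
#'
#' Computes \eqn{BF_{10} = \int_{\Omega_1} f(D \mid \beta) f(\beta)\,
#' d\beta \; / \; f(D \mid \beta_0)}, where \eqn{f(D \mid \beta)} is the
#' exponential of the Efron log partial likelihood and \eqn{f(\beta)} the
#' (truncated) Normal prior density on the alternative region
#' \eqn{\Omega_1}. The integral is evaluated by adaptive Gauss-Kronrod
#' quadrature after recentring the integrand by its maximum log value,
#' with a fixed 61-point Gauss-Legendre rule on
#' \eqn{\hat\beta \pm 12\,SE \cap \Omega_1} as fallback when the adaptive
#' error estimate is unreliable.
#'
#' @param data A [survival_data] object.
#' @param prior A [prior_spec] object.
#'
#' @return An object of class `bf_result` with components `bf10`,
#'   `log_bf10`, `log_marginal_h1`, `log_lik_h0`, `prior`, and a
#'   `numerics` list (integration method, node count, error estimate).
#'
#' @details A dataset with no events has a constant partial likelihood:
#'   the data carry no information about \eqn{\beta}, the prior
#'   integrates to 1, and \eqn{BF_{10} = 1} exactly.
#'
#' @examples
#' d <- simulate_survival(simulation_spec(40, 40, beta_true = 0.6, seed = 2))
#' bayes_factor_full(d, prior_spec(0, 1, side = "greater"))
#' @export
bayes_factor_full <- function(data, prior) {
  if (!inherits(data, "survival_data")) {
    stop_invalid("data must be a survival_data object")
  }
  if (!inherits(prior, "prior_spec")) {
    stop_invalid("prior must be a prior_spec object")
  }
  st <- efron_structure(data$time, data$event, data$group)
  if (st$n_events == 0L) {
    # flat likelihood: no information, perfect balance
    return(new_bf_result(
      log_bf10 = 0, log_marginal_h1 = 0, log_lik_h0 = 0, prior = prior,
      numerics = list(method = "flat_likelihood", nodes = 0L,
                      abs_error = 0)
    ))
  }
  check_two_group(data)
  fit <- fit_cox(data)
  # the log partial likelihood is concave, so its maximum on the closure
  # of Omega_1 sits at beta_hat clamped into the region
  b_ref <- min(max(fit$beta_hat, prior$lower), prior$upper)
  if (!is.finite(b_ref)) b_ref <- prior$beta0
  M <- efron_eval(st, b_ref)$loglik
  f <- function(b) {
    vapply(b, function(bi) {
      exp(efron_eval(st, bi)$loglik - M + prior_density(bi, prior, log = TRUE))
    }, numeric(1))
  }
  res <- tryCatch(
    stats::integrate(f, prior$lower, prior$upper,
                     rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L),
    error = function(e) NULL
  )
  ok <- !is.null(res) && res$message == "OK" && res$value > 0 &&
    is.finite(res$value) && res$abs.error <= 1e-6 * res$value
  if (ok) {
    value <- res$value
    numerics <- list(method = "gauss_kronrod_adaptive",
                     nodes = res$subdivisions * 21L,
                     abs_error = res$abs.error)
  } else {
    lo <- max(fit$beta_hat - 12 * fit$se, prior$lower)
    hi <- min(fit$beta_hat + 12 * fit$se, prior$upper)
    if (!(hi > lo)) {
      lo <- prior$beta0 - 12 * fit$se
      hi <- prior$beta0 + 12 * fit$se
      lo <- max(lo, prior$lower); hi <- min(hi, prior$upper)
    }
    gl <- pracma::gaussLegendre(61L, lo, hi)
    value <- sum(gl$w * f(gl$x))
    if (!is.finite(value) || value <= 0) {
      stop_numerical("quadrature failed: non-positive marginal likelihood")
    }
    numerics <- list(method = "gauss_legendre_61", nodes = 61L,
                     abs_error = NA_real_)
  }
  log_marg <- M + log(value)
  ll0 <- efron_eval(st, prior$beta0)$loglik
  new_bf_result(
    log_bf10 = log_marg - ll0, log_marginal_h1 = log_marg,
    log_lik_h0 = ll0, prior = prior, numerics = numerics
  )
}

#' Savage-Dickey Normal-approximation Bayes factor
#'
#' Fast closed-form comparator: the likelihood for the log hazard ratio
#' is approximated by a Normal with mean \eqn{\hat\beta} and standard
#' deviation \eqn{SE(\hat\beta)}. With a two-sided Normal prior
#' \eqn{N(\mu, \sigma^2)} the Savage-Dickey density ratio gives the
#' closed form
#' \deqn{BF_{01} = \sqrt{\frac{\sigma^2 + SE^2}{SE^2}}
#'   \exp\!\left(-\tfrac12\left[\frac{(\hat\beta - \beta_0)^2}{SE^2}
#'   - \frac{(\hat\beta - \mu)^2}{\sigma^2 + SE^2}\right]\right).}
#' For one-sided priors the ratio of truncated prior to truncated
#' (conjugate Normal) posterior ordinates at \eqn{\beta_0} is used; the
#' closed form above is its two-sided special case.
#'
#' @param beta_hat Maximum likelihood estimate of the log hazard ratio.
#' @param se Its standard error (> 0).
#' @param prior A [prior_spec] object.
#'
#' @return An object of class `bf_result` (marginal-likelihood components
#'   are `NA`: the approximation works on density ordinates).
#'
#' @examples
#' savage_dickey_bf(0.27, 0.073, prior_spec(0, 1, side = "greater"))
#' @export
savage_dickey_bf <- function(beta_hat, se, prior) {
  if (!is.numeric(beta_hat) || length(beta_hat) != 1L ||
      !is.finite(beta_hat)) {
    stop_invalid("beta_hat must be a finite numeric scalar")
  }
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se <= 0) {
    stop_invalid("se must be a positive numeric scalar")
  }
  if (!inherits(prior, "prior_spec")) {
    stop_invalid("prior must be a prior_spec object")
  }
  mu <- prior$mu; s2 <- prior$sigma^2; v <- se^2; b0 <- prior$beta0
  if (prior$side == "two_sided") {
    log_bf01 <- 0.5 * log((s2 + v) / v) -
      0.5 * ((beta_hat - b0)^2 / v - (beta_hat - mu)^2 / (s2 + v))
    log_bf10 <- -log_bf01
  } else {
    # conjugate-Normal posterior for beta under the Normal likelihood
    post_var <- 1 / (1 / v + 1 / s2)
    post_mean <- post_var * (beta_hat / v + mu / s2)
    lower_tail <- prior$side == "less"
    log_prior_ord <- stats::dnorm(b0, mu, prior$sigma, log = TRUE) -
      prior$log_mass
    log_post_mass <- stats::pnorm(b0, post_mean, sqrt(post_var),
                                  lower.tail = lower_tail, log.p = TRUE)
    log_post_ord <- stats::dnorm(b0, post_mean, sqrt(post_var),
                                 log = TRUE) - log_post_mass
    log_bf10 <- log_prior_ord - log_post_ord
  }
  new_bf_result(
    log_bf10 = log_bf10, log_marginal_h1 = NA_real_,
    log_lik_h0 = NA_real_, prior = prior,
    numerics = list(method = "savage_dickey_closed_form", nodes = 0L,
                    abs_error = 0)
  )
}

new_bf_result <- function(log_bf10, log_marginal_h1, log_lik_h0, prior,
                          numerics) {
  structure(
    list(
      bf10 = exp(log_bf10), log_bf10 = log_bf10,
      log_marginal_h1 = log_marginal_h1, log_lik_h0 = log_lik_h0,
      prior = prior, numerics = numerics
    ),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.6g  (log BF10 = %.6g)  [%s]\n",
              x$bf10, x$log_bf10, x$numerics$method))
  for (s in c("jeffreys", "lee_wagenmakers", "kass_raftery")) {
    lab <- classify_evidence(x$bf10, s)
    cat(sprintf("  %-16s %s evidence%s\n", paste0(s, ":"),
                as.character(lab),
                switch(attr(lab, "direction"),
                       none = "", h1 = " for H1", h0 = " for H0")))
  }
  print(x$prior)
  invisible(x)
}

#' Classify a Bayes factor into an evidence category
#'
#' Maps a Bayes factor to the qualitative evidence label of a published
#' classification scheme. Values below 1 are classified through their
#' reciprocal with the direction flagged toward the null.
#'
#' @param bf10 Positive Bayes factor for H1 over H0.
#' @param scheme `"jeffreys"`, `"lee_wagenmakers"` (thresholds
#'   1, 3, 10, 30, 100), or `"kass_raftery"` (thresholds 1, 3, 20, 150).
#'
#' @return The category label (character), with attribute `direction`
#'   (`"h1"`, `"h0"`, or `"none"`).
#'
#' @examples
#' classify_evidence(134.4, "jeffreys")       # "decisive"
#' classify_evidence(0.1, "lee_wagenmakers")  # "strong", toward H0
#' @export
classify_evidence <- function(bf10,
                              scheme = c("jeffreys", "lee_wagenmakers",
                                         "kass_raftery")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(bf10) || length(bf10) != 1L || !is.finite(bf10) ||
      bf10 <= 0) {
    stop_invalid("bf10 must be a positive finite number")
  }
  if (bf10 == 1) {
    return(structure("no evidence", direction = "none", scheme = scheme))
  }
  direction <- if (bf10 > 1) "h1" else "h0"
  b <- max(bf10, 1 / bf10)
  label <- switch(scheme,
    jeffreys = if (b >= 100) "decisive" else if (b >= 30) "very strong"
      else if (b >= 10) "strong" else if (b >= 3) "substantial"
      else "not worth more than a bare mention",
    lee_wagenmakers = if (b >= 100) "extreme" else if (b >= 30) "very strong"
      else if (b >= 10) "strong" else if (b >= 3) "moderate"
      else "anecdotal",
    kass_raftery = if (b >= 150) "very strong" else if (b >= 20) "strong"
      else if (b >= 3) "positive" else "not worth more than a bare mention"
  )
  structure(label, direction = direction, scheme = scheme)
}
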
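#' Normal prior specification for the log hazard ratio
#'
#' A (possibly truncated) Normal prior on the log hazard ratio
#' \eqn{\beta} under the alternative hypothesis. One-sided alternatives
#' truncate the Normal to \eqn{\beta > \beta_0} (`"greater"`, a
#' superiority hypothesis) or \eqn{\beta < \beta_0} (`"less"`) and
#' renormalize the density on that region.
#'
#' @param mu Prior mean.
#' @param sigma Prior standard deviation (> 0).
#' @param side One of `"two_sided"`, `"greater"`, `"less"`, defining the
#'   support of the alternative.
#' @param beta0 Null value of the log hazard ratio (default 0, i.e. equal
#'   hazards).
#'
#' @return An object of class `prior_spec`.
#'
#' @examples
#' prior_spec(0, 1, side = "greater")  # one-sided H1: beta > 0
#' @export
prior_spec <- function(mu = 0, sigma = 1,
                       side = c("two_sided", "greater", "less"),
                       beta0 = 0) {
  side <- match.arg(side)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop_invalid("mu must be a finite numeric scalar")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop_invalid("sigma must be a positive numeric scalar")
  }
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0)) {
    stop_invalid("beta0 must be a finite numeric scalar")
  }
  bounds <- switch(side,
    two_sided = c(-Inf, Inf),
    greater = c(beta0, Inf),
    less = c(-Inf, beta0)
  )
  # log prior mass of the untruncated Normal on the support
  log_mass <- switch(side,
    two_sided = 0,
    greater = stats::pnorm(beta0, mu, sigma, lower.tail = FALSE,
                           log.p = TRUE),
    less = stats::pnorm(beta0, mu, sigma, lower.tail = TRUE, log.p = TRUE)
  )
  if (!is.finite(log_mass)) {
    stop_invalid("prior mass on the alternative region is zero")
  }
  structure(
    list(mu = mu, sigma = sigma, side = side, beta0 = beta0,
         lower = bounds[1], upper = bounds[2], log_mass = log_mass),
    class = "prior_spec"
  )
}

# Truncated-Normal prior density on the alternative region (0 outside).
prior_density <- function(beta, prior, log = FALSE) {
  ld <- stats::dnorm(beta, prior$mu, prior$sigma, log = TRUE) -
    prior$log_mass
  ld[beta < prior$lower | beta > prior$upper] <- -Inf
  if (log) ld else exp(ld)
}

#' @export
print.prior_spec <- function(x, ...) {
  region <- switch(x$side,
    two_sided = "beta unrestricted",
    greater = sprintf("beta > %g", x$beta0),
    less = sprintf("beta < %g", x$beta0)
  )
  cat(sprintf(
    "Prior on log hazard ratio: Normal(mu = %g, sigma = %g), %s (null: beta = %g)\n",
    x$mu, x$sigma, region, x$beta0
  ))
  invisible(x)
}
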
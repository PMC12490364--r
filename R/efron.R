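# Efron partial-likelihood machinery for a single binary covariate.
#
# All risk-set quantities reduce to counts because exp(beta * x) takes only
# two values; the per-distinct-event-time structure below is computed once
# per dataset and reused across beta values (Newton-Raphson, quadrature,
# and the PSO loss all evaluate the likelihood many times).

# Aggregate a dataset into the sufficient structure for Efron's formula:
# per distinct event time k, the numbers at risk per group (subjects with
# time >= t_k; ties between events and censorings keep the censored subject
# in the risk set), the tied event counts per group, and the expanded tie
# positions l/d for l = 0..d-1.
efron_structure <- function(time, event, group) {
  ut <- sort(unique(time))
  k <- match(time, ut)
  m <- length(ut)
  # subjects entering the risk set at each distinct time, per group
  n0_at <- tabulate(k[group == 0], nbins = m)
  n1_at <- tabulate(k[group == 1], nbins = m)
  n0_risk <- rev(cumsum(rev(n0_at)))
  n1_risk <- rev(cumsum(rev(n1_at)))
  ev <- event == 1
  d0 <- tabulate(k[ev & group == 0], nbins = m)
  d1 <- tabulate(k[ev & group == 1], nbins = m)
  d <- d0 + d1
  keep <- d > 0L
  d0 <- d0[keep]; d1 <- d1[keep]; d <- d[keep]
  n0_risk <- n0_risk[keep]; n1_risk <- n1_risk[keep]
  # tie-position expansion: row j repeated d_j times with fractions l/d_j
  row <- rep.int(seq_along(d), d)
  frac <- (sequence(d) - 1) / rep.int(d, d)
  list(
    n_events = sum(d), d1_total = sum(d1),
    n0_risk = n0_risk, n1_risk = n1_risk,
    d0 = d0, d1 = d1,
    row = row, frac = frac
  )
}

# Log partial likelihood, score and observed information at beta, from a
# precomputed structure. For binary x the second risk-set moment equals the
# first, which collapses the information term to B/A * (1 - B/A).
efron_eval <- function(st, beta) {
  if (st$n_events == 0L) {
    return(list(loglik = 0, score = 0, info = 0))
  }
  eb <- exp(beta)
  S0 <- st$n0_risk + st$n1_risk * eb
  S1 <- st$n1_risk * eb
  D0 <- st$d0 + st$d1 * eb
  D1 <- st$d1 * eb
  A <- S0[st$row] - st$frac * D0[st$row]
  B <- S1[st$row] - st$frac * D1[st$row]
  ratio <- B / A
  ll <- beta * st$d1_total - sum(log(A))
  if (is.nan(ll)) ll <- -Inf  # exp(beta) overflow far in a tail
  list(
    loglik = ll,
    score = st$d1_total - sum(ratio),
    info = sum(ratio * (1 - ratio))
  )
}

#' Efron log partial likelihood
#'
#' Evaluates the log of Efron's approximation to the Cox partial likelihood
#' for the two-group model \eqn{\lambda(t \mid x) = \lambda(t) e^{x\beta}}
#' at a given log hazard ratio \eqn{\beta}. At each distinct event time
#' with \eqn{d} tied events, the denominator at tie position
#' \eqn{l \in \{0, \dots, d-1\}} subtracts the fraction \eqn{l/d} of the
#' tied subjects' risk contributions. With no tied event times this equals
#' the exact Cox partial likelihood.
#'
#' @param data A [survival_data] object.
#' @param beta Finite numeric scalar, the log hazard ratio.
#'
#' @return The log partial likelihood (0 for a dataset with no events).
#'
#' @examples
#' d <- survival_data(c(1, 2, 3, 4), c(1, 0, 0, 0), c(0, 1, 0, 1))
#' efron_loglik(d, 0)  # single event, 4 at risk: -log(4)
#' @export
efron_loglik <- function(data, beta) {
  if (!inherits(data, "survival_data")) {
    stop_invalid("data must be a survival_data object")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop_invalid("beta must be a finite numeric scalar")
  }
  st <- efron_structure(data$time, data$event, data$group)
  efron_eval(st, beta)$loglik
}
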
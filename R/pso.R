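#' Particle swarm minimization (SPSO-2007-style)
#'
#' Self-contained standard particle swarm optimizer for box-constrained,
#' derivative-free minimization, with the canonical SPSO-2007 defaults:
#' swarm size \eqn{\lfloor 10 + 2\sqrt{d} \rfloor}, inertia
#' \eqn{1/(2\ln 2)}, cognitive and social coefficients
#' \eqn{0.5 + \ln 2}, an adaptive random informant topology (each
#' particle informs itself and on average 3 others, links redrawn after
#' a non-improving iteration), and reflecting bound handling (a particle
#' crossing a bound is reflected back with its velocity component
#' reversed).
#'
#' @param fn Scalar objective; may return `Inf` for infeasible points.
#' @param lower,upper Bound vectors defining the search box.
#' @param max_iter Maximum number of iterations.
#' @param patience Stop after this many consecutive iterations without a
#'   reduction of the best loss (default: one fifth of `max_iter`).
#' @param swarm_size Number of particles (default
#'   \eqn{\lfloor 10 + 2\sqrt{d} \rfloor}).
#' @param init Optional matrix of initial positions (rows), e.g. a known
#'   feasible starting point; evaluated as part of the initial swarm.
#'
#' @return List with `par` (best position), `value` (best loss), `trace`
#'   (best-so-far loss after each iteration, including iteration 0), and
#'   `iterations` (number performed).
#'
#' @details The caller controls reproducibility through R's global RNG
#'   (`set.seed` before the call).
#' @export
pso_minimize <- function(fn, lower, upper, max_iter = 300L,
                         patience = ceiling(max_iter / 5),
                         swarm_size = NULL, init = NULL) {
  d <- length(lower)
  if (length(upper) != d || any(upper < lower)) {
    stop_invalid("lower/upper must be conformable bounds with upper >= lower")
  }
  if (max_iter < 1L) stop_invalid("max_iter must be positive")
  S <- if (is.null(swarm_size)) floor(10 + 2 * sqrt(d)) else as.integer(swarm_size)
  if (S < 2L) S <- 2L
  span <- upper - lower

  X <- matrix(stats::runif(S * d), S, d) * rep(span, each = S) +
    rep(lower, each = S)
  if (!is.null(init)) {
    init <- rbind(init)
    k <- min(nrow(init), S)
    for (i in seq_len(k)) X[i, ] <- pmin(pmax(init[i, ], lower), upper)
  }
  V <- (matrix(stats::runif(S * d), S, d) * rep(span, each = S) +
          rep(lower, each = S) - X) / 2

  fvals <- apply(X, 1L, fn)
  P <- X                       # personal bests
  pbest <- fvals
  g <- which.min(pbest)
  gbest <- pbest[g]
  gpar <- P[g, ]

  w <- 1 / (2 * log(2))
  c_acc <- 0.5 + log(2)
  p_link <- 1 - (1 - 1 / S)^3  # ~3 informees per particle on average
  links <- NULL
  stall <- 0L
  trace <- numeric(max_iter + 1L)
  trace[1L] <- gbest
  iters <- 0L

  for (it in seq_len(max_iter)) {
    if (is.null(links)) {
      links <- matrix(stats::runif(S * S) < p_link, S, S)
      diag(links) <- TRUE
    }
    improved <- FALSE
    for (i in seq_len(S)) {
      informants <- which(links[, i])
      b <- informants[which.min(pbest[informants])]
      V[i, ] <- w * V[i, ] +
        c_acc * stats::runif(d) * (P[i, ] - X[i, ]) +
        c_acc * stats::runif(d) * (P[b, ] - X[i, ])
      x <- X[i, ] + V[i, ]
      # reflect off the box; clamp guards pathological overshoots
      lo_hit <- x < lower
      if (any(lo_hit)) {
        x[lo_hit] <- 2 * lower[lo_hit] - x[lo_hit]
        V[i, lo_hit] <- -V[i, lo_hit]
      }
      hi_hit <- x > upper
      if (any(hi_hit)) {
        x[hi_hit] <- 2 * upper[hi_hit] - x[hi_hit]
        V[i, hi_hit] <- -V[i, hi_hit]
      }
      x <- pmin(pmax(x, lower), upper)
      X[i, ] <- x
      f <- fn(x)
      fvals[i] <- f
      if (f < pbest[i]) {
        pbest[i] <- f
        P[i, ] <- x
        if (f < gbest) {
          gbest <- f
          gpar <- x
          improved <- TRUE
        }
      }
    }
    iters <- it
    trace[it + 1L] <- gbest
    if (improved) {
      stall <- 0L
    } else {
      stall <- stall + 1L
      links <- NULL  # redraw the informant topology after stagnation
      if (stall >= patience) break
    }
  }
  list(par = gpar, value = gbest, trace = trace[seq_len(iters + 1L)],
       iterations = iters)
}
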
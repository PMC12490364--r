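#' Loss specification for summary-statistic reconstruction
#'
#' Names the summary statistics the reconstruction matches (the target
#' vector E) and their non-negative weights. The default configuration —
#' hazard ratio weighted twice as much as its confidence bounds, with
#' Kaplan-Meier statistics excluded — is the recommended one: including
#' KM measures increases both the bias and the variance of the resulting
#' Bayes factors.
#'
#' @param targets Character vector drawn from `"hr"`, `"hr_ci_lower"`,
#'   `"hr_ci_upper"`, `"km_c"`, `"km_c_lb"`, `"km_c_ub"`, `"km_e"`,
#'   `"km_e_lb"`, `"km_e_ub"`.
#' @param weights Non-negative weights, one per target, at least one
#'   positive.
#' @param epsilon_floor Small positive floor applied inside the log of
#'   the loss so a perfect match returns `log(epsilon_floor)` rather
#'   than `-Inf`.
#'
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(targets = c("hr", "hr_ci_lower", "hr_ci_upper"),
                      weights = c(2, 1, 1), epsilon_floor = 1e-300) {
  valid <- c("hr", "hr_ci_lower", "hr_ci_upper",
             "km_c", "km_c_lb", "km_c_ub", "km_e", "km_e_lb", "km_e_ub")
  if (length(targets) < 1L || !all(targets %in% valid)) {
    stop_invalid(paste0("targets must be drawn from: ",
                        paste(valid, collapse = ", ")))
  }
  if (anyDuplicated(targets)) stop_invalid("duplicate targets")
  if (length(weights) != length(targets)) {
    stop_invalid("weights must align with targets")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || all(weights == 0)) {
    stop_invalid("weights must be non-negative with at least one positive")
  }
  if (!is.finite(epsilon_floor) || epsilon_floor <= 0) {
    stop_invalid("epsilon_floor must be a small positive number")
  }
  structure(
    list(targets = targets, weights = as.numeric(weights),
         epsilon_floor = epsilon_floor),
    class = "loss_spec"
  )
}

uses_km <- function(spec) any(startsWith(spec$targets, "km"))

# Target vector E extracted from published summary statistics, aligned
# with spec$targets.
expected_stats <- function(stats, spec) {
  e <- unlist(stats[spec$targets])
  if (anyNA(e)) {
    stop_invalid(sprintf(
      "summary statistics do not provide every loss target (missing: %s)",
      paste(spec$targets[is.na(e)], collapse = ", ")
    ))
  }
  e
}

#' Observed summary statistics of a candidate dataset
#'
#' Computes, on a dataset, the same kinds of summary statistics named in
#' a [loss_spec]: hazard-ratio entries from [fit_cox] and Kaplan-Meier
#' entries from per-group [km_summary].
#'
#' @param data A [survival_data] object.
#' @param spec A [loss_spec].
#' @param conf_level Confidence level for the intervals.
#'
#' @return Named numeric vector O aligned with `spec$targets`.
#' @export
compute_observed_stats <- function(data, spec, conf_level = 0.95) {
  if (!inherits(spec, "loss_spec")) {
    stop_invalid("spec must be a loss_spec object")
  }
  out <- numeric(0)
  if (any(startsWith(spec$targets, "hr"))) {
    fit <- fit_cox(data, conf_level)
    out <- c(out, hr = fit$hr, hr_ci_lower = fit$ci_lower,
             hr_ci_upper = fit$ci_upper)
  }
  if (uses_km(spec)) {
    kc <- km_summary(data$time[data$group == 0],
                     data$event[data$group == 0], conf_level)
    ke <- km_summary(data$time[data$group == 1],
                     data$event[data$group == 1], conf_level)
    out <- c(out, km_c = kc$median, km_c_lb = kc$ci_lower,
             km_c_ub = kc$ci_upper, km_e = ke$median,
             km_e_lb = ke$ci_lower, km_e_ub = ke$ci_upper)
  }
  out[spec$targets]
}

#' Reconstruction loss for a candidate time adjustment
#'
#' Evaluates the loss \eqn{\phi(\xi) = \log\big[\frac{1}{|E|}\sum_r
#' ((O_r - E_r)/E_r \cdot w_r)^2\big]} where the candidate times are
#' \eqn{Y' = e^{\xi} \circ Y} (elementwise) and O holds the summary
#' statistics of the candidate dataset. Each \eqn{\xi_i} is bounded in
#' \eqn{[\log(1/Y_i), \log(t_{max}/Y_i)]} so candidate times stay in
#' \eqn{[1, t_{max}]}. The mean squared term is floored at
#' `epsilon_floor` before the log.
#'
#' @param xi Numeric vector of per-subject log time adjustments.
#' @param base The base [survival_data] whose times are adjusted (event
#'   and group indicators are kept as-is).
#' @param stats A [summary_stats] object providing the targets E.
#' @param spec A [loss_spec].
#'
#' @return The scalar loss \eqn{\phi}.
#' @export
reconstruction_loss <- function(xi, base, stats, spec) {
  if (!inherits(base, "survival_data")) {
    stop_invalid("base must be a survival_data object")
  }
  if (!inherits(stats, "summary_stats")) {
    stop_invalid("stats must be a summary_stats object")
  }
  n <- nrow(base)
  if (length(xi) != n || any(!is.finite(xi))) {
    stop_invalid(sprintf("xi must be a finite vector of length %d", n))
  }
  tmax <- effective_tmax(stats, spec)
  tol <- 1e-8
  if (any(xi < log(1 / base$time) - tol) ||
      any(xi > log(tmax / base$time) + tol)) {
    stop_invalid("xi outside the per-coordinate bounds [log(1/Y), log(tmax/Y)]")
  }
  loss_function(base, stats, spec)(xi)
}

# tmax actually used in reconstruction: the reported one when available,
# else 1000 — with hazard-ratio-only targets the choice is irrelevant
# because the partial likelihood is rank-based.
effective_tmax <- function(stats, spec) {
  if (!is.na(stats$tmax)) stats$tmax else 1000
}

# Fast closure evaluating the loss for many xi on a fixed base dataset.
# Candidate datasets that cannot be fitted (divergent or degenerate Cox
# fits) score +Inf, which the swarm simply avoids.
loss_function <- function(base, stats, spec) {
  E <- expected_stats(stats, spec)
  w <- spec$weights
  eps <- spec$epsilon_floor
  time0 <- base$time
  event <- base$event
  group <- base$group
  conf_level <- stats$conf_level
  km <- uses_km(spec)
  needs_hr <- any(startsWith(spec$targets, "hr"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  function(xi) {
    times <- exp(xi) * time0
    O <- tryCatch({
      o <- numeric(0)
      if (needs_hr) {
        st <- efron_structure(times, event, group)
        fit <- cox_newton(st)
        o <- c(o, hr = exp(fit$beta),
               hr_ci_lower = exp(fit$beta - z * fit$se),
               hr_ci_upper = exp(fit$beta + z * fit$se))
      }
      if (km) {
        kc <- km_summary(times[group == 0], event[group == 0], conf_level)
        ke <- km_summary(times[group == 1], event[group == 1], conf_level)
        o <- c(o, km_c = kc$median, km_c_lb = kc$ci_lower,
               km_c_ub = kc$ci_upper, km_e = ke$median,
               km_e_lb = ke$ci_lower, km_e_ub = ke$ci_upper)
      }
      o[spec$targets]
    }, coxbf_error = function(e) NULL)
    if (is.null(O) || anyNA(O)) return(Inf)
    log(max(mean(((O - E) / E * w)^2), eps))
  }
}
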
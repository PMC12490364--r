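#' Published summary statistics of a two-group survival study
#'
#' Container for the statistics a published article typically reports
#' about a two-group time-to-event comparison, used as the target of the
#' pseudo-raw-data reconstruction: per-group sample sizes and event
#' counts, the Cox hazard ratio with its confidence interval, optionally
#' per-group Kaplan-Meier median survival times with confidence
#' intervals, and the maximum observed (or possible) time.
#'
#' @param nc,ne Per-group sample sizes (control, experimental).
#' @param vc,ve Per-group event counts.
#' @param tmax Maximum observed/possible time. Required when any
#'   Kaplan-Meier statistic is supplied; irrelevant (and defaulted at
#'   reconstruction time) when only hazard-ratio statistics are used.
#' @param hr Hazard ratio; `hr_ci_lower`, `hr_ci_upper` its confidence
#'   bounds.
#' @param km_c,km_c_lb,km_c_ub Control-group Kaplan-Meier median and CI.
#' @param km_e,km_e_lb,km_e_ub Experimental-group median and CI.
#' @param conf_level Level of the reported intervals.
#'
#' @return An object of class `summary_stats`.
#'
#' @examples
#' summary_stats(nc = 60, ne = 60, vc = 42, ve = 40,
#'               hr = 1.45, hr_ci_lower = 1.02, hr_ci_upper = 2.06)
#' @export
summary_stats <- function(nc, ne, vc, ve, tmax = NA_real_,
                          hr = NA_real_, hr_ci_lower = NA_real_,
                          hr_ci_upper = NA_real_,
                          km_c = NA_real_, km_c_lb = NA_real_,
                          km_c_ub = NA_real_,
                          km_e = NA_real_, km_e_lb = NA_real_,
                          km_e_ub = NA_real_,
                          conf_level = 0.95) {
  if (nc < 1 || ne < 1) stop_invalid("sample sizes must be positive")
  if (vc < 0 || ve < 0 || vc > nc || ve > ne) {
    stop_invalid("event counts must satisfy 0 <= vc <= nc and 0 <= ve <= ne")
  }
  ci_ok <- function(est, lb, ub) {
    is.na(est) || ((is.na(lb) || lb <= est) && (is.na(ub) || ub >= est))
  }
  if (!ci_ok(hr, hr_ci_lower, hr_ci_upper) ||
      !ci_ok(km_c, km_c_lb, km_c_ub) || !ci_ok(km_e, km_e_lb, km_e_ub)) {
    stop_invalid("confidence bounds must bracket their point estimate")
  }
  km_any <- !all(is.na(c(km_c, km_c_lb, km_c_ub, km_e, km_e_lb, km_e_ub)))
  if (km_any && is.na(tmax)) {
    stop_invalid("tmax is required when Kaplan-Meier statistics are used")
  }
  if (all(is.na(c(hr, hr_ci_lower, hr_ci_upper))) && !km_any) {
    stop_invalid("at least one of the hazard-ratio or Kaplan-Meier statistics must be supplied")
  }
  if (!is.na(tmax) && (!is.finite(tmax) || tmax <= 1)) {
    stop_invalid("tmax must exceed 1 (reconstructed times live in [1, tmax])")
  }
  structure(
    list(nc = as.integer(nc), ne = as.integer(ne),
         vc = as.integer(vc), ve = as.integer(ve), tmax = tmax,
         hr = hr, hr_ci_lower = hr_ci_lower, hr_ci_upper = hr_ci_upper,
         km_c = km_c, km_c_lb = km_c_lb, km_c_ub = km_c_ub,
         km_e = km_e, km_e_lb = km_e_lb, km_e_ub = km_e_ub,
         conf_level = conf_level),
    class = "summary_stats"
  )
}

#' Summary statistics computed from a full dataset
#'
#' Convenience wrapper that fits the Cox model (and, when requested, the
#' per-group Kaplan-Meier medians) on an existing dataset and packages
#' the results as a [summary_stats] object — the "as if only the paper's
#' numbers were available" starting point for reconstruction.
#'
#' @param data A [survival_data] object.
#' @param include_km Also compute per-group Kaplan-Meier medians and CIs
#'   (sets `tmax` to the maximum observed time).
#' @param conf_level Confidence level for all intervals.
#'
#' @return A [summary_stats] object.
#' @export
summarize_survival <- function(data, include_km = FALSE,
                               conf_level = 0.95) {
  fit <- fit_cox(data, conf_level)
  args <- list(
    nc = sum(data$group == 0), ne = sum(data$group == 1),
    vc = sum(data$event == 1 & data$group == 0),
    ve = sum(data$event == 1 & data$group == 1),
    hr = fit$hr, hr_ci_lower = fit$ci_lower, hr_ci_upper = fit$ci_upper,
    conf_level = conf_level
  )
  if (include_km) {
    kc <- km_summary(data$time[data$group == 0],
                     data$event[data$group == 0], conf_level)
    ke <- km_summary(data$time[data$group == 1],
                     data$event[data$group == 1], conf_level)
    args <- c(args, list(
      tmax = max(data$time),
      km_c = kc$median, km_c_lb = kc$ci_lower, km_c_ub = kc$ci_upper,
      km_e = ke$median, km_e_lb = ke$ci_lower, km_e_ub = ke$ci_upper
    ))
  }
  do.call(summary_stats, args)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary statistics: nc = %d (vc = %d), ne = %d (ve = %d)\n",
              x$nc, x$vc, x$ne, x$ve))
  if (!is.na(x$hr)) {
    cat(sprintf("  HR = %.6g  %g%% CI [%.6g, %.6g]\n", x$hr,
                100 * x$conf_level, x$hr_ci_lower, x$hr_ci_upper))
  }
  if (!is.na(x$km_c) || !is.na(x$km_e)) {
    cat(sprintf("  KM medians: control %.6g [%.6g, %.6g], experimental %.6g [%.6g, %.6g]\n",
                x$km_c, x$km_c_lb, x$km_c_ub, x$km_e, x$km_e_lb, x$km_e_ub))
  }
  if (!is.na(x$tmax)) cat(sprintf("  tmax = %.6g\n", x$tmax))
  invisible(x)
}
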
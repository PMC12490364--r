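#' Kaplan-Meier survival summary for one sample
#'
#' Product-limit estimate of the survival function with the median
#' survival time and its confidence interval. The median is the first
#' time at which the estimated curve drops to 0.5 or below; the interval
#' is the Brookmeyer-Crowley construction on the log-survival variance
#' scale (the common default in survival software), delegated to
#' [survival::survfit].
#'
#' @param time Positive observed times.
#' @param event 0/1 event indicators.
#' @param conf_level Confidence level for the median interval.
#' @param conf_type Variance transformation for the interval, passed to
#'   [survival::survfit] (`"log"` by default).
#'
#' @return An object of class `km_estimate` with components `median`,
#'   `ci_lower`, `ci_upper` (each `NA` when the curve never reaches 0.5)
#'   and `curve`, a data frame of `(time, surv)` step-function values.
#'
#' @examples
#' km_summary(c(1, 2, 3, 4, 5), c(1, 1, 1, 1, 1))$median  # 3
#' @export
km_summary <- function(time, event, conf_level = 0.95, conf_type = "log") {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) < 1L || length(event) != length(time)) {
    stop_invalid("time and event must be non-empty vectors of equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_invalid("times must be strictly positive and finite")
  }
  if (!all(event %in% c(0, 1))) {
    stop_invalid("event indicators must be 0 or 1")
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    conf.int = conf_level, conf.type = conf_type
  )
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  structure(
    list(
      median = med,
      ci_lower = unname(q$lower),
      ci_upper = unname(q$upper),
      conf_level = conf_level,
      curve = data.frame(time = fit$time, surv = fit$surv)
    ),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  if (is.na(x$median)) {
    cat("Kaplan-Meier median: not reached (curve stays above 0.5)\n")
  } else {
    cat(sprintf("Kaplan-Meier median: %.6g  %g%% CI [%.6g, %.6g]\n",
                x$median, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  }
  invisible(x)
}
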
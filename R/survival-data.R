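#' Two-group right-censored survival data
#'
#' Bundles observed times, event indicators and a binary group indicator
#' into a validated container used by every fitting and Bayes-factor
#' routine in the package.
#'
#' @param time Numeric vector of strictly positive, finite observed times
#'   (event or censoring time per subject).
#' @param event Integer/numeric vector of 0/1 event indicators (1 = event
#'   observed, 0 = right-censored).
#' @param group Integer/numeric vector of 0/1 condition indicators
#'   (0 = control, 1 = experimental).
#'
#' @return An object of class `survival_data`: a data frame with columns
#'   `time`, `event`, `group`.
#'
#' @examples
#' d <- survival_data(c(5, 8, 2, 9), c(1, 0, 1, 1), c(0, 0, 1, 1))
#' d
#' @export
survival_data <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  group <- as.numeric(group)
  n <- length(time)
  if (n < 2L) {
    stop_invalid("survival data needs at least 2 subjects")
  }
  if (length(event) != n || length(group) != n) {
    stop_invalid("time, event and group must have equal length")
  }
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0)) {
    stop_invalid("times must be strictly positive and finite")
  }
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    stop_invalid("event indicators must be 0 or 1")
  }
  if (anyNA(group) || !all(group %in% c(0, 1))) {
    stop_invalid("group indicators must be 0 or 1")
  }
  structure(
    data.frame(time = time, event = event, group = group),
    class = c("survival_data", "data.frame")
  )
}

#' @export
print.survival_data <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "Two-group survival data: n = %d (%d control, %d experimental), %d events (%.0f%% censored)\n",
    n, sum(x$group == 0), sum(x$group == 1), sum(x$event),
    100 * mean(x$event == 0)
  ))
  NextMethod()
  invisible(x)
}

# Both groups present and at least one event: required by every
# two-group fitting operation.
check_two_group <- function(data) {
  if (length(unique(data$group)) < 2L) {
    stop_invalid("both groups must be present")
  }
  invisible(data)
}
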
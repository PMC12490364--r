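#' @keywords internal
stop_coxbf <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "coxbf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_invalid <- function(msg, ...) {
  stop_coxbf(msg, "coxbf_invalid_argument", ...)
}

stop_no_information <- function(msg, ...) {
  stop_coxbf(msg, "coxbf_no_information", ...)
}

stop_divergence <- function(msg, ...) {
  stop_coxbf(msg, "coxbf_divergence", ...)
}

stop_numerical <- function(msg, ...) {
  stop_coxbf(msg, "coxbf_numerical", ...)
}
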
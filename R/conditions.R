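# Structured conditions so the CLI layer can map failures to exit codes.

rl_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rl_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
stop_validation <- function(message) rl_abort(message, "rl_validation_error")

#' @noRd
stop_no_solution <- function(message) rl_abort(message, "rl_no_solution_error")

#' @noRd
stop_domain <- function(message) rl_abort(message, "rl_domain_error")
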
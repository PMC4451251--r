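#' Signal a classed keyfusion error
#'
#' All user-facing failures are signalled with subclasses of
#' `keyfusion_error` so that callers (and the command-line wrapper) can map
#' them to exit codes: validation problems are `keyfusion_validation_error`,
#' stage failures `keyfusion_stage_error`.
#'
#' @param msg message, passed through [sprintf()] when `...` supplied.
#' @param class additional condition subclass.
#' @param ... sprintf arguments.
#' @keywords internal
kf_stop <- function(msg, ..., class = "keyfusion_error") {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "keyfusion_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

kf_validation_error <- function(msg, ...) {
  kf_stop(msg, ..., class = "keyfusion_validation_error")
}

kf_stage_error <- function(msg, ...) {
  kf_stop(msg, ..., class = "keyfusion_stage_error")
}

#' @keywords internal
kf_assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) kf_validation_error(msg, ...)
  invisible(TRUE)
}
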
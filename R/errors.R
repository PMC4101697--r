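#' Error conditions used throughout the registry
#'
#' All failures raised by omicslog are classed conditions so that callers
#' (and the command-line interface) can react to the failure mode rather
#' than parse messages:
#'
#' * `ems_validation_error` -- an entity violates a structural invariant,
#'   or an argument is malformed.
#' * `ems_permission_error` -- the acting user lacks the right to perform
#'   the operation (ownership / grant rules).
#' * `ems_not_found_error` -- a referenced identifier does not resolve.
#' * `ems_integrity_error` -- the operation would break referential
#'   integrity (dangling or still-referenced identifiers).
#'
#' Every condition also carries the superclass `ems_error`.
#'
#' @name ems-errors
#' @keywords internal
NULL

ems_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ems_error"), ...)
}

abort_validation <- function(message, report = character()) {
  ems_abort(message, "ems_validation_error", report = report)
}

abort_permission <- function(message) {
  ems_abort(message, "ems_permission_error")
}

abort_not_found <- function(message, id = NULL) {
  ems_abort(message, "ems_not_found_error", id = id)
}

abort_integrity <- function(message, referrers = character()) {
  ems_abort(message, "ems_integrity_error", referrers = referrers)
}

#' Exit status associated with a condition
#'
#' Maps the condition taxonomy to the stable exit codes used by the
#' command-line interface: validation = 2, permission = 3, not-found = 4,
#' integrity = 5. Anything else maps to 1.
#'
#' @param cond A condition object.
#' @return An integer exit status.
#' @keywords internal
ems_exit_status <- function(cond) {
  if (inherits(cond, "ems_validation_error")) return(2L)
  if (inherits(cond, "ems_permission_error")) return(3L)
  if (inherits(cond, "ems_not_found_error")) return(4L)
  if (inherits(cond, "ems_integrity_error")) return(5L)
  1L
}
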
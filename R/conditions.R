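#' Classed error conditions
#'
#' All user-facing failures are signalled as classed conditions so callers
#' (and the command-line front end, which maps them to exit codes) can react
#' programmatically:
#' \itemize{
#'   \item `comfba_format_error` — unparsable model/config file
#'   \item `comfba_model_error` — a model violating a structural invariant
#'   \item `comfba_config_error` — inconsistent community configuration
#'   \item `comfba_infeasible_error` — a solve certified infeasible
#'   \item `comfba_unbounded_error` — a solve certified unbounded
#' }
#' @name comfba-conditions
#' @keywords internal
NULL

abort_comfba <- function(class, message, ...) {
  stop(structure(class = c(class, "comfba_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

abort_format <- function(message, ...) abort_comfba("comfba_format_error", message, ...)
abort_model <- function(message, ...) abort_comfba("comfba_model_error", message, ...)
abort_config <- function(message, ...) abort_comfba("comfba_config_error", message, ...)
abort_infeasible <- function(message, ...) abort_comfba("comfba_infeasible_error", message, ...)
abort_unbounded <- function(message, ...) abort_comfba("comfba_unbounded_error", message, ...)
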
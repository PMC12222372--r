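param_units <- c(f = "mL/min/mL", f_A = "mL/min/mL", f_P = "mL/min/mL",
                 f_p = "mL/min/mL", k = "/min", E = "fraction",
                 V_B = "fraction", dt1 = "s", dt2 = "s")

#' Serialise model parameters to and from JSON
#'
#' Parameters are written with explicit unit strings and the model identity
#' (`1tcm`, `taniguchi`, `rijzewijk`, `new_dual_input`).
#'
#' @param params an `hbf_params` object.
#' @param path optional file; when NULL the JSON string is returned.
#' @return `params_to_json()`: the path (invisibly) or a JSON string;
#'   `params_from_json()`: an `hbf_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "hbf_params"))
  vals <- params[setdiff(names(params), "model")]
  obj <- list(model = params$model,
              params = vals,
              units = as.list(param_units[names(vals)]))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @param json a JSON string or file path.
#' @export
params_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json)
  else jsonlite::fromJSON(json, simplifyVector = FALSE)
  build_params(match.arg(obj$model, model_ids),
               obj$params[setdiff(names(obj$params), c("dt1", "dt2"))],
               obj$params[intersect(names(obj$params), c("dt1", "dt2"))])
}

#' Read a fit configuration from JSON
#'
#' The JSON object mirrors [fit_config()] field for field; missing fields
#' take the defaults.
#'
#' @param path JSON file path.
#' @return A [fit_config()].
#' @export
read_fit_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(fit_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown fit config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(obj$initials)) obj$initials <- as.list(obj$initials)
  do.call(fit_config, obj)
}

#' Write a fit result to JSON
#'
#' Carries the fitted parameters with units, the SSE, the frame metrics and
#' derived quantities, the winning delays, and the delay-grid trace.
#'
#' @param fit an `hbf_fit`.
#' @param path output file.
#' @param include_trace include the per-cell delay grid trace.
#' @export
write_fit_json <- function(fit, path, include_trace = TRUE) {
  stopifnot(inherits(fit, "hbf_fit"))
  vals <- fit$params[setdiff(names(fit$params), "model")]
  obj <- list(model = fit$model,
              params = vals,
              units = as.list(param_units[names(vals)]),
              sse = fit$sse,
              derived = fit$derived,
              metrics = if (!is.null(fit$metrics)) unclass(fit$metrics),
              diagnostics = fit$diagnostics)
  if (include_trace) obj$trace <- fit$trace
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
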
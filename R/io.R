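# JSON serialisation of the package's result objects.

#' Serialise package objects to JSON
#'
#' Converts a curve registry, an [idv_spec()], a [simulate_treatments()]
#' result or a [utility_curve()] to a JSON string (or file). Outcome matrices
#' are omitted from simulation results; only the grid, the refit parameters
#' and the R' vector are kept.
#'
#' @param x Object to serialise.
#' @param path Optional file path; when given the JSON is written there and
#'   the path returned invisibly.
#' @param ... Unused.
#' @return A JSON string (class `json`), or `path` invisibly.
#' @export
idv_json <- function(x, path = NULL, ...) UseMethod("idv_json")

.emit_json <- function(lst, path) {
  if (is.null(path))
    jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}

#' @export
idv_json.dose_response_params <- function(x, path = NULL, ...) {
  .emit_json(list(name = x$name, form = x$form, D50 = x$d50,
                  gamma = x$gamma, role = x$role), path)
}

#' @export
idv_json.list <- function(x, path = NULL, ...) {
  # a registry: named list of dose_response_params
  stopifnot(all(vapply(x, inherits, logical(1), "dose_response_params")))
  .emit_json(lapply(x, function(p)
    list(name = p$name, form = p$form, D50 = p$d50, gamma = p$gamma,
         role = p$role)), path)
}

#' @export
idv_json.idv_spec <- function(x, path = NULL, ...) {
  .emit_json(list(family = x$family, shape_params = as.list(x$shape_params),
                  location = x$location, scale = x$scale,
                  mean_idv = x$mean_idv, sd_idv = x$sd_idv,
                  skewness = x$skewness, rss = x$rss,
                  ad_pvalue = x$ad_pvalue), path)
}

#' @export
idv_json.simulation_result <- function(x, path = NULL, ...) {
  refit <- if (is.null(x$refit_params)) NULL
  else list(D50 = x$refit_params$d50, gamma = x$refit_params$gamma)
  .emit_json(list(curve = x$curve$name, dose_grid = x$dose_grid,
                  refit_params = refit, rprime_curve = x$rprime_curve), path)
}

#' @export
idv_json.utility_curve <- function(x, path = NULL, ...) {
  .emit_json(list(dose_grid = x$dose_grid, utility = x$utility,
                  optimal_dose = x$optimal_dose,
                  rflc_at_optimum = x$rflc_at_optimum), path)
}

#' @export
idv_json.failure_rate_result <- function(x, path = NULL, ...) {
  .emit_json(list(curve = x$curve_name, sampling = x$sampling,
                  replicate_rates = x$replicate_rates,
                  mean_rate = x$mean_rate, sd_rate = x$sd_rate,
                  sigma_from_control = x$sigma_from_control), path)
}
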
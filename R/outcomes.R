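# Event-based treatment failure rates with replicate statistics, local
# control / morbidity probability differences, combined-OAR NTCP and the
# dose-escalation estimate.

#' Pooled treatment failure rate
#'
#' The percentage of non-responses (zeros) among all simulated treatments,
#' pooled over the full dose grid with equal weight. This is the 3-year
#' treatment failure rate of the simulated cohort.
#'
#' @param result A [simulate_treatments()] result, or a binary vector/matrix
#'   of outcomes.
#' @return Failure rate in percent.
#' @export
failure_rate <- function(result) {
  outcomes <- if (inherits(result, "simulation_result")) result$outcomes
  else result
  if (length(outcomes) == 0)
    stop("failure_rate: no outcomes", call. = FALSE)
  100 * mean(outcomes == 0)
}

#' Replicated treatment failure rates
#'
#' Repeats the event simulation `config$n_replicates` times (default 30, to
#' invoke the central limit theorem on the replicate mean) with independent
#' child seeds derived from the master seed, and summarises the replicate
#' failure rates. When a control run is supplied, the mean shift is also
#' expressed in control replicate standard deviations (the sigma-distance).
#'
#' @inheritParams simulate_treatments
#' @param sampling Label for the IDV sampling mode (`"control"`, `"beta"`,
#'   `"snd"`, ...); inferred from `idv_spec` when missing.
#' @param control Optional `failure_rate_result` of the matching control run.
#' @return An object of class `failure_rate_result`: `curve_name`,
#'   `sampling`, `replicate_rates`, `mean_rate`, `sd_rate`,
#'   `sigma_from_control` (NA without a control).
#' @export
replicate_failure_rates <- function(curve, idv_spec = NULL,
                                    config = simulation_config(),
                                    oar_spec = NULL, sampling = NULL,
                                    control = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_replicates < 2)
    stop("replicate_failure_rates: need at least 2 replicates", call. = FALSE)
  if (is.null(sampling))
    sampling <- if (is.null(idv_spec) || idv_spec$family == "point") "control"
    else idv_spec$family
  if (!is.null(config$seed)) set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  rates <- vapply(child, function(s) {
    failure_rate(simulate_treatments(curve, idv_spec, config,
                                     oar_spec = oar_spec, refit = FALSE,
                                     seed = s))
  }, numeric(1))
  out <- structure(list(curve_name = curve$name, sampling = sampling,
                        replicate_rates = rates, mean_rate = mean(rates),
                        sd_rate = stats::sd(rates),
                        sigma_from_control = NA_real_),
                   class = "failure_rate_result")
  if (!is.null(control)) out$sigma_from_control <- sigma_distance(out, control)
  out
}

#' @export
print.failure_rate_result <- function(x, ...) {
  cat(sprintf("<failure_rate_result> %s (%s): %.2f +/- %.2f %% over %d replicates",
              x$curve_name, x$sampling, x$mean_rate, x$sd_rate,
              length(x$replicate_rates)))
  if (!is.na(x$sigma_from_control))
    cat(sprintf(", %.1f sigma from control", x$sigma_from_control))
  cat("\n")
  invisible(x)
}

#' Sigma-distance of a failure rate from its control
#'
#' `(mean_test - mean_control) / sd_control`, using unrounded means and the
#' CONTROL run's replicate SD as the denominator.
#'
#' @param test,control `failure_rate_result` objects (or lists with
#'   `mean_rate`/`sd_rate`).
#' @return Dimensionless standard-deviation count.
#' @export
sigma_distance <- function(test, control) {
  if (control$sd_rate <= 0)
    stop("sigma_distance: control replicate SD is zero", call. = FALSE)
  (test$mean_rate - control$mean_rate) / control$sd_rate
}

#' Welch t-test between two sets of replicate failure rates
#'
#' Two-sample unequal-variance t-test; used to compare Beta-sampled against
#' SND-sampled (or control) replicate failure rates.
#'
#' @param rates_a,rates_b Replicate rate vectors (percent), each of length at
#'   least 2, or `failure_rate_result` objects.
#' @param alternative Passed to [stats::t.test()].
#' @return The p-value.
#' @export
compare_rates_ttest <- function(rates_a, rates_b,
                                alternative = "two.sided") {
  if (inherits(rates_a, "failure_rate_result")) rates_a <- rates_a$replicate_rates
  if (inherits(rates_b, "failure_rate_result")) rates_b <- rates_b$replicate_rates
  if (length(rates_a) < 2 || length(rates_b) < 2)
    stop("compare_rates_ttest: need at least 2 replicates per group",
         call. = FALSE)
  if (stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0)
    stop("compare_rates_ttest: zero variance in both groups", call. = FALSE)
  stats::t.test(rates_a, rates_b, alternative = alternative,
                var.equal = FALSE)$p.value
}

#' Local-control (or morbidity) probability difference at a dose
#'
#' `100 * (R'(dose) - R(dose))` in percentage points, with the convolved
#' curve linearly interpolated on its grid. Negative values mean the IDV
#' uncertainty reduced the response probability at that dose.
#'
#' @param rprime Convolved response probabilities on `dose_grid`.
#' @param reference_curve The reference [dose_response_params()].
#' @param dose Evaluation dose in Gy (must lie within the grid).
#' @param dose_grid Grid the curve lives on.
#' @return Difference in percentage points.
#' @export
lc_difference <- function(rprime, reference_curve, dose, dose_grid) {
  if (dose < min(dose_grid) || dose > max(dose_grid))
    stop("lc_difference: dose outside the curve grid", call. = FALSE)
  rp <- stats::approx(dose_grid, rprime, xout = dose)$y
  # reference is interpolated on the same grid so that R' == R gives exactly 0
  r <- stats::approx(dose_grid, response(dose_grid, reference_curve),
                     xout = dose)$y
  100 * (rp - r)
}

#' Combined organ-at-risk NTCP curve
#'
#' Pointwise arithmetic mean of the per-structure convolved NTCP curves.
#'
#' @param structure_curves List (or matrix columns) of equal-length
#'   probability vectors on a common grid.
#' @return Mean probability vector.
#' @export
combined_oar_curve <- function(structure_curves) {
  if (is.list(structure_curves)) {
    lens <- lengths(structure_curves)
    if (length(unique(lens)) != 1)
      stop("combined_oar_curve: curves differ in length (mismatched grids)",
           call. = FALSE)
    structure_curves <- do.call(cbind, structure_curves)
  }
  rowMeans(structure_curves)
}

#' Iso-complication dose-escalation estimate
#'
#' The reduced morbidity of the convolved OAR NTCP curve permits a higher
#' target dose at equal complication probability. This returns the dose at
#' which `oar_rprime` reaches the reference NTCP's value at `base_dose`
#' (linear interpolation), minus `base_dose`.
#'
#' @param reference_ntcp Reference NTCP probabilities on `dose_grid`.
#' @param oar_rprime Convolved (combined) OAR NTCP probabilities on the same
#'   grid.
#' @param base_dose Baseline dose in Gy, within the grid.
#' @param dose_grid Common dose grid in Gy.
#' @return Escalation in Gy (positive when the convolved curve tolerates a
#'   higher dose).
#' @export
dose_escalation_estimate <- function(reference_ntcp, oar_rprime, base_dose,
                                     dose_grid) {
  if (length(reference_ntcp) != length(dose_grid) ||
      length(oar_rprime) != length(dose_grid))
    stop("dose_escalation_estimate: curves and grid differ in length",
         call. = FALSE)
  if (base_dose < min(dose_grid) || base_dose > max(dose_grid))
    stop("dose_escalation_estimate: base_dose outside grid", call. = FALSE)
  level <- stats::approx(dose_grid, reference_ntcp, xout = base_dose)$y
  if (level < min(oar_rprime) || level > max(oar_rprime))
    stop("dose_escalation_estimate: iso-complication level not bracketed by ",
         "the convolved curve on this grid", call. = FALSE)
  iso <- stats::approx(oar_rprime, dose_grid, xout = level, ties = "ordered")$y
  iso - base_dose
}

#' Failure-rate table across curves and IDV sampling modes
#'
#' Convenience wrapper producing a tidy table of mean/SD failure rates,
#' sigma-distances from the control, and Welch t-test p-values of each
#' non-control mode against the control, for each requested reference curve.
#'
#' @param curves List of [dose_response_params()] (default: the four
#'   reference TCP curves).
#' @param idv_specs Named list of [idv_spec()] objects or `NULL` entries;
#'   the entry named `"control"` (or a `NULL`/point spec) is the control.
#' @param config A [simulation_config()]; its `seed` drives all runs.
#' @return Data frame with one row per curve x sampling mode.
#' @export
failure_rate_table <- function(curves = reference_registry()[1:4],
                               idv_specs = list(control = NULL,
                                                beta = default_beta_spec(),
                                                snd = snd_spec()),
                               config = simulation_config()) {
  rows <- list()
  for (curve in curves) {
    control <- NULL
    results <- list()
    for (mode in names(idv_specs)) {
      res <- replicate_failure_rates(curve, idv_specs[[mode]], config,
                                     sampling = mode, control = control)
      if (is.null(control)) control <- res
      results[[mode]] <- res
    }
    for (mode in names(results)) {
      res <- results[[mode]]
      rows[[length(rows) + 1L]] <- data.frame(
        curve = curve$name, sampling = mode,
        mean_rate = res$mean_rate, sd_rate = res$sd_rate,
        sigma_from_control = res$sigma_from_control,
        p_vs_control = if (mode == names(results)[1]) NA_real_
        else compare_rates_ttest(res, control),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
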
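# Synthetic 100-patient cohort generator: HDR prescriptions, HRCTV IDVs and
# linearly correlated organ-at-risk (OAR) IDVs.

#' OAR IDV regression specification
#'
#' Linear model linking an organ-at-risk IDV to the HRCTV IDV:
#' `oar_idv = slope * hrctv_idv + intercept + N(0, residual_sd)`.
#' Structures whose IDVs are not significantly correlated with the HRCTV IDV
#' carry `correlated = FALSE` (which forces `slope = 0`) and are excluded from
#' outcome simulations.
#'
#' @param structure Structure name, e.g. `"rectum"`.
#' @param slope Dimensionless regression slope; must be 0 when
#'   `correlated = FALSE`.
#' @param intercept Intercept in percent.
#' @param residual_sd Residual SD in percent (non-negative).
#' @param correlated Logical flag from the regression significance test.
#' @param p_value Optional slope p-value (filled by [fit_oar_regressions()]).
#' @return An object of class `oar_regression_spec`.
#' @export
oar_regression_spec <- function(structure, slope, intercept = 0,
                                residual_sd = 0, correlated = TRUE,
                                p_value = NA_real_) {
  if (residual_sd < 0)
    stop("oar_regression_spec: residual_sd must be non-negative", call. = FALSE)
  if (!correlated && slope != 0)
    stop("oar_regression_spec: correlated = FALSE forces slope = 0",
         call. = FALSE)
  structure(list(structure = as.character(structure), slope = as.numeric(slope),
                 intercept = as.numeric(intercept),
                 residual_sd = as.numeric(residual_sd),
                 correlated = isTRUE(correlated), p_value = p_value),
            class = "oar_regression_spec")
}

#' @export
print.oar_regression_spec <- function(x, ...) {
  cat(sprintf("<oar_regression_spec> %s: slope %.3g, intercept %.3g%%, residual SD %.3g%%, %s",
              x$structure, x$slope, x$intercept, x$residual_sd,
              if (x$correlated) "correlated" else "uncorrelated"))
  if (!is.na(x$p_value)) cat(sprintf(" (p = %.3g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Default OAR regression specifications
#'
#' Rectum and bladder IDVs moderately correlated with the HRCTV IDV, sigmoid
#' uncorrelated. The numeric coefficients are synthetic placeholders (no
#' institutional regression coefficients are published); only the
#' correlated/uncorrelated structure is load-bearing, and every number is a
#' knob.
#'
#' @return Named list of three [oar_regression_spec()] objects.
#' @export
default_oar_specs <- function() {
  list(rectum  = oar_regression_spec("rectum",  0.5, 0, 8),
       bladder = oar_regression_spec("bladder", 0.4, 0, 8),
       sigmoid = oar_regression_spec("sigmoid", 0, 0, 8, correlated = FALSE))
}

# exact truncated-normal sampling by CDF inversion
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic HDR brachytherapy cohort
#'
#' Emulates the statistical structure of the institutional dataset: HDR
#' prescription EQD2 drawn from a normal(29.4, 7.44) truncated to
#' [18.8, 40] Gy (alpha/beta = 10); HRCTV IDV drawn from `hrctv_idv_spec`;
#' delivered HRCTV EQD2 = prescribed * (1 + IDV/100); each OAR's IDV follows
#' its linear regression on the HRCTV IDV (plus normal residual) applied to an
#' expected OAR EQD2 taken as a fixed fraction of the prescription
#' (alpha/beta = 3 dose role); HRCTV volume carried as lognormal metadata.
#'
#' @param n_patients Number of patients (default 100, the study cohort size).
#' @param hrctv_idv_spec [idv_spec()] for the HRCTV IDV; default the
#'   left-skewed Beta matched to mean -1.53%, SD 11.0%.
#' @param oar_specs Non-empty list of [oar_regression_spec()] objects.
#' @param prescription_mean,prescription_sd,prescription_range HDR
#'   prescription EQD2 distribution in Gy (truncated normal).
#' @param oar_dose_fraction Expected OAR EQD2 as a fraction of the HRCTV
#'   prescription.
#' @param volume_mean,volume_sd HRCTV volume lognormal moments in cm^3.
#' @param seed Optional integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return A `data.frame` of class `patient_cohort`, one row per patient.
#' @examples
#' coh <- generate_cohort(10, seed = 1)
#' coh$hrctv_prescribed_eqd2
#' @export
generate_cohort <- function(n_patients = 100,
                            hrctv_idv_spec = default_beta_spec(),
                            oar_specs = default_oar_specs(),
                            prescription_mean = 29.4, prescription_sd = 7.44,
                            prescription_range = c(18.8, 40),
                            oar_dose_fraction = 0.65,
                            volume_mean = 53.0, volume_sd = 34.3,
                            seed = NULL) {
  if (n_patients < 1)
    stop("generate_cohort: n_patients must be at least 1", call. = FALSE)
  if (length(oar_specs) == 0)
    stop("generate_cohort: oar_specs must not be empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  presc <- .rtruncnorm(n_patients, prescription_mean, prescription_sd,
                       prescription_range[1], prescription_range[2])
  idv_h <- sample_idv(hrctv_idv_spec, n_patients)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n_patients)),
                    hrctv_prescribed_eqd2 = presc,
                    hrctv_delivered_eqd2 = presc * (1 + idv_h / 100),
                    stringsAsFactors = FALSE)
  for (spec in oar_specs) {
    expected <- presc * oar_dose_fraction
    idv_o <- spec$slope * idv_h + spec$intercept +
      stats::rnorm(n_patients, 0, spec$residual_sd)
    out[[paste0(spec$structure, "_expected_eqd2")]] <- expected
    out[[paste0(spec$structure, "_delivered_eqd2")]] <-
      expected * (1 + idv_o / 100)
  }
  # lognormal volume matched to the target mean/SD
  cv2 <- (volume_sd / volume_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  out$hrctv_volume_cc <- stats::rlnorm(n_patients,
                                       log(volume_mean) - sdlog^2 / 2, sdlog)
  class(out) <- c("patient_cohort", "data.frame")
  out
}

#' Per-structure IDV table for a cohort
#'
#' Applies [compute_idv()] to each structure's delivered vs prescribed (HRCTV)
#' or expected (OAR) EQD2.
#'
#' @param cohort A [generate_cohort()] result (or any data.frame with
#'   `<structure>_delivered_eqd2` / `_prescribed_eqd2` / `_expected_eqd2`
#'   columns).
#' @return Data frame with `patient_id` and one IDV column (percent) per
#'   structure.
#' @export
cohort_idv_table <- function(cohort) {
  if (nrow(cohort) == 0)
    stop("cohort_idv_table: empty cohort", call. = FALSE)
  delivered <- grep("_delivered_eqd2$", names(cohort), value = TRUE)
  out <- data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE)
  for (col in delivered) {
    st <- sub("_delivered_eqd2$", "", col)
    ref_col <- if (paste0(st, "_prescribed_eqd2") %in% names(cohort))
      paste0(st, "_prescribed_eqd2") else paste0(st, "_expected_eqd2")
    out[[st]] <- compute_idv(cohort[[col]], cohort[[ref_col]])
  }
  out
}

#' Fit OAR IDV regressions against the HRCTV IDV
#'
#' Ordinary least squares of each OAR structure's IDV on the HRCTV IDV. A
#' structure is flagged `correlated` when the slope p-value is below `alpha`;
#' uncorrelated structures get `slope = 0` in the returned spec (they are
#' excluded from outcome simulation) with the raw estimates kept in the
#' `estimates` attribute.
#'
#' @param idv_table A [cohort_idv_table()] result with at least 10 patients.
#' @param alpha Significance level for the slope test (default 0.05).
#' @return Named list of fitted [oar_regression_spec()] objects.
#' @export
fit_oar_regressions <- function(idv_table, alpha = 0.05) {
  if (nrow(idv_table) < 10)
    stop("fit_oar_regressions: need at least 10 patients", call. = FALSE)
  if (!"hrctv" %in% names(idv_table))
    stop("fit_oar_regressions: idv_table lacks an 'hrctv' column",
         call. = FALSE)
  x <- idv_table$hrctv
  if (stats::sd(x) == 0)
    stop("fit_oar_regressions: degenerate HRCTV IDV predictor", call. = FALSE)
  oars <- setdiff(names(idv_table), c("patient_id", "hrctv"))
  out <- lapply(oars, function(st) {
    fit <- stats::lm(idv_table[[st]] ~ x)
    cf <- summary(fit)$coefficients
    p <- cf["x", "Pr(>|t|)"]
    slope <- unname(stats::coef(fit)["x"])
    intercept <- unname(stats::coef(fit)["(Intercept)"])
    res_sd <- stats::sd(stats::residuals(fit))
    correlated <- is.finite(p) && p < alpha
    spec <- oar_regression_spec(st,
                                slope = if (correlated) slope else 0,
                                intercept = intercept,
                                residual_sd = res_sd,
                                correlated = correlated, p_value = p)
    attr(spec, "estimates") <- c(slope = slope, intercept = intercept,
                                 residual_sd = res_sd)
    spec
  })
  names(out) <- oars
  out
}

#' Write / read a cohort as long-format CSV
#'
#' One row per patient-structure pair with columns `patient_id`, `structure`,
#' `prescribed_or_expected_eqd2`, `delivered_eqd2`, `idv_percent`,
#' `hrctv_volume_cc`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the wide `patient_cohort` data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  delivered <- grep("_delivered_eqd2$", names(cohort), value = TRUE)
  rows <- lapply(delivered, function(col) {
    st <- sub("_delivered_eqd2$", "", col)
    ref_col <- if (paste0(st, "_prescribed_eqd2") %in% names(cohort))
      paste0(st, "_prescribed_eqd2") else paste0(st, "_expected_eqd2")
    data.frame(patient_id = cohort$patient_id, structure = st,
               prescribed_or_expected_eqd2 = cohort[[ref_col]],
               delivered_eqd2 = cohort[[col]],
               idv_percent = compute_idv(cohort[[col]], cohort[[ref_col]]),
               hrctv_volume_cc = cohort$hrctv_volume_cc,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$patient_id)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (st in unique(long$structure)) {
    sub <- long[long$structure == st, ]
    sub <- sub[match(ids, sub$patient_id), ]
    ref_name <- if (st == "hrctv") paste0(st, "_prescribed_eqd2")
    else paste0(st, "_expected_eqd2")
    out[[ref_name]] <- sub$prescribed_or_expected_eqd2
    out[[paste0(st, "_delivered_eqd2")]] <- sub$delivered_eqd2
  }
  hr <- long[long$structure == unique(long$structure)[1], ]
  out$hrctv_volume_cc <- hr$hrctv_volume_cc[match(ids, hr$patient_id)]
  class(out) <- c("patient_cohort", "data.frame")
  out
}
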
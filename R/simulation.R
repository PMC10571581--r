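# Monte Carlo simulation-convolution engine: perturb HDR prescriptions over
# the range of clinical interest with sampled IDVs, draw binary outcomes,
# refit logistic dose-response curves, and compute direct numerical
# convolutions R'(D) = R (x) IDV.

#' Simulation configuration
#'
#' Defines the dose grid and Monte Carlo sizes. The range of clinical
#' interest (RoCI) covers total cervical-cancer radiotherapy doses of roughly
#' 70-100 Gy EQD2, built as HDR prescriptions of 25-55 Gy plus the EBRT
#' course. The EBRT contribution defaults to 44.25 Gy EQD2 (45 Gy in 25
#' fractions of 1.8 Gy, alpha/beta = 10, LQ-converted).
#'
#' @param hdr_range HDR prescription EQD2 interval in Gy (default
#'   `c(25, 55)`).
#' @param ebrt_eqd2 Fixed EBRT EQD2 contribution in Gy.
#' @param grid_step Grid step in Gy over the HDR range.
#' @param n_sims_per_dose Simulated treatments per grid dose (at least 100).
#' @param n_replicates Replicate repetitions for failure-rate statistics.
#' @param seed Optional master seed; all child streams derive from it.
#' @return An object of class `simulation_config` with the derived
#'   `hdr_grid` and total `dose_grid`.
#' @export
simulation_config <- function(hdr_range = c(25, 55), ebrt_eqd2 = 44.25,
                              grid_step = 1, n_sims_per_dose = 10000,
                              n_replicates = 30, seed = NULL) {
  if (hdr_range[1] <= 0)
    stop("simulation_config: HDR doses must be positive over the grid",
         call. = FALSE)
  if (n_sims_per_dose < 100)
    stop("simulation_config: n_sims_per_dose must be at least 100",
         call. = FALSE)
  hdr_grid <- seq(hdr_range[1], hdr_range[2], by = grid_step)
  structure(list(hdr_range = hdr_range, ebrt_eqd2 = ebrt_eqd2,
                 grid_step = grid_step, hdr_grid = hdr_grid,
                 dose_grid = ebrt_eqd2 + hdr_grid,
                 roci = ebrt_eqd2 + hdr_range,
                 n_sims_per_dose = as.integer(n_sims_per_dose),
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> HDR %g-%g Gy (step %g) + EBRT ",
                     "%g Gy; %d sims/dose x %d replicates\n"),
              x$hdr_range[1], x$hdr_range[2], x$grid_step, x$ebrt_eqd2,
              x$n_sims_per_dose, x$n_replicates))
  invisible(x)
}

# IDV matrix (grid x n_sims) for a curve: HRCTV IDVs straight from the spec,
# OAR IDVs passed through the regression on the sampled HRCTV IDV.
.sample_idv_matrix <- function(idv_spec, oar_spec, n_grid, n_sims) {
  n <- n_grid * n_sims
  eps_h <- if (is.null(idv_spec)) rep(0, n) else sample_idv(idv_spec, n)
  eps <- if (is.null(oar_spec)) eps_h else sample_oar_idv(eps_h, oar_spec)
  matrix(eps, n_grid, n_sims)
}

#' Simulate HDR treatments over the dose grid
#'
#' At each total-dose grid point P the HDR component P - ebrt is perturbed
#' multiplicatively by an IDV sampled from `idv_spec` (or, for an
#' organ-at-risk curve, from the OAR regression on the sampled HRCTV IDV);
#' the delivered total dose `ebrt + hdr * (1 + IDV/100)` (floored at the EBRT
#' contribution) is looked up on the reference curve, and a uniform random
#' number decides the binary treatment response. A logistic dose-response
#' curve is then refitted to the simulated outcomes by maximum likelihood.
#'
#' @param curve A [dose_response_params()] reference curve.
#' @param idv_spec An [idv_spec()] for the HRCTV IDV, or `NULL` for the
#'   no-IDV control run.
#' @param config A [simulation_config()].
#' @param oar_spec Optional correlated [oar_regression_spec()]; when given,
#'   the applied IDVs are the OAR IDVs derived from the sampled HRCTV IDVs.
#' @param refit Refit the logistic curve (default: only for tumour curves).
#' @param seed Seed for this run; defaults to `config$seed`.
#' @return An object of class `simulation_result`: `dose_grid`, binary
#'   `outcomes` matrix (grid x sims), `refit_params` and the refitted
#'   `rprime_curve` on the grid (both `NULL` when `refit = FALSE`).
#' @export
simulate_treatments <- function(curve, idv_spec = NULL,
                                config = simulation_config(),
                                oar_spec = NULL,
                                refit = curve$role == "tumor",
                                seed = config$seed) {
  stopifnot(inherits(curve, "dose_response_params"),
            inherits(config, "simulation_config"))
  if (!is.null(idv_spec)) stopifnot(inherits(idv_spec, "idv_spec"))
  if (!is.null(seed)) set.seed(seed)
  grid <- config$dose_grid
  hdr <- config$hdr_grid
  n_grid <- length(grid)
  n_sims <- config$n_sims_per_dose
  eps <- .sample_idv_matrix(idv_spec, oar_spec, n_grid, n_sims)
  delivered <- pmax(config$ebrt_eqd2,
                    config$ebrt_eqd2 + hdr * (1 + eps / 100))
  p <- response(delivered, curve)
  outcomes <- matrix(as.integer(stats::runif(n_grid * n_sims) < p),
                     n_grid, n_sims)
  refit_params <- rprime <- NULL
  if (refit) {
    refit_params <- fit_logistic_mle(rep(grid, times = n_sims),
                                     as.vector(outcomes))
    rprime <- logistic_response(grid, refit_params)
  }
  structure(list(curve = curve, dose_grid = grid, outcomes = outcomes,
                 refit_params = refit_params, rprime_curve = rprime,
                 config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s: %d x %d outcomes over %g-%g Gy\n",
              x$curve$name, nrow(x$outcomes), ncol(x$outcomes),
              min(x$dose_grid), max(x$dose_grid)))
  if (!is.null(x$refit_params))
    cat(sprintf("  refit: D50 = %.2f Gy, gamma = %.3f\n",
                x$refit_params$d50, x$refit_params$gamma))
  invisible(x)
}

#' Sample OAR IDVs from the regression on HRCTV IDVs
#'
#' `slope * hrctv_idv + intercept + N(0, residual_sd)`, vectorised over
#' `hrctv_idv`. Uncorrelated structures are excluded from simulation and
#' raise an error.
#'
#' @param hrctv_idv HRCTV IDV(s) in percent.
#' @param spec A correlated [oar_regression_spec()].
#' @return OAR IDV(s) in percent.
#' @export
sample_oar_idv <- function(hrctv_idv, spec) {
  stopifnot(inherits(spec, "oar_regression_spec"))
  if (!spec$correlated)
    stop("sample_oar_idv: structure '", spec$structure,
         "' is uncorrelated with the HRCTV IDV and is excluded from ",
         "simulation", call. = FALSE)
  spec$slope * hrctv_idv + spec$intercept +
    stats::rnorm(length(hrctv_idv), 0, spec$residual_sd)
}

# Negative Bernoulli log-likelihood and gradient in (log D50, log gamma),
# aggregated over unique doses for speed. eta = 4*gamma*(1 - D/D50);
# p = 1/(1 + exp(eta)).
.logis_nll <- function(theta, d, n_d, s_d) {
  d50 <- exp(theta[1]); g <- exp(theta[2])
  eta <- 4 * g * (1 - d / d50)
  # softplus(eta) summed with counts; s_d = number of successes at dose d
  sp <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  sum(n_d * sp - (n_d - s_d) * eta)
}

.logis_grad <- function(theta, d, n_d, s_d) {
  d50 <- exp(theta[1]); g <- exp(theta[2])
  eta <- 4 * g * (1 - d / d50)
  p <- 1 / (1 + exp(eta))
  resid <- s_d - n_d * p            # sum over observations of (y - p)
  c(sum(resid * 4 * g * d / d50),   # d eta / d log D50 = 4 g D / D50
    sum(resid * 4 * g * (1 - d / d50)))
}

#' Maximum-likelihood logistic dose-response fit
#'
#' Fits the logistic curve `R(D) = 1/(1 + exp(4 gamma (1 - D/D50)))` to
#' binary outcomes by maximising the Bernoulli likelihood directly in the
#' (D50, gamma) parameterisation (quasi-Newton with analytic gradient,
#' multi-start at the reference parameter sets), so refitted curves are
#' directly comparable to the reference curves.
#'
#' @param doses Dose in Gy for each outcome.
#' @param outcomes Binary (0/1) outcome vector; both classes must be present.
#' @param starts Optional list of `c(d50, gamma)` starting points; defaults
#'   to the four reference TCP parameter sets plus a data-driven start.
#' @return A [dose_response_params()] with `form = "logistic"`,
#'   `name = "refit"`, and attributes `logLik` and `convergence`.
#' @export
fit_logistic_mle <- function(doses, outcomes, starts = NULL) {
  if (length(doses) != length(outcomes))
    stop("fit_logistic_mle: doses and outcomes differ in length",
         call. = FALSE)
  y <- as.integer(outcomes)
  if (!all(y %in% c(0L, 1L)))
    stop("fit_logistic_mle: outcomes must be binary 0/1", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("fit_logistic_mle: complete separation (single outcome class)",
         call. = FALSE)
  if (max(doses[y == 0L]) < min(doses[y == 1L]))
    stop("fit_logistic_mle: complete separation (outcomes split at a dose ",
         "threshold)", call. = FALSE)
  d <- unique(doses)
  n_d <- vapply(d, function(dd) sum(doses == dd), numeric(1))
  s_d <- vapply(d, function(dd) sum(y[doses == dd]), numeric(1))
  if (is.null(starts)) {
    tab <- .reference_table()
    starts <- c(lapply(seq_len(4), function(i) c(tab$d50[i], tab$gamma[i])),
                list(c(stats::weighted.mean(d, n_d), 1)))
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(log(s), .logis_nll, .logis_grad,
                            d = d, n_d = n_d, s_d = s_d, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("fit_logistic_mle: optimisation failed from every start",
         call. = FALSE)
  d50 <- exp(best$par[1]); g <- exp(best$par[2])
  if (g > 1e3 || d50 > 100 * max(d))
    stop(sprintf(paste0("fit_logistic_mle: estimates diverged (D50 = %.3g, ",
                        "gamma = %.3g); outcomes are likely separated"),
                 d50, g), call. = FALSE)
  out <- dose_response_params("refit", "logistic", d50, g, "tumor")
  attr(out, "logLik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Deterministic convolution of a dose-response curve with an IDV distribution
#'
#' Computes `R'(P) = E[R(ebrt + hdr (1 + eps/100))]` on the configured grid
#' by quadrature over the IDV density (trapezoid rule on `n_quad` nodes over
#' the distribution's support), without Monte Carlo noise. With an OAR
#' regression spec the expectation also integrates over the normal residual,
#' giving the marginal OAR IDV distribution. This is the direct numerical
#' form of the simulation-convolution and is used for the NTCP R' curves,
#' where no event refit is needed.
#'
#' @inheritParams simulate_treatments
#' @param n_quad Number of quadrature nodes for the IDV density.
#' @param n_quad_residual Nodes for the OAR residual integral.
#' @return Numeric vector of convolved response probabilities on
#'   `config$dose_grid`.
#' @export
convolve_response <- function(curve, idv_spec, config = simulation_config(),
                              oar_spec = NULL, n_quad = 2001,
                              n_quad_residual = 201) {
  stopifnot(inherits(curve, "dose_response_params"),
            inherits(idv_spec, "idv_spec"),
            inherits(config, "simulation_config"))
  if (idv_spec$family == "point") {
    eps <- idv_spec$location
    w <- 1
  } else {
    sup <- idv_support(idv_spec)
    eps <- seq(sup[1], sup[2], length.out = n_quad)
    w <- didv(eps, idv_spec)
    # trapezoid weights, renormalised
    h <- diff(eps)[1]
    w <- w * h
    w[c(1, length(w))] <- w[c(1, length(w))] / 2
    w <- w / sum(w)
  }
  if (!is.null(oar_spec)) {
    stopifnot(inherits(oar_spec, "oar_regression_spec"))
    if (!oar_spec$correlated)
      stop("convolve_response: uncorrelated OAR structures are excluded",
           call. = FALSE)
    mu <- oar_spec$slope * eps + oar_spec$intercept
    if (oar_spec$residual_sd > 0) {
      z <- seq(-8, 8, length.out = n_quad_residual)
      wz <- stats::dnorm(z); wz <- wz / sum(wz)
      eps <- as.vector(outer(mu, z * oar_spec$residual_sd, `+`))
      w <- as.vector(outer(w, wz))
    } else {
      eps <- mu
    }
  }
  vapply(config$hdr_grid, function(h) {
    delivered <- pmax(config$ebrt_eqd2,
                      config$ebrt_eqd2 + h * (1 + eps / 100))
    sum(w * response(delivered, curve))
  }, numeric(1))
}
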
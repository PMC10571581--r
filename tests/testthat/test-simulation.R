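test_that("simulation_config derives the dose grid and validates inputs", {
  cfg <- simulation_config()
  expect_equal(cfg$hdr_grid, 25:55)
  expect_equal(cfg$dose_grid, 44.25 + 25:55)
  expect_equal(cfg$roci, c(69.25, 99.25))
  expect_error(simulation_config(hdr_range = c(-5, 10)), "positive")
  expect_error(simulation_config(n_sims_per_dose = 50), "at least 100")
})

test_that("zero-noise event simulation reproduces the reference curve", {
  cfg <- simulation_config(n_sims_per_dose = 10000, seed = 201)
  for (nm in c("TCP1", "TCP2C")) {
    curve <- ref_registry[[nm]]
    res <- simulate_treatments(curve, control_spec(), cfg, refit = FALSE)
    p_hat <- rowMeans(res$outcomes)
    p_ref <- response(res$dose_grid, curve)
    z <- (p_hat - p_ref) / sqrt(p_ref * (1 - p_ref) / cfg$n_sims_per_dose)
    expect_true(z_scores_ok(z))
  }
})

test_that("NULL idv_spec and the point-mass spec are the same control", {
  cfg <- simulation_config(n_sims_per_dose = 300, seed = 202)
  a <- simulate_treatments(ref_registry$TCP2B, NULL, cfg, refit = FALSE)
  b <- simulate_treatments(ref_registry$TCP2B, control_spec(), cfg,
                           refit = FALSE)
  expect_identical(a$outcomes, b$outcomes)
})

test_that("SND-perturbed probit outcomes match the closed-form convolution", {
  # at total dose 85 Gy (EBRT taken as 45 here so 85 lies on the grid)
  cfg <- simulation_config(ebrt_eqd2 = 45, hdr_range = c(40, 40),
                           n_sims_per_dose = 40000, seed = 203)
  res <- simulate_treatments(ref_registry$TCP2C, snd_spec(), cfg,
                             refit = FALSE)
  p_hat <- mean(res$outcomes)
  p_oracle <- gauss_probit_oracle(40, 45, 68, 2.0, 11.2)
  expect_equal(p_oracle, 0.883, tolerance = 1e-3)
  expect_lt(abs(p_hat - p_oracle),
            3 * sqrt(p_oracle * (1 - p_oracle) / 40000))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_sims_per_dose = 500)
  r1 <- simulate_treatments(ref_registry$TCP2A, snd_spec(), cfg,
                            refit = FALSE, seed = 204)
  r2 <- simulate_treatments(ref_registry$TCP2A, snd_spec(), cfg,
                            refit = FALSE, seed = 204)
  expect_identical(r1$outcomes, r2$outcomes)
})

test_that("sample_oar_idv applies the regression with normal residuals", {
  lin <- oar_regression_spec("rectum", 0.5, 1, 0)
  expect_equal(sample_oar_idv(c(-10, 0, 20), lin), c(-4, 1, 11))
  noisy <- oar_regression_spec("rectum", 0.5, 0, 8)
  set.seed(205)
  draws <- sample_oar_idv(rep(-10, 1e5), noisy)
  expect_equal(mean(draws), -5.0, tolerance = 0.1)
  expect_equal(sd(draws), 8.0, tolerance = 0.1)
  sig <- oar_regression_spec("sigmoid", 0, 0, 8, correlated = FALSE)
  expect_error(sample_oar_idv(0, sig), "excluded")
})

test_that("logistic MLE recovers the generating curve and matches glm", {
  cfg <- simulation_config(seed = 206, n_sims_per_dose = 3300)  # ~1e5 outcomes
  res <- simulate_treatments(ref_registry$TCP1, control_spec(), cfg)
  fit <- res$refit_params
  expect_equal(fit$d50, 36, tolerance = 1.5 / 36)
  expect_equal(fit$gamma, 0.47, tolerance = 0.05 / 0.47)
  # independent cross-check: glm in intercept/slope form, transformed back
  d <- rep(res$dose_grid, times = ncol(res$outcomes))
  y <- as.vector(res$outcomes)
  g <- glm(y ~ d, family = binomial())
  a <- unname(coef(g)[1]); b <- unname(coef(g)[2])
  # logit p = -4 gamma + (4 gamma / D50) D, so gamma = -a/4, D50 = -a/b
  expect_equal(fit$gamma, -a / 4, tolerance = 1e-4)
  expect_equal(fit$d50, -a / b, tolerance = 1e-4)
})

test_that("logistic MLE is exchangeable and detects separation", {
  set.seed(207)
  d <- rep(seq(70, 100, 5), each = 200)
  p <- logistic_response(d, ref_registry$TCP1)
  y <- as.integer(runif(length(d)) < p)
  f1 <- fit_logistic_mle(d, y)
  idx <- sample(length(d))
  f2 <- fit_logistic_mle(d[idx], y[idx])
  expect_equal(f1$d50, f2$d50, tolerance = 1e-8)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  expect_error(fit_logistic_mle(d, rep(1L, length(d))), "separation")
  expect_error(fit_logistic_mle(d, rep(0L, length(d))), "separation")
  # perfectly separated outcomes diverge
  ysep <- as.integer(d > 85)
  expect_error(fit_logistic_mle(d, ysep), "separat")
})

test_that("convolution with a point mass returns the reference curve", {
  cfg <- simulation_config()
  for (nm in names(ref_registry)) {
    curve <- ref_registry[[nm]]
    expect_equal(convolve_response(curve, control_spec(), cfg),
                 response(cfg$dose_grid, curve), tolerance = 1e-12)
  }
})

test_that("quadrature convolution matches the Gaussian x probit closed form", {
  cfg <- simulation_config(ebrt_eqd2 = 45, hdr_range = c(25, 55))
  for (nm in c("TCP2A", "TCP2B", "TCP2C", "NTCP_ref")) {
    curve <- ref_registry[[nm]]
    got <- convolve_response(curve, snd_spec(), cfg)
    oracle <- gauss_probit_oracle(cfg$hdr_grid, 45, curve$d50, curve$gamma,
                                  11.2)
    expect_lt(max(abs(got - oracle)), 1e-3)
  }
})

test_that("a symmetric IDV leaves the response unchanged at the inflection
           point (Jensen equality)", {
  # TCP2C inflection at 68 Gy: delivered dose locally linear in the IDV
  cfg <- simulation_config(ebrt_eqd2 = 44.25, hdr_range = c(23.75, 23.75))
  narrow <- idv_spec("normal", location = 0, scale = 2)
  got <- convolve_response(ref_registry$TCP2C, narrow, cfg)
  expect_equal(got, 0.5, tolerance = 1e-3)
})

test_that("Monte Carlo and quadrature convolutions agree for all reference
           curves under the SND", {
  cfg <- simulation_config(n_sims_per_dose = 10000, seed = 208)
  for (nm in names(ref_registry)) {
    curve <- ref_registry[[nm]]
    res <- simulate_treatments(curve, snd_spec(), cfg, refit = FALSE)
    p_hat <- rowMeans(res$outcomes)
    quad <- convolve_response(curve, snd_spec(), cfg)
    se <- sqrt(pmax(quad * (1 - quad), 1e-12) / cfg$n_sims_per_dose)
    expect_true(z_scores_ok((p_hat - quad) / se))
  }
})

test_that("refit logistic R' tracks the quadrature convolution for logistic
           references", {
  cfg <- simulation_config(n_sims_per_dose = 10000, seed = 209)
  res <- simulate_treatments(ref_registry$TCP1, snd_spec(), cfg)
  quad <- convolve_response(ref_registry$TCP1, snd_spec(), cfg)
  expect_lt(max(abs(res$rprime_curve - quad)), 0.02)
})

test_that("simulation results serialise to JSON without the outcome matrix", {
  cfg <- simulation_config(n_sims_per_dose = 300, seed = 210)
  res <- simulate_treatments(ref_registry$TCP1, snd_spec(), cfg)
  js <- jsonlite::fromJSON(idv_json(res))
  expect_equal(js$curve, "TCP1")
  expect_length(js$rprime_curve, length(cfg$dose_grid))
  expect_null(js$outcomes)
})
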
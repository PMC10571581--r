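test_that("compute_idv is the signed percent difference", {
  expect_equal(compute_idv(29.4, 29.4), 0)
  expect_equal(compute_idv(26.46, 29.4), -10, tolerance = 1e-12)
  expect_equal(compute_idv(33.0, 30.0), 10, tolerance = 1e-12)
  expect_error(compute_idv(30, 0), "positive")
  expect_error(compute_idv(30, -5), "positive")
})

test_that("beta_from_moments matches target moments analytically", {
  # symmetry forces a = b = concentration/2
  sym <- beta_from_moments(0, 1, 0, 10)
  expect_equal(unname(sym$shape_params), c(5, 5))
  expect_equal(sym$mean_idv, 0, tolerance = 1e-10)
  expect_equal(sym$sd_idv, 1, tolerance = 1e-10)
  # cohort default: analytic moments recomputed from the returned parameters
  spec <- beta_from_moments(-1.53, 11.0, -0.6, 10)
  mom <- idv_moments(spec)
  expect_equal(unname(mom[["mean"]]), -1.53, tolerance = 1e-8)
  expect_equal(unname(mom[["sd"]]), 11.0, tolerance = 1e-8)
  expect_equal(unname(mom[["skewness"]]), -0.6, tolerance = 1e-8)
  expect_equal(sum(spec$shape_params), 10, tolerance = 1e-8)
  # infeasible skewness at low concentration (shapes constrained >= 1)
  expect_error(beta_from_moments(-1.53, 11.0, -2.9, 4), "no solution")
  expect_error(beta_from_moments(0, -1, 0, 10), "sd")
  expect_error(beta_from_moments(0, 1, 0, 2), "concentration")
})

test_that("analytic moments agree with large-sample moments for every family", {
  specs <- list(beta = default_beta_spec(),
                gev = idv_spec("gev", -0.25, location = -3, scale = 9),
                normal = snd_spec())
  n <- 1e6
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    x <- sample_idv(spec, n, seed = 7)
    se_mean <- spec$sd_idv / sqrt(n)
    expect_lt(abs(mean(x) - spec$mean_idv), 4 * se_mean)
    # SE of the SD estimate ~ sd/sqrt(2n) for near-normal tails; double it
    # to cover the skewed families' excess kurtosis
    expect_lt(abs(sd(x) - spec$sd_idv), 8 * spec$sd_idv / sqrt(2 * n))
  }
})

test_that("fit_distribution recovers known generators", {
  set.seed(21)
  # standard-normal convention fixes the mean at 0
  x <- rnorm(5000, 0, 11.2)
  fit <- fit_distribution(x, "normal", standard_normal = TRUE)
  expect_equal(fit$mean_idv, 0)
  expect_equal(fit$sd_idv, 11.2, tolerance = 0.05)
  expect_true(fit$standard_normal)
  # unconstrained normal estimates the mean
  fit2 <- fit_distribution(x, "normal")
  expect_equal(fit2$mean_idv, mean(x))
  # beta parameter recovery: fitted moments close to the generator's
  gen <- default_beta_spec()
  y <- sample_idv(gen, 5000, seed = 22)
  bfit <- fit_distribution(y, "beta")
  expect_equal(bfit$mean_idv, gen$mean_idv, tolerance = 0.6)
  expect_equal(bfit$sd_idv, gen$sd_idv, tolerance = 0.6)
  expect_lt(bfit$skewness, -0.3)   # left skew detected
  # gev recovery
  ggen <- idv_spec("gev", -0.25, location = -3, scale = 9)
  z <- sample_idv(ggen, 5000, seed = 23)
  gfit <- fit_distribution(z, "gev")
  expect_equal(gfit$shape_params[["shape"]], -0.25, tolerance = 0.06)
  expect_equal(gfit$location, -3, tolerance = 0.5)
  expect_equal(gfit$scale, 9, tolerance = 0.5)
  expect_error(fit_distribution(rep(1, 50), "normal"), "degenerate")
  expect_error(fit_distribution(rnorm(10), "normal"), "at least 20")
})

test_that("rss_score matches a hand-computed histogram comparison", {
  # 10 samples over [0, 5]: equal-width bins, density = count / (n * width)
  x <- c(0.2, 0.4, 1.5, 2.5, 2.6, 2.7, 3.5, 4.2, 4.4, 5.0)
  spec <- idv_spec("normal", location = 2.5, scale = 1.5)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 6), plot = FALSE)
  expected <- sum((h$density - dnorm(h$mids, 2.5, 1.5))^2)
  expect_equal(rss_score(x, spec, n_bins = 5), expected, tolerance = 1e-12)
  expect_gte(rss_score(x, spec), 0)
  expect_error(rss_score(x, spec, n_bins = 3), "at least 5")
})

test_that("rss_score prefers the generating distribution", {
  gen <- default_beta_spec()
  x <- sample_idv(gen, 5000, seed = 31)
  wrong <- snd_spec()
  expect_lt(rss_score(x, gen), rss_score(x, wrong))
  # and a fitted beta scores at least as well as a fitted normal
  fb <- fit_distribution(x, "beta")
  fn <- fit_distribution(x, "normal", standard_normal = TRUE)
  expect_lt(fb$rss, fn$rss)
})

test_that("anderson_darling accepts its own family and rejects a normal fit
           to skewed data", {
  set.seed(41)
  # type I error with the normal-case tables: ~5% at alpha = 0.05
  pvals <- vapply(1:100, function(i) {
    x <- rnorm(1000)
    anderson_darling(x, fit_distribution(x, "normal"))$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
  # strongly left-skewed beta draws (skewness near the feasibility bound at
  # concentration 6) vs the standard-normal convention
  skewed <- sample_idv(beta_from_moments(-1.53, 11, -1.1, 6), 100,
                       seed = 9602)
  m <- mean(skewed); s3 <- mean((skewed - m)^3) / sd(skewed)^3
  expect_lt(s3, -1)   # the draw really is strongly left-skewed
  snd_fit <- fit_distribution(skewed, "normal", standard_normal = TRUE)
  ad <- anderson_darling(skewed, snd_fit, n_bootstrap = 500, seed = 43)
  expect_lt(ad$p_value, 0.05)
  expect_error(anderson_darling(skewed, default_beta_spec(),
                                n_bootstrap = 50), "at least 100")
  expect_error(anderson_darling(rnorm(5), snd_spec()), "at least 20")
})

test_that("anderson_darling statistic is affine invariant", {
  x <- sample_idv(snd_spec(), 200, seed = 44)
  spec1 <- idv_spec("normal", location = 0, scale = 11.2)
  a1 <- anderson_darling(x, spec1, n_bootstrap = 100, seed = 1)$statistic
  spec2 <- idv_spec("normal", location = 5, scale = 11.2 * 3)
  a2 <- anderson_darling(3 * x + 5, spec2, n_bootstrap = 100,
                         seed = 1)$statistic
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("normal-case tables agree with the reference normality test", {
  skip_if_not_installed("nortest")
  for (s in c(51, 52, 53)) {
    x <- rnorm(300 + s, mean = s)
    ours <- anderson_darling(x, fit_distribution(x, "normal"))
    theirs <- nortest::ad.test(x)
    expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-6)
  }
})

test_that("bootstrap p-values are calibrated under the null for a known spec", {
  spec <- default_beta_spec()   # known parameters: no refit inside bootstrap
  set.seed(61)
  seeds <- sample.int(1e6, 200)
  pvals <- vapply(seeds, function(s) {
    x <- sample_idv(spec, 100, seed = s)
    anderson_darling(x, spec, n_bootstrap = 199, seed = s + 1)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("bootstrap with refit accepts its own fitted family", {
  x <- sample_idv(idv_spec("gev", -0.2, location = -2, scale = 10), 150,
                  seed = 71)
  fit <- fit_distribution(x, "gev")
  ad <- anderson_darling(x, fit, n_bootstrap = 100, seed = 72)
  expect_gt(ad$p_value, 0.05)
})

test_that("sample_idv is reproducible, bounded and converges in mean", {
  spec <- default_beta_spec()
  x1 <- sample_idv(spec, 1000, seed = 5)
  x2 <- sample_idv(spec, 1000, seed = 5)
  expect_identical(x1, x2)
  # bounded support of the four-parameter beta
  big <- sample_idv(spec, 1e5, seed = 6)
  expect_true(all(big >= spec$location & big <= spec$location + spec$scale))
  m <- mean(sample_idv(spec, 1e6, seed = 8))
  expect_equal(m, -1.53, tolerance = 0.04)
  expect_error(sample_idv(spec, 0), "at least 1")
})

test_that("qq_points pairs sorted samples with (i - 0.5)/n quantiles", {
  x <- c(3, 1, 2)
  qq <- qq_points(x, snd_spec())
  expect_length(qq$theoretical, 3)
  expect_equal(qq$sample, c(1, 2, 3))
  expect_equal(qq$theoretical, qidv(c(0.5, 1.5, 2.5) / 3, snd_spec()))
  # self-consistency: slope of the Q-Q pairs near 1 for own-spec samples
  spec <- default_beta_spec()
  y <- sample_idv(spec, 1e4, seed = 9)
  qq2 <- qq_points(y, spec)
  slope <- coef(lm(qq2$sample ~ qq2$theoretical))[2]
  expect_gt(slope, 0.97)
  expect_lt(slope, 1.03)
  expect_error(qq_points(c(1, 2), snd_spec()), "at least 3")
})

test_that("idv specs serialise to JSON", {
  js <- jsonlite::fromJSON(idv_json(default_beta_spec()))
  expect_equal(js$family, "beta")
  expect_equal(js$mean_idv, -1.53, tolerance = 1e-8)
  expect_equal(js$shape_params$a + js$shape_params$b, 10, tolerance = 1e-8)
})
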
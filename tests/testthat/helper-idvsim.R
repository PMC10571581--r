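# Shared fixtures for the idvsim test suite.

ref_registry <- reference_registry()

# Normal-CDF oracle for the probit form: Phi((D - D50) * gamma * sqrt(2*pi) / D50)
probit_oracle <- function(dose, d50, gamma) {
  stats::pnorm((dose - d50) * gamma * sqrt(2 * pi) / d50)
}

# Closed-form Gaussian (x) probit convolution oracle on the HDR-perturbed
# dose: delivered = ebrt + h*(1 + eps/100), eps ~ N(0, sd_pct) implies
# delivered ~ N(ebrt + h, (sd_pct/100 * h)^2).
gauss_probit_oracle <- function(hdr, ebrt, d50, gamma, sd_pct) {
  s <- d50 / (gamma * sqrt(2 * pi))
  sig_d <- sd_pct / 100 * hdr
  stats::pnorm((ebrt + hdr - d50) / sqrt(s^2 + sig_d^2))
}

# Small configs keep unit tests fast; acceptance tests use the full scale.
tiny_config <- function(seed = NULL, ...) {
  simulation_config(n_sims_per_dose = 500, n_replicates = 3, seed = seed, ...)
}

# Decide whether a vector of z-scores is compatible with per-point 3-sigma
# agreement once multiplicity is accounted for: at most one exceedance of 3,
# none of 4.
z_scores_ok <- function(z) sum(abs(z) > 3) <= 1 && all(abs(z) < 4)
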
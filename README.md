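# idvsim

Monte Carlo simulation-convolution of **interfraction dose variations
(IDVs)** in high-dose-rate (HDR) brachytherapy for cervical cancer.

Delivered HRCTV D90 doses drift from the prescription between HDR
fractions. Institutional data show the drift, expressed as

```
IDV (%) = 100 * (delivered EQD2 - prescribed/expected EQD2) / (prescribed/expected EQD2),
```

is **left-skewed** (mean ≈ −1.5%, SD ≈ 11%) — under-dosing is more likely
than over-dosing — rather than the Gaussian assumed by earlier uncertainty
studies. `idvsim` is for medical physicists and outcome modellers who want
to quantify what that asymmetry does to clinical outcomes. It convolves
published logistic/probit dose-response curves with parametric IDV
distributions,

```
R'(D) = R_D' (x) IDV(D - D'),
```

where the tumour-control references are `R(D) = 1/(1 + exp(4γ(1 − D/D50)))`
(logistic) or `R(D) = Φ((D − D50) · γ√(2π) / D50)` (probit), and reports:

* **treatment failure rates** from a binary event simulator (10,000
  simulated treatments per dose over the 70–100 Gy EQD2 range of clinical
  interest, 30 replicates), with sigma-distances from a no-IDV control and
  Welch t-tests between sampling modes;
* **convolved R′ curves** by logistic maximum-likelihood refit of the
  simulated events and by deterministic quadrature, with local-control and
  morbidity probability differences and an iso-complication dose-escalation
  estimate;
* **the utility model** `U(D) = TCP(D)·(1 − NTCP(D))`, the probability of
  risk-free local control (RFLC), whose argmax is the predicted optimal
  prescription;
* the **distribution machinery** behind the IDV specs: moment-matched
  four-parameter Beta, generalized extreme value and normal families, RSS
  ranking against density histograms, Anderson–Darling tests (normal-case
  tables or parametric bootstrap), Q–Q export, and a synthetic 100-patient
  cohort generator with organ-at-risk IDV regressions.

## Worked example

```r
library(idvsim)

cfg <- simulation_config(seed = 2026)   # HDR 25-55 Gy + 44.25 Gy EBRT EQD2,
                                        # 10,000 sims/dose, 30 replicates
failure_rate_table(config = cfg)
#>    curve sampling mean_rate sd_rate sigma_from_control p_vs_control
#> 1   TCP1  control     8.072 0.04844                 NA           NA
#> 2   TCP1     beta     8.473 0.05782              8.279    1.274e-35
#> 3   TCP1      snd     8.264 0.05311              3.962    4.957e-21
#> 4  TCP2A  control    10.416 0.04600                 NA           NA
#> 5  TCP2A     beta    11.016 0.06954             13.053    1.659e-39
#> 6  TCP2A      snd    10.710 0.06172              6.393    1.817e-27
#> 7  TCP2B  control    16.496 0.06088                 NA           NA
#> 8  TCP2B     beta    17.574 0.08593             17.708    2.326e-48
#> 9  TCP2B      snd    17.007 0.06756              8.391    2.346e-37
#> 10 TCP2C  control    16.081 0.05479                 NA           NA
#> 11 TCP2C     beta    17.836 0.07495             32.031    5.842e-63
#> 12 TCP2C      snd    17.036 0.05709             17.429    3.114e-56
```

Each row is a reference TCP curve under one IDV sampling mode: `control`
applies no IDV, `beta` samples the left-skewed Beta matched to the cohort
(mean −1.53%, SD 11.0%), `snd` the zero-mean normal with SD 11.2%. The
left-skewed Beta raises the 3-year treatment failure rate of the
large-tumour TCP2C curve from 16.1% to 17.8% (+1.8 points, ~32 control
SDs), about twice the Gaussian estimate — the clinical cost of ignoring the
skew.

```r
res <- simulate_treatments(reference_curve("TCP2C"), snd_spec(),
                           simulation_config(seed = 11))
res
#> <simulation_result> TCP2C: 31 x 10000 outcomes over 69.25-99.25 Gy
#>   refit: D50 = 68.44 Gy, gamma = 2.116
lc_difference(res$rprime_curve, reference_curve("TCP2C"), 85, res$dose_grid)
#> [1] -0.92   # percentage points, logistic-refit path

reference_utility("TCP2A")
#> <utility_curve> optimal dose 80.0 Gy, RFLC 80.4% (grid 70-100 Gy)
```

IDV uncertainty lowers the local-control probability at the common 85 Gy
prescription and shifts the utility-optimal dose upward; convolved OAR NTCP
curves (via `convolve_response()` with an `oar_regression_spec`) feed
`convolved_utility()` and `dose_escalation_estimate()` for the
iso-complication escalation analysis.

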
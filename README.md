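# uvmix

Quantifies the two components of a binary drug mixture from severely
overlapped UV-Vis absorption spectra — no chromatographic separation — by
three classical spectrophotometric resolutions, together with the
validation statistics a regulated assay needs. The motivating system is the
aspirin (ASP) + rivaroxaban (ROX) combination therapy measured over
200-350 nm at 0.2 nm steps, in methanol and in deproteinated human plasma;
the routines are generic.

For a mixture obeying Beer-Lambert additivity,
`A(λ) = c_X a_X(λ) + c_Y a_Y(λ)`, the package implements:

* **Dual wavelength (DW)** — the absorbance difference
  `ΔA = A(λ2) − A(λ1)` at a pair where the interferent absorbs equally, so
  its contribution cancels and `ΔA` is linear in the analyte concentration.
  Includes an exhaustive pair search with off-grid refinement
  (`select_pair()`).
* **Ratio difference (RD)** — divide by a standard spectrum of the
  interferent (the *divisor*); the interferent becomes a constant on the
  ratio trace and the amplitude difference `ΔP = P(λ1) − P(λ2)` at any two
  wavelengths removes it.
* **Derivative ratio (¹DD)** — first derivative of the ratio trace
  (window Δλ = 4 nm, scaling factor 10); the constant differentiates to
  zero and peak/trough amplitudes are analyte-proportional
  (`dd_candidate_wavelengths()` ranks candidate wavelengths by
  sensitivity).

Around the core: OLS calibration with broom-style `tidy()`/`glance()`,
recovery/RSD/LOD/LOQ (`3.3σ/|slope|`, `10σ/|slope|`), standard addition,
pooled two-sample t and variance-ratio F comparison from summary
statistics, plasma dilution-chain arithmetic with matrix interference
checks, the GSK-style composite solvent greenness score
`G = (H·S·E·W)^(1/4)`, and a synthetic spectra generator
(Gaussian-band components, Beer-Lambert mixing, plasma-like baseline,
detector + photometric noise) that makes every stage testable without
instrument data. ggplot2 `autoplot()` methods cover spectra, ratio and
derivative traces, and calibrations.

## Worked example

Published calibration lines ship as fixed constants and invert measured
signals directly:

```r
library(uvmix)

cal <- fixed_calibration("ASP", "dw")   # ΔA(255.5, 242.5) = 0.0054 C + 0.001
predict_concentration(cal, 0.109)
#> [1] 20
```

A full in-silico run — simulate calibration standards, calibrate all three
methods, resolve mixtures, summarise recoveries:

```r
res <- run_pipeline(default_config(seed = 1, noise_fraction = 0.01,
                                   n_replicates = 3))
res$calibrations$asp_dw
#> <uv_calibration> DW [asp] @ 231.5572, 305.2000 nm
#>   signal = -0.0310528 C +4.47646e-17   r = -1.00000, n = 6
dplyr::filter(res$report$by_method, method == "rd")
#> # A tibble: 2 × 5
#>   analyte method     n mean_recovery sd_recovery
#>   <chr>   <chr>  <int>         <dbl>       <dbl>
#> 1 asp     rd        75          99.8       0.923
#> 2 rox     rd        75         100.0       1.13
```

The printed calibration says the search found a usable dual-wavelength pair
(231.6/305.2 nm) whose fit is perfectly linear on noise-free standards;
the report rows say ratio-difference determinations over the mixture grid
average ~100% recovery with ~1% SD at 1% photometric noise.

Method comparison against a reference assay from summary statistics
(mean recovery, variance, n per series):

```r
out <- compare_methods(reference_assay_stats())
out[out$analyte == "ROX" & out$method == "rd", c("t", "t_crit", "F", "F_crit")]
#> # A tibble: 1 × 4
#>       t t_crit     F F_crit
#>   <dbl>  <dbl> <dbl>  <dbl>
#> 1 0.562   2.18  1.79   3.97
```

Neither statistic exceeds its 5% critical value: the spectrophotometric
result is statistically indistinguishable from the reference HPLC assay in
both accuracy and precision.

A thin command-line front end wraps the same functions
(`inst/cli/uvmix.R`):

```sh
Rscript inst/cli/uvmix.R simulate --component asp --levels 4,8,16,24,32,40 --out std/
Rscript inst/cli/uvmix.R dw calibrate --standards std/ --pair 231.6,251.6 --out dw.cal
Rscript inst/cli/uvmix.R dw predict --calibration dw.cal --sample std/asp_003.csv
# 16
Rscript inst/cli/uvmix.R plasma --initial 25 --step 4:5 --step 2:10
# 4
Rscript inst/cli/uvmix.R greenness --scores 4,9,4,9
# 6
```

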
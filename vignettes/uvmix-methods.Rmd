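---
title: "Resolving overlapped UV-Vis spectra of binary mixtures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapped UV-Vis spectra of binary mixtures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvmix)
```

## The problem

Two co-formulated drugs whose UV absorption bands overlap severely cannot be
quantified from a single zero-order absorbance reading: at every wavelength
both components contribute. Chromatographic separation solves this at the
cost of solvent, energy and time. The alternative implemented here is purely
mathematical: under Beer-Lambert additivity the mixture spectrum is

$$A(\lambda) = c_X\,a_X(\lambda) + c_Y\,a_Y(\lambda),$$

with $a_X, a_Y$ the unit-concentration absorptivity profiles, and three
classical manipulations each construct a scalar signal that depends on one
concentration only. The motivating system is the aspirin (ASP) +
rivaroxaban (ROX) combination (working ranges 4-40 and 2-20 ug/mL on a
200-350 nm, 0.2 nm grid), but every routine is generic.

**Dual wavelength (DW).** Pick $\lambda_1 < \lambda_2$ where the interferent
absorbs equally, $a_Y(\lambda_1) = a_Y(\lambda_2)$. Then
$\Delta A = A(\lambda_2) - A(\lambda_1) = c_X\,[a_X(\lambda_2) -
a_X(\lambda_1)]$ is linear in $c_X$ with the interferent cancelled.

**Ratio difference (RD).** Divide the mixture spectrum by a standard
spectrum of the interferent at divisor concentration $c_0$. The ratio trace
is $c_X\,a_X(\lambda)/(c_0\,a_Y(\lambda)) + c_Y/c_0$: the interferent's
share is a wavelength-independent constant, so the amplitude difference
$\Delta P = P(\lambda_1) - P(\lambda_2)$ at *any* two wavelengths removes it.

**Derivative ratio (1DD).** Differentiate the same ratio trace: the
constant differentiates to zero everywhere, and the derivative amplitude at
a chosen extremum is proportional to $c_X$. The window
$\Delta\lambda = 4$ nm and scaling factor 10 are the conventional
instrument settings; the operator is a symmetric finite difference over the
window,

$$D(\lambda) = s\,\frac{R(\lambda + \Delta\lambda/2) -
R(\lambda - \Delta\lambda/2)}{\Delta\lambda},$$

the simplest operator consistent with reading the window as a smoothing
span. A Savitzky-Golay first derivative over the same window is available
behind `deriv_config(method = "savgol")` (default off); on smooth traces
both agree to $O(\Delta\lambda^2)$.

Each method is calibrated by ordinary least squares of its signal on
concentration ([`fit_line()`]), and inverted as
$C = (\text{signal} - b_0)/b_1$.

## Wavelengths may sit between grid nodes

Instrument software reports measurement positions such as 242.5 or 238.5 nm
that fall halfway between the nodes of a 0.2 nm grid (200.0, 200.2, ...).
`value_at()` therefore reads any trace by linear interpolation between the
bracketing nodes; at 0.2 nm spacing on smooth solution-phase bands, linear
interpolation is accurate far below the photometric noise floor, and because
it is a linear operator it preserves Beer-Lambert additivity exactly.

The same fact shapes the DW pair search. `select_pair()` scans all grid
pairs exhaustively and keeps those whose interferent difference is below a
tolerance (default 0.002 AU at the interferent's top level — the point where
"negligible" has to be quantified; it is exposed in the configuration).
Grid-quantized pairs, however, leave a residual interferent difference of up
to roughly $|A'(\lambda)| \times 0.1\,\text{nm}$, which propagates into a
concentration bias of order 0.1 ug/mL — visible at low analyte levels. The
search therefore polishes the leading pairs off-grid: one wavelength is
moved within one grid step, solving for the zero of the interpolated
interferent difference, after which the cancellation is exact to numerical
precision on interpolated data. Ranking is by analyte signal magnitude,
with ties broken by smaller interferent difference, then lower wavelength,
so results are deterministic.

## Ratio-method configuration

The divisor guard: ratio amplitudes blow up where the divisor approaches
zero, so points with divisor absorbance below `guard` (default 0.01 AU) are
masked invalid, and masked points propagate through derivatives and raise
errors when read. The published divisors (ROX 20 ug/mL for determining ASP,
ASP 36 ug/mL for determining ROX) avoid this by construction; synthetic
divisors may not.

The RD pair order is part of the configuration: `rd_calibrate()` flips the
pair if the fitted slope is negative (`orient = "positive_slope"`), so a
persisted calibration is unambiguous about sign. `rd_select_pair()` proposes
the argmax/argmin of the ratio trace over the valid interior, the
sensitivity-maximal choice.

`dd_candidate_wavelengths()` locates peaks and troughs of the mean
derivative-ratio trace (sign change of the discrete first difference, with a
minimum prominence of 1e-4 to suppress noise wiggles), regresses the signal
at each on concentration, and ranks qualifying candidates
($r \ge 0.999$) by absolute slope — the published workflow picked its
measurement wavelength the same way, by sensitivity.

`optimize_divisor()` scores candidate divisors by leave-one-out recovery RSD
over the calibration set, ties broken by higher sensitivity, then input
order. The published account of divisor optimization is qualitative
("average recovery and RSD percentage"); leave-one-out is the
interpretation that makes the metric computable from the calibration set
alone, and it is flagged as an interpretation here.

## The synthetic system

`default_models()` provides Gaussian-band stand-ins (band shape is not
constrained by the chemistry; Gaussians are adequate for solution UV bands
and analytically convenient):

```{r}
purrr::map(default_models(), tibble::as_tibble)
```

The parameters were tuned once to reproduce the *structure* the methods
need, not the real absorptivities:

* severe overlap of both components in 230-270 nm;
* the ASP-like component dark beyond ~290 nm (< 0.005 AU at 40 ug/mL at
  293 nm) while the ROX-like one still absorbs there (> 0.01 AU at
  2 ug/mL) — the asymmetry the DW/1DD determination of ROX exploits;
* usable DW pairs in both directions, and basis shapes far from
  proportional so ratio spectra are informative.

The plasma blank is a single broad short-wavelength band
(`plasma_baseline_model()`), strong below ~225 nm and fully decayed before
the long-wavelength measurement region, mimicking end-absorption of a
deproteinated, diluted plasma filtrate. Its exact shape is a free choice;
only "strong at short wavelengths, gone by 290 nm" matters to the checks.

**Noise.** `make_mixture()` adds Gaussian noise with pointwise SD
$\sqrt{\sigma_0^2 + (f\,A(\lambda))^2}$: a homoscedastic detector floor
$\sigma_0$ (AU) plus a signal-proportional photometric term $f$. "1%
relative noise" throughout the package means $f = 0.01$. The
signal-proportional reading matters: noise-propagation through the
derivative-ratio chain shows that a 1%-of-full-scale homoscedastic noise
would swamp the small derivative slopes (about 0.9 ug/mL SD per
determination for the ROX-like 1DD) and no spectrophotometric workflow
would publish 98-102% recoveries under it, whereas proportional noise gives
per-determination RSDs of ~1% (DW, RD) to ~5% (1DD), matching the
precision class the methods are known for. Shot-noise modelling beyond this
is out of scope.

## Validation statistics and conventions

* Recovery % $= 100\,\hat c/c$; precision as RSD % over replicates.
* $\mathrm{LOD} = 3.3\,\sigma/|b_1|$, $\mathrm{LOQ} = 10\,\sigma/|b_1|$,
  with $\sigma$ the residual SD of the calibration by default (the SE of the
  intercept is selectable; published tables rarely say which was used). The
  LOQ/LOD ratio is 10/3.3 by construction.
* Standard addition regresses the signal on added concentration including
  the unspiked sample at zero addition and reports the x-intercept
  magnitude, $b_0/b_1$.
* Between-method comparison uses the pooled-variance two-sample t (not
  Welch) — the degrees of freedom $n_1 + n_2 - 2$ are what assay-comparison
  tables conventionally report — and the variance-ratio F oriented
  larger/smaller so $F \ge 1$, each against 5% critical values from
  `stats::qt()`/`stats::qf()`. Published tables sometimes print the F
  critical value with the method's degrees of freedom first even when the
  comparator variance is the larger one; this package keeps the degrees of
  freedom consistent with the max/min orientation of the statistic itself.
* Summary statistics may carry both a rounded SD and a rounded variance;
  they are accepted if consistent within 5% relative, and the variance is
  what enters the tests.

## Plasma protocol arithmetic

The spiked-plasma chain is: 0.5 mL plasma + 4 mL spiking mixture + 0.5 mL
methanol precipitant (5 mL total, of which the 4 mL spike carries the
analyte), vortex/centrifuge/filter (volume-neutral no-ops in the model),
then 2 mL of filtrate diluted to 10 mL. The 5 mL intermediate volume is
inferred — it is the only arithmetic consistent with the protocol's stated
final concentrations (a 25 ug/mL spike ends at
$25 \times \tfrac{4}{5} \times \tfrac{2}{10} = 4$ ug/mL).
`final_concentration()` multiplies the aliquot and total products
separately so decimal protocol volumes reproduce their finals exactly.
Protein binding, recovery losses and extraction efficiency are deliberately
not modelled.

`interference_check()` evaluates each method's raw signal on a blank-matrix
spectrum and on the top standard and flags any |blank|/|top| ratio above 2%.
Note that an *uncorrected* synthetic blank can legitimately fail this check
at short wavelengths while blank-subtracted quantification remains accurate
— the check is about where one may measure without correction.

## Solvent greenness

`g_score()` implements the composite solvent sustainability score
$G = \sqrt[4]{H \times S \times E \times W}$ over health, safety,
environment and waste sub-scores on (0, 10]. Sub-scores are user input —
their derivation belongs to the external solvent guide — and the published
composite values for the candidate solvents (ethanol 6.6, DMSO 6.4,
methanol 5.8) ship as reference constants via
`reference_solvent_scores()`, not recomputed.

## What the tests do and do not show

The test suite and `scripts/acceptance.R` run entirely on the synthetic
system; no instrument spectra are distributed. Problem sizes, chosen for
statistical power rather than speed:

* noise-free checks (method agreement, interferent invariance,
  constant-contribution cancellation) run on a 5 x 5 mixture grid and are
  exact to numerical precision — they verify the algebra, not robustness;
* the 1%-relative-noise recovery study uses pure samples at the accuracy
  levels (10/14/22 ug/mL ASP-like, 5/9/11 ug/mL ROX-like) with 50
  replicates per level, so the SE of each mean recovery is at most ~0.8%
  (noisiest case) and the 98-102% envelope bounds *bias*, not noise;
* the blank-corrected plasma study uses 100 replicate determinations per
  concentration branch for the same reason (per-determination RSD reaches
  ~40% for the ROX-like 1DD at 2 ug/mL; the 90-110% envelope is a bias
  test).

Passing these says the implementations are faithful to their definitions
and unbiased under the stated noise model. It does not certify performance
on real spectra: real bands are not Gaussian, real baselines drift, real
noise is correlated across wavelengths, and stray light/bandwidth effects
break Beer-Lambert linearity at high absorbance. The published calibration
equations are therefore shipped as fixed constants for signal inversion,
never re-derived from the synthetic system.

## Known limitations

* One divisor per determination; no mean-centring or second-derivative
  ratio variants; binary mixtures only.
* No baseline-drift correction beyond blank subtraction, and no smoothing
  other than the optional Savitzky-Golay derivative.
* JCAMP-DX support is read-only and covers the affine
  `##XYDATA=(X++(Y..Y))` form only.
* The open question whether the original instrument smoothed spectra before
  differentiation is unresolved; both derivative operators are provided and
  configuration records which was used.
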
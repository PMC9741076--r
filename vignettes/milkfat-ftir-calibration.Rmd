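---
title: "Calibrating milk-fat fatty acid profiles from ATR-FTIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating milk-fat fatty acid profiles from ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gas chromatography is the reference method for quantifying the fatty
acid (FA) composition of human milk fat, but it is slow, solvent-heavy
and labour-intensive. Attenuated total reflection Fourier-transform
infrared (ATR-FTIR) spectroscopy of the separated fat fraction offers a
fast alternative: triglyceride absorption bands respond to the degree
of unsaturation, chain length and ester content of the constituent
acids, so a multivariate calibration can map a spectrum to relative FA
concentrations in g/100 g fat. Working on the relative scale removes
the covariation with total fat content that plagues whole-milk
calibrations.

`milkfatir` implements that calibration chain end to end:

1. **Preprocessing** — Savitzky-Golay second derivative (15-point
   window, 2nd-order polynomial) plus mean centering.
2. **PLS1 regression** — one NIPALS partial least squares model per
   target (9 individual acids and 7 sum parameters).
3. **Region selection** — per-channel selectivity ratio (SR) from a
   target projection of the fitted model; contiguous wavenumber runs
   with SR above threshold are kept and the model refitted on them.
4. **Validation** — contiguous-blocks cross-validation (10 splits) on
   a training set of 35, parsimonious latent-variable (LV) choice, and
   external prediction of a 15-sample validation set, reported as
   RMSEC/R², RMSECV/R²CV, RMSEP/R²P.
5. **Clinical analyses** — ordinary least-squares trends of the
   predicted profile against days postpartum, Welch and rank-sum
   comparisons of pasteurized versus unpasteurized milk, and a screen
   of further covariates.

A synthetic spectra generator reproduces the statistical structure this
chain assumes, so every stage is testable without laboratory data.

## Models and conventions

### PLS1 (NIPALS)

For centred spectra $X$ and centred response $y$, each component takes
$w = X^\top y / \lVert X^\top y \rVert$, $t = Xw$,
$p = X^\top t/(t^\top t)$, $q_a = y^\top t/(t^\top t)$, then deflates
$X \leftarrow X - tp^\top$, $y \leftarrow y - tq_a$. The regression
vector is $b = W(P^\top W)^{-1}q$, and predictions are
$\hat y = \bar y + (x - \bar x)^\top b$. If the residual covariance
vanishes before the requested number of components, fitting stops early
with a warning and the achieved count is kept. PLS1 coefficients are
algorithm-invariant, which is what the test suite exploits when
cross-checking against an independent implementation and against
ordinary least squares at full rank.

### Selectivity ratio

The fitted model's target projection is
$t_{TP} = Xb/\lVert b\rVert$, $p_{TP} = X^\top t_{TP}/(t_{TP}^\top t_{TP})$,
$\hat X = t_{TP}p_{TP}^\top$, $E = X - \hat X$, and the per-channel
selectivity ratio is the explained-to-residual sum-of-squares ratio
$SR_j = \sum_i \hat X_{ij}^2 / \sum_i E_{ij}^2$. Channels with zero
total variance get $SR = 0$; channels whose residual falls below
$10^{-15}$ of the explained part are capped at $10^{15}$. Selection
keeps channels with $SR \ge 1$ (explained exceeds unexplained), groups
them into contiguous runs, drops runs shorter than 5 channels
(10 cm⁻¹), and falls back to the top SR decile with a warning if
nothing survives — a model can always be built, and the warning marks
targets whose spectra carry little selective information.

Which latent-variable count feeds the SR model is an open choice; here
a full-spectrum cross-validation picks it, the SR mask is derived, and
the masked model then gets its own cross-validated LV choice
(two-pass). The region selection runs once on the full training set
before cross-validation. That matches the sequence "regions chosen,
then calibrations evaluated by CV", and is mildly optimistic: the
out-of-fold samples did influence the mask. A nested selection would
remove the bias at roughly tenfold cost; the external validation set,
which never enters selection, is the honest check.

### Cross-validation and figures of merit

Contiguous-blocks CV cuts the training samples, in their file order,
into 10 consecutive runs (with $n = 35$: five blocks of 4, then five of
3). The Savitzky-Golay filter is applied once globally — it is
per-sample and uses no cross-sample statistics, so it cannot leak —
while mean centering is refit inside every fold. RMSE is
$\sqrt{\sum(\hat y - y)^2/n}$ with no degrees-of-freedom correction,
the common chemometrics-toolbox convention. R² is
$1 - SS_{res}/SS_{tot}$ (not a squared correlation), with $SS_{tot}$
about the training-set mean for calibration and CV and about the
validation-set mean for external prediction. The LV count is the
smallest whose RMSECV is within 2% of the curve minimum (parsimony); an
exact-minimum rule and manual override are available.

### Sum parameters and the SAT/UNSAT mirror

Sum parameters are sums over member acids: MONO = C16:1cis + C18:1cis,
PUFA = C18:2cis, UNSAT = MONO + PUFA, SCFA = C8:0 + C10:0 (C10 and
shorter), MCFA = C12:0 + C14:0 + C16:0 + C16:1cis (C11–C16), LCFA =
C18:0 + C18:1cis + C18:2cis (C17 and longer). The unmodelled remainder
of the panel (`OTHER`) is counted as saturated by default
(`include_other_in_sat = TRUE`), so SAT + UNSAT = 100 exactly. Under
that closure $y_{SAT} = 100 - y_{UNSAT}$, and because PLS1 on centred
data is equivariant under an affine reflection of $y$ (every quantity
in the fit negates exactly, including the selectivity ratios and hence
the selected regions), the SAT and UNSAT calibrations have *identical*
absolute errors — a strong internal consistency check the pipeline
asserts at $10^{-9}$. The chain-length classes leave `OTHER`
unallocated, so SCFA + MCFA + LCFA + OTHER = 100.

## The synthetic generator

`generate_dataset()` emulates the study conditions the pipeline
expects: 50 samples, a 600–4000 cm⁻¹ grid at 2 cm⁻¹ (1701 channels),
compositions drawn uniformly within per-acid ranges typical of mature
human milk fat (C16:0 12–22, C18:1cis 28–51, C18:2cis 16–47, trace
C8:0 0–0.15 g/100 g fat, …), with `OTHER` closing each row to 100 and
draws that would drive it negative rejected.

Spectra are sums of Gaussian bands whose amplitudes respond linearly to
composition descriptors: a double-bond index (MONO + 2·PUFA) drives the
cis =C–H stretch at 3006 cm⁻¹, a mean-chain-length proxy drives the
CH₂/CH₃ stretching and rocking bands, ester density drives the C=O and
C–O bands, and a free-fatty-acid nuisance descriptor (mean 2, jitter
0.5 g/100 g) drives the 1710/1570 cm⁻¹ acid bands *only* — those bands
carry no composition information, so region selection should learn to
ignore them. A CH₂-wagging progression series (1200–1350 cm⁻¹) plus a
C–O band adds a per-acid signature, each acid's dominant band shared
only with its chain-length neighbours, and a collective medium-chain
deformation band (1435 cm⁻¹) responds to the MCFA members jointly.
Together these make the composition-to-spectrum map full rank over the
nine modelled acids — the designed-in identifiability that guarantees,
at the default noise, R²CV ≥ 0.95 for the main sum parameters; trace
acids (C8:0) remain near-unpredictable because their variance is tiny,
mirroring how trace acids behave in practice. A linear baseline
(offset sd 5·10⁻³ AU, slope sd 10⁻⁶ AU/cm⁻¹) and white noise
(10⁻⁴ AU) are added; the second derivative annihilates the baseline
exactly.

Clinical structure: days postpartum uniform on 5–400 (median ≈ 200,
IQR ≈ 200, matching mature-milk donor cohorts); a lactation trend of
+0.055 g/100 g fat/day on the MCFA members, −0.015 on C18:0/C18:1cis
and −0.040 on C18:2cis, applied about the midpoint of the day range so
compositions stay in their ranges, with slopes summing to zero so
closure is preserved exactly. Magnitudes were set by a power analysis:
against the compositional variance implied by the sampling ranges, an
OLS slope test at n = 50 then has ≳95% per-target power, so a study of
this size reliably recovers all three trend directions. Pasteurization
flags go to half the samples and have, deliberately, no composition
effect — the pipeline should find nothing. Sex, gestational age,
maternal age and birth weight are drawn independently of composition.

What the generator does *not* emulate: ATR penetration-depth
dispersion, scattering artifacts, water-vapour lines, band-shape
changes (Lorentzian wings, matrix shifts), correlated noise, and any
nonlinearity between composition and absorbance. Passing tests
therefore demonstrate that the chain recovers a linear spectral
encoding under realistic noise — not that a particular instrument will
achieve the same figures on real milk.

## Numerical choices

* **Derivative scaling and edges.** The windowed polynomial derivative
  is divided by (Δν)², giving physical AU/(cm⁻¹)² units; any positive
  scale would be equivalent after centering, but units must be
  declared. The 7 channels at each edge have no complete window and
  are dropped (the grid is trimmed), rather than extrapolated — edge
  polynomials create artifacts that region selection could latch onto.
* **Order of operations.** Derivative first, centering second; for a
  linear filter the order is immaterial, it is fixed for
  reproducibility.
* **Split.** Stratified by pasteurization status with
  largest-remainder rounding (26/24 strata at 35/15 give 18+17
  training), shuffled by a seeded RNG; sample order for the contiguous
  blocks is the input file order, and the split is stored with the
  registry so runs are reproducible.
* **Degeneracies.** Zero-variance targets are skipped with a warning;
  zero covariance stops deflation early; zero-variance references make
  R² undefined (reported as missing); a regression vector of zero is a
  hard error for the selectivity ratio.
* **Problem sizes.** The shipped tests and the acceptance script run
  the full chain at the study scale (n = 50, 1701 channels, 16
  targets, two CV passes of 10 folds × 10 LVs), which completes in a
  few seconds; replicate studies (50 datasets) complete in well under
  a minute.

## Limitations

Absolute FA concentrations are out of scope — all outputs are relative
(g/100 g fat). The SR-before-CV sequence is mildly optimistic, as
discussed. The membership of `OTHER` is a modelling convention; if the
unmodelled acids of a real panel are not predominantly saturated, set
`include_other_in_sat = FALSE` and the SAT/UNSAT mirror no longer
holds. The trend analysis is a straight line on an unpaired
cross-section; longitudinal designs need mixed models, which this
package does not provide.

## A worked run

```{r, eval = FALSE}
library(milkfatir)

ds <- generate_dataset(synthetic_config(n_samples = 50, seed = 42))
reg <- train_all_targets(ds$spectra, ds$profile, ds$clinical,
                         pipeline_config(seed = 42))
print(reg)                       # Table-1-style figures of merit

prof <- predict_profile(reg, ds$spectra)
clinical_analysis(prof, ds$clinical,
                  targets = c("MCFA", "LCFA", "PUFA"))$trends
```
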
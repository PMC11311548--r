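---
title: "Shelf-life kinetics and FTIR chemometrics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shelf-life kinetics and FTIR chemometrics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxishelf)
```

# What this package models

`oxishelf` analyses accelerated-storage studies of lipid-containing foods
(the motivating system is green coffee beans) in which two oxidation
markers are followed over storage time at several temperatures:

* **PV** — peroxide value, the primary oxidation marker, in
  milliequivalents of peroxide per kg of extracted oil (iodometric
  titration);
* **TBARS** — thiobarbituric acid reactive substances, the secondary
  oxidation marker, quantified as malondialdehyde (MDA) in nmol per g of
  sample from absorbance at 532 nm with a 600 nm turbidity baseline.

Alongside the wet-chemistry markers, each sample is measured by ATR-FTIR
over the mid-infrared range, and latent-variable regression links the
spectra to the oxidation state.

# Assay arithmetic

The assay layer is deliberately plain arithmetic, kept separate so each
conversion is auditable:

* moisture, wet basis: $100 \cdot \Delta m / m$;
* peroxide value: $\mathrm{PV} = 2 (V_s - V_b) / m_{oil}$, with the
  titrant normality folded into the conventional factor 2 for 0.002 M
  thiosulfate;
* TBARS: $c_{\mathrm{MDA}} = (A_{532} - A_{600}) / (\varepsilon \ell)$ in
  mM, scaled by extract volume, dilution and sample mass into nmol/g.

The TBARS extract volume and dilution are **explicit parameters**, not
hard-coded protocol constants: published TBARS protocols rarely document
the full volume accounting, and hiding assumed volumes inside the formula
would make the output unauditable. Negative PV (blank exceeding sample)
is returned with a warning rather than clipped — it is diagnostic of assay
failure and should reach QC intact. A helper converts nmol/g to mg/kg
(× 0.07207, MDA molar mass 72.07 g/mol) because the two unit conventions
coexist in the literature.

# Kinetic and Arrhenius model

Oxidation growth is modelled per storage temperature by either

* zero order: $y(t) = y_0 + k t$, or
* first order: $\ln y(t) = \ln y_0 + k t$,

fitted by ordinary least squares with replicates pooled into one
regression (pooling uses all information; the per-cell SD is instead
obtained by refitting the entire chain on each replicate separately).
Order selection compares the two fits' $R^2$ (squared correlation of
fitted vs observed); ties go to first order, whose form the shelf-life
expression assumes. A printed first-order law of the form
"$y = kt + \ln y_0$" is dimensionally inconsistent; the integrated law
above is the only reading compatible with the closed-form shelf life.

Temperature dependence follows Arrhenius,
$\ln k = \ln k_0 - E_a / (RT)$ with $R = 8.3144$ J K$^{-1}$ mol$^{-1}$,
fitted as a straight line in $1/T$ ($T$ in kelvin, $K = {}^\circ C +
273.15$). Shelf life to a quality endpoint $y_c$ at temperature $T$ is

$$\mathrm{SL}(T) = \frac{\ln y_c - \ln y_0}{k_0 e^{-E_a/(RT)}}
\quad\text{(first order)},\qquad
\mathrm{SL}(T) = \frac{y_c - y_0}{k(T)} \quad\text{(zero order)}.$$

**Endpoints are a required, echoed parameter.** No universally accepted
critical PV or TBARS exists for green coffee; the defaults (PV = 2.0
meq/kg, TBARS = 12 nmol/g) were chosen once so that, with the generator's
default kinetics, predicted shelf lives land in the tens-of-days (PV) and
days-to-two-weeks (TBARS) ranges typical of accelerated-storage studies
of green coffee. Every output row carries `endpoint_used`; there is no
hidden constant.

A practical caveat the tests quantify: with three temperatures, the
Arrhenius line is best constrained in the middle of the $1/T$ range.
Shelf-life recovery on synthetic data is ~2–4 % (median) at 40–50 °C but
~9 % at the 30 °C edge, where the regression amplifies its own slope
uncertainty. Conclusions about the lowest temperature are the softest.

# Spectral preprocessing

Two pretreatments are implemented, in either order:

* **SNV** (standard normal variate): each spectrum is centred and scaled
  to unit sample SD ($n-1$ denominator). This removes exactly the
  per-spectrum multiplicative scatter and additive offset that the
  synthetic generator injects; any affine transform of a spectrum has the
  same SNV image. A constant spectrum has no defined SNV and is an error
  naming the sample.
* **Savitzky–Golay first derivative**: local polynomial least squares on
  a sliding window, differentiated with respect to the *physical*
  wavenumber axis so values have units of absorbance per cm$^{-1}$.
  Window 11 and polynomial order 2 are the de facto standard in FTIR
  chemometrics and are exposed as parameters; the source protocol names
  the derivative but not the algorithm. Edge channels are handled by
  fitting the polynomial on the truncated end window and differentiating
  it at each edge position, so the grid length is preserved. The filter
  is exact on polynomials up to the chosen order, which is what the tests
  assert.

The default recipe is SNV then derivative (the order in which the two are
conventionally listed); both orders are supported and produce different
matrices on scattered data, so the applied order is recorded in the
dataset's preprocessing log and serialised with the outputs.

# PLS, cross-validation, VIP, PCA

The calibration model is PLS1 by NIPALS with X-deflation: weights
$w_a \propto X_a' y_a$, scores $t_a = X_a w_a$, loadings
$p_a = X_a' t_a / t_a' t_a$, $q_a = y_a' t_a / t_a' t_a$. X and y are
mean-centred, not variance-scaled (standard for derivative spectra;
centring is switchable). The regression vector $b = W (P'W)^{-1} q$
reproduces training predictions, and scores are mutually orthogonal —
both are tested invariants, and the fitted values are cross-checked in
the test suite against an independent Krylov-subspace closed form (the
A-component PLS1 solution is the least-squares solution restricted to
$\mathrm{span}\{s, Ms, \dots, M^{A-1}s\}$, $s = X'y$, $M = X'X$).

Metrics follow the chemometrics conventions: RMSECV from leave-one-out
refits, $R^2 = 1 - SS_{res}/SS_{tot}$ on held-out predictions (the
squared-correlation variant is also reported, since published tables
rarely say which definition they use), and RPD $= sd(y)/\mathrm{RMSE}$.
Auto-prediction (fit and evaluate on all samples) is reported alongside
LOOCV; it is optimistic by construction, and the acceptance suite checks
`auto R² ≥ LOOCV R²` on every run. Ten latent variables is the default to
mirror common practice with ~78-sample FTIR calibrations, always exposed
as a parameter, with a minimum-RMSECV selector provided.

**VIP** uses Wold's formula,
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\|w_a\|)^2 /
\sum_a \mathrm{SSY}_a}$ with $\mathrm{SSY}_a = q_a^2 t_a' t_a$, whose
squared scores average to 1; bands are maximal runs of channels with
VIP ≥ 1, reported as wavenumber intervals in descending order.

A genuine interaction between preprocessing and VIP, documented here
because it is easy to misread in band tables: the first derivative of a
Gaussian band is **zero at the band apex**. After derivative
preprocessing, the informative channels are the band's flanks, and VIP ≥ 1
intervals bracket rather than contain the apex (on the default grid the
gap at a planted apex is ~6 cm$^{-1}$ wide). Apex-coverage checks (and
users interested in "which peak centres matter") should therefore run VIP
on SNV-only spectra; Table-2-style performance metrics keep the full
SNV + derivative recipe.

**Outliers** are never removed silently: the deterministic rule flags
samples whose LOOCV residual exceeds 3 × the MAD-based robust scale
(constant 1.4826); removal is an explicit user action.

**PCA** is mean-centring plus SVD, with explained variance from squared
singular values; by default the spectra are augmented with the PV and
TBARS columns before decomposition (the score plot is then of the joint
oxidation/spectral structure), and spectra-only mode is available.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the design of a
two-process accelerated storage study:

* processes DP (dry/natural) and HP (honey), temperatures 30/40/50 °C,
  sampling at 0/5/10/15/20 days, 3 replicates;
* day 0 is a single unpackaged control per process, shared across
  temperatures — this is the only accounting consistent with 26 distinct
  samples (2 × 3 × 4 stored + 2 controls), i.e. 78 spectra at 3
  replicates;
* latent PV/TBARS trajectories follow first-order kinetics with
  $E_a = 50$ kJ/mol and pre-exponential factors chosen so PV spans
  ≈ 0.7–3.2 meq/kg and TBARS ≈ 7–27 nmol/g over 20 days across 30–50 °C —
  the ranges reported for green coffee under accelerated storage.
  Measurement noise is Gaussian with SD 0.05 meq/kg for PV and 0.5 nmol/g
  for TBARS (a single scalar cannot serve both scales; both are ~2–5 %
  relative);
* spectra are 12 Gaussian bands (σ = 15 cm$^{-1}$) at the absorbance
  maxima characteristic of green coffee (3313, 3010, 2925, 2854, 1745,
  1645, 1458, 1377, 1248, 1157, 1049, 715 cm$^{-1}$) on 1869 equally
  spaced channels over 401–4000 cm$^{-1}$ (spacing ≈ 1.93 cm$^{-1}$; the
  channel count, not a nominal 4 cm$^{-1}$ resolution, fixes array
  shapes). The bands at 2854 (aliphatic C–H of the fatty-acid backbone)
  and 1745 cm$^{-1}$ (ester carbonyl) respond linearly to the latent PV
  and TBARS; the rest are static background chemistry;
* artefacts are exactly those SNV + derivative are designed to remove:
  per-spectrum lognormal multiplicative scatter (log-SD 0.05), a random
  linear baseline, and additive channel noise (SD 0.002 absorbance).

Every draw derives from the config seed through keyed sub-streams, so a
study is bit-for-bit reproducible and each generator call is
independently deterministic. Oxidation series and spectra share the same
latent states, so the generating truth is recoverable end to end.

**What a green test does not establish.** The generator is stylised: real
coffee spectra are not sums of 12 Gaussians, real PV is non-monotone
(it can decline after ~15 days as hydroperoxides decompose — a linear
decline hook exists in the config, default off, because the kinetic
models themselves assume pure growth), replicates are i.i.d. rather than
nested per bag or grind, and moisture/water-activity time courses are not
modelled. Green tests establish that the *computations* are correct and
that the pipeline recovers known structure at realistic noise — not that
the models are adequate for any particular real dataset.

# Numerical and interface choices

* OLS fits use QR (`lm.fit`); Arrhenius and first-order fits are linear
  in log space, so noiseless recovery is exact to ~10$^{-12}$ and is
  tested at 10$^{-9}$.
* NIPALS stops with an informative error when X deflates to numerical
  rank below the requested number of latent variables.
* $R^2$ of a zero-variance (constant) series is reported as 0 with a
  `zero_variance` flag rather than NaN.
* CSV is the interchange format (wide spectra with a `wavenumber_cm1`
  column, or long `sample_id,wavenumber_cm1,absorbance`, plus a metadata
  sidecar); descending grids are reversed on read with a message. Run
  configurations are JSON (no YAML parser in the supported dependency
  set); the manifest records package version, seed, the full config and
  an FNV-1a hash of its canonical JSON, so a run is reproducible from its
  manifest.
* All computation happens before any report file is written, so a
  failing stage leaves the output directory untouched.

# Known limitations

* Only SNV and the SG first derivative are implemented (no MSC,
  detrending or atmospheric correction) — matching the preprocessing the
  analysis workflow actually uses.
* Only PLS1 (one response at a time), no PLS-DA/OPLS.
* The Arrhenius chain assumes the same kinetic order at all temperatures
  within a process/response cell.
* Shelf-life uncertainty is replicate-resampling SD, not a full
  error-propagation or bootstrap interval.
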
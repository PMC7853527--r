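---
title: "From variable fluorescence to carbon: the phiec methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From variable fluorescence to carbon: the phiec methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phiec)
```

## The problem

Fast repetition rate fluorometry (FRRf) measures, in real time and at depth,
the photochemistry of photosystem II (PSII): fluorescence yields under dark
(`Fo`, `Fm`) and ambient light (`Fo'`, `F'`, `Fm'`), and the functional
absorption cross section `sigma_PSII` (nm²). From these one can derive a
volumetric electron transport rate — but ecologists usually want carbon.
The bridge is the electron requirement for carbon fixation,
$\Phi_{e,C}$ (mol e⁻ per mol C fixed, mechanistically ≥ 4), which varies
with temperature, light, nutrients, and community composition. `phiec`
implements the full inference chain from FRRf casts and bottle incubations
to a statistical model of $\Phi_{e,C}$ and to daily, depth-integrated gross
primary productivity (GPP), together with a synthetic campaign generator
that provides ground truth for every stage.

## The chain, stage by stage

**Quality control.** Records are kept when the probability of a reaction
centre closing during the first saturation flashlet, dark and under ambient
light, lies within the closed band [0.03, 0.08]; the instrument targets
0.05, and values outside the band indicate under- or over-saturating flash
energy. The bounds are inclusive because the rejection rule is strictly
"below 0.03 or above 0.08". Cyanobacteria-dominated samples can carry a
dark-state bias in `Fo`; the package flags such dates (via the biomass
fraction) but, matching field practice, applies no correction.

**Photophysiology.** `Fv/Fm = (Fm−Fo)/Fm`, the open-centre fraction
`qP = (F'−Fo')/(Fm'−Fo')` (identified with 1−C), and the normalised
Stern–Volmer quenching `NPQ_NSV = Fo'/(Fm'−Fo')`. Records with
`Fm' = Fo'` have undefined ratios and are flagged out.

**Reaction centres and electron transport.** RCII concentration
(nmol m⁻³) comes from `RCII = (K_R/E_FRRf) · (Fo/sigma_PSII) · 10⁻⁹`, with
`K_R/E_FRRf` a single configured instrument constant. The RCII-specific
electron transport rate is `J_f = E · sigma_PSII' · qP`, with the ambient
cross section first multiplied by the spectral correction factor (below).
Because `sigma` is quoted in nm² while PAR is in µmol photons m⁻² s⁻¹, a
single documented unit bridge (`sigma_unit_scale()`, the Avogadro-based
6.022×10⁻⁴) lands `J_f` in µmol e⁻ nmol RCII⁻¹ s⁻¹. The published unit
chain for these equations is not fully explicit; the bridge is therefore a
configurable constant whose correctness is asserted by the noise-free
round trip, not assumed.

**Underwater light.** PAR profiles are fitted log-linearly
(`E(z) = E(0) e^{-K_d z}`); a two-layer fit is adopted when the best
breakpoint improves the residual sum of squares by an F test at α = 0.05
with a Bonferroni correction over the searched breakpoints (without it,
selecting the best break first inflates the false-split rate several-fold).
Spectral irradiance at depth follows Beer–Lambert attenuation over a
400–700 nm grid with a four-part absorption budget: pure water, CDOM
(`a_CDOM(320) e^{-0.017(λ-320)}`, with basin-specific anchors 1.03 and
2.28 m⁻¹), non-algal particles (`0.264 e^{-0.004(λ-440)}`), and
chlorophyll-scaled phytoplankton absorption `a*phy`. The spectral
correction factor

$$SCF = \frac{\sum a^*_{phy} E_{insitu} \cdot \sum E_{FRRf}}
             {\sum a^*_{phy} E_{FRRf} \cdot \sum E_{insitu}}$$

uses plain grid sums on a 1 nm grid (the definition is written as a sum,
not an integral; the step is configurable) and is applied to
`sigma_PSII'` and to growth-chamber PAR. All spectra here — pure water,
the two `a*phy` variants, LED and chamber lamps, and incident sunlight —
are smooth synthetic stand-ins generated in code: shaped like their real
counterparts (chlorophyll peaks at 440/675 nm, a phycocyanin shoulder at
630 nm for the cyanobacteria variant), but not copies of any published
coefficient table, which keeps every test independent of external data.
The `a*phy` variant switches to the cyanobacteria shape when the
cyanobacterial biomass fraction of a date exceeds 30%.

**Incubations.** Light-dark oxygen bottles give
`JV_O = (NP_O − R_d) × 3.47×10⁻²` (hours→seconds, mg→µmol O₂, 4 e⁻ per
O₂). ¹³C bottles give gross carbon fixation by the standard isotope-mixing
form `GP_C = POC · (a_inc − a_nat)/(a_DIC − a_nat)/t` — the tracer
equation the field's standard citation denotes, with a configurable
natural-abundance default of 1.1 atom% — and `PB_C = GP_C/RCII`.

**P–E curves and the electron requirement.** `PB_C` against
SCF-corrected chamber irradiance is fitted with the two-parameter
saturating exponential `P = P_s(1 − e^{-αE/P_s})` or, when the response at
the highest light level falls more than 5% below the observed maximum
(a configurable stand-in for "declining after the light-saturated phase"),
the three-parameter exponential-photoinhibition form
`P = P_s(1 − e^{-αE/P_s})e^{-βE/P_s}`. The three-parameter equation is the
canonical Platt-type form in the lineage the field cites; it nests the
two-parameter form exactly at β = 0. Fits use Levenberg–Marquardt with
positivity bounds and deterministic starts (α from the low-E secant,
`P_s` from the maximum response, β = 0.01α); non-convergence is reported
in a flag, never silently. Each FRRf record is then paired with the fitted
curve's `PB_C` at its own in-situ E — per-observation rather than on a
depth grid, since every record carries its own irradiance — and

$$\Phi_{e,C} = \frac{J_f}{PB_C} \times 43.2$$

(seconds→hours, µmol→mg C). Values below the mechanistic floor of 4 are
kept and labelled *apparent*: bottle artifacts affect all bottles alike,
so excluding them would bias the model.

**Statistical model.** To undo the sampling imbalance between shallow and
deep layers (high light aborts FRRf acquisitions), each date is resampled
with replacement to 240 observations: 60 from each of four layers
(0–3.75, 3.75–7.5, 7.5–12.5, 12.5–17.5 m) in the deep basin, 80 from each
of three (0–1, 1–3, 3–5.5 m) in the shallow one; a 14-date campaign gives
3360 rows, 1680 per basin. Resampling seeds derive from the global seed
per (date, stratum), and each stratum pool is put in a canonical order
first, so results are independent of row order. Candidate covariates are
screened by Spearman correlation (|ρ| ≥ 0.7 with p < 0.05 via the
large-sample t approximation, average ranks for ties); among flagged
pairs the thirteen named covariates are retained as proxies (e.g.
diatoms absorb the zygnematophyte signal, PAR absorbs `NPQ_NSV`).
Covariates are substituted at detection limits (NH₄ 0.1 µmol L⁻¹;
biomass fractions 0.1%), log-transformed, and standardised. $\Phi_{e,C}$
is fitted by a gamma GLM with log link; every subset of the 13 candidate
terms (2¹³ = 8192 models) is ranked by AIC, with named extracts for the
best model, the best without nutrient chemistry, and the best without
nutrients and microscopy. Because a gamma GLM has no canonical R², both
the squared Pearson correlation of observed and fitted response and the
deviance-based 1 − D_res/D_null are reported, neither privileged. VIFs
are computed for every term of a fitted model.

**Daily productivity.** `PB_f = J_f/\hat\Phi_{e,C} × 43.2` converts
electron transport to carbon through the fitted requirement model. Daily
GPP integrates `RCII(z) · Σ_t PB(z,t)` over depth by the trapezoid rule on
a 1.25 m grid (deep basin) or 0.5 m grid (shallow basin), with hourly PB
evaluated from the date's P–E curve at `E(z,t) = E_0(t) e^{-K_d z}`
(layered). The diel course of surface PAR is a half-sine over the day
length — hourly steps match the summation the definition writes. GPP is
reported in mg C m⁻² d⁻¹; the g C m⁻² d⁻¹ unit sometimes printed for
lake values of this magnitude is dimensionally implausible, and the
package states its unit explicitly rather than silently matching.

## The synthetic campaign generator

The generator emulates a two-basin, 14-date seasonal campaign (seven
dates per basin; deep-station casts every 1–2 m to 10 m and sparser
below, shallow-station casts every 0.5 m) and is built by inverting the
analysis chain, which is what makes the noise-free round trip exact:

1. each date owns surface PAR `E_0` (150–1700 µmol photons m⁻² s⁻¹, the
   span of the field campaign), a one- or two-layer `K_d` (0.25–0.55 m⁻¹
   deep basin, 0.6–1.9 m⁻¹ shallow, matching the reported range), a sky
   state, and a true P–E curve for `PB_C` (α 0.012–0.03, P_s 1.2–2.5);
2. covariates are drawn per depth with smooth vertical structure and a
   seasonal sinusoid, spanning the reported field ranges (temperature
   7.5–30.2 °C, PO₄ 0.01–0.04 µmol L⁻¹, …); biomass fractions come from
   normalised gamma draws, so the compositional negative correlation
   (diatoms vs zygnematophytes) arises naturally rather than by fiat;
   beyond that the covariates default to independence, since no joint
   distribution is reported;
3. the true requirement is `Φ = exp(β₀ + zᵀβ) · ν`, with `z` the
   log-standardised covariates of the whole campaign, β the field-scale
   coefficient vector (temperature 0.51, PAR 0, cyanobacteria −0.20, …)
   and ν mean-1 gamma noise with shape 5 — chosen so the campaign's
   explained variance is comparable to the field study's R² ≈ 0.67 —
   and `J_f = Φ · PB_C / 43.2` is back-computed, with `sigma_PSII'`
   recovered from `J_f = E · σ' · qP`;
4. yields are reconstructed by inverting their definitions (`Fo` from
   RCII, `Fm` from `Fv/Fm`, `Fm'` from `NPQ_NSV`, `F'` from `qP`), and
   incubation observables (O₂ differences, ¹³C atom fractions, POC) are
   forward-simulated so the incubation module recovers `GP_C` exactly.

Each depth carries five replicate acquisitions (`n_casts`), matching the
protocol of repeating every excitation sequence several times per depth.
Measurement noise is a lognormal multiplier per acquisition and light
state — the dark yields share one multiplier, the ambient yields another,
and each cross section has its own — because within one acquisition the
yields share gain and biomass fluctuations; fully independent per-yield
noise would produce the physically impossible `F' < Fo'`. About 2% of
acquisitions draw an out-of-band closure probability, exercising the
quality gate. Photoinhibited
dates (the two brightest by default) solve β per date so the brightest
incubator level sits 25% below the observed peak, keeping the truth's
curve family unambiguous under the 5% model-choice rule. Dispersion `Inf`
and noise 0 switch the campaign to exact mode.

What the generator does *not* emulate: flashlet-level induction
transients (generation starts at derived yields), state transitions in
cyanobacteria, bottle artifacts (UV relief, wall growth), or diel changes
in `J_f`. Passing tests therefore validate the inference chain, not the
instrument physics or incubation biases of real campaigns.

## Numerical choices and degenerate inputs

* Breakpoint ties in the two-layer `K_d` fit resolve to the deepest
  equivalent break, so a boundary observation belongs to the upper layer;
  non-attenuating profiles clamp at `K_d = 10⁻⁶ m⁻¹` and are flagged.
* The P–E optimiser runs with tight tolerances (1e-14) and an iteration
  cap; exact data are recovered to near machine precision, which the
  round-trip test requires.
* `Fm' = Fo'` (undefined `qP`), zero isotopic gradients, non-positive
  `RCII`, and empty bootstrap strata all fail loudly with the offending
  record or stratum named, never silently.
* All-subset fits reuse a precomputed model matrix through `glm.fit`;
  its AIC matches `stats::AIC` on the equivalent `glm` object, which a
  self-consistency test asserts.
* Standardisation moments travel with the transformed table as
  attributes, so model predictions for new records reuse the fitting
  scale.

## Problem sizes in the tests

The test suite exercises the chain at the campaign scale the package
targets: 14-date campaigns (~160 raw records, 3360 bootstrap rows) for
round trip, counts, and coefficient recovery (20 replicate seeds); 100
replicate curves for P–E recovery; and reduced candidate sets (k ≤ 6)
for the model-selection consistency property, with the full 2¹³
enumeration exercised once for count and AIC self-consistency. These
sizes keep the whole suite within a few minutes on one CPU while leaving
every statistical check at its intended effect size.

## Known limitations

* The requirement model is correlational; coefficients describe the
  synthetic (or supplied) campaign, not mechanisms.
* GLM standard errors treat bootstrap rows as independent, so they are
  optimistic relative to the ~160 underlying observations — inherent to
  the resampling design; the replicate-seed tests quantify the real
  scatter.
* No interaction terms, mixed effects, or spatial error structure.
* Radiative transfer is absorption-only Beer–Lambert: no scattering
  phase functions or surface reflection.
* The `a*phy` switch is binary (cyanobacteria-type vs eukaryote-type);
  real communities blend continuously.
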
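---
title: "Quenching analysis for chilled leaf discs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quenching analysis for chilled leaf discs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npqkit)
library(dplyr)
```

## The measurement and its quantities

Pulse-amplitude-modulated (PAM) fluorometry probes photosystem II by firing
saturating flashes at a dark-adapted leaf disc and then during and after a
period of actinic light. The dark-adapted minimal and maximal fluorescence
(F~o~, F~m~) give the maximum quantum yield of PSII,

$$F_v/F_m = (F_m - F_o)/F_m,$$

and each saturating flash under light gives a momentary maximum F~m~′ from
which non-photochemical quenching is computed under the Stern–Volmer model,

$$\mathrm{NPQ}(t) = F_m / F_m'(t) - 1.$$

`compute_fvfm()` and `compute_npq()` implement exactly these, on a tidy
flash table (one row per disc per flash). Steady-state fluorescence F~s~ is
stored for provenance but used by no computed quantity. Two flash-schedule
presets are built in (`protocol_preset()`), matching the two imagers'
printed schedules: 10 min of 2000 µmol m⁻² s⁻¹ actinic light followed by
10 min of darkness, with flashes at fixed times. The light phase is the
half-open interval [light-on, light-off), so a flash at exactly the
light-off minute is classified as dark — a deterministic convention rather
than a physical claim.

## Adjusted NPQ: correcting a quenched dark reference

A chilling night can induce quenching that persists into the dark-adapted
state (sustained, zeaxanthin-associated quenching). The measured dark F~m~
of such a disc is then already quenched, which both depresses F~v~/F~m~ and
deflates every subsequent NPQ value, because F~m~ sits in the numerator.

The adjustment uses warm-treated discs of the same accession as an
unquenched reference. If the warm yield is $r_w = (F_v/F_m)_{warm}$ and the
cold disc's minimal fluorescence is unaffected by the sustained quenching,
the unquenched maximum of the cold disc can be reconstructed as

$$F_{m,true} = \frac{F_{o,cold}}{1 - r_w},$$

giving the quenching already present in darkness,
$\mathrm{NPQ_A(dark)} = F_{m,true}/F_{m,cold} - 1
= (1 - r_c)/(1 - r_w) - 1$, and at each flash
$\mathrm{NPQ_A}(t) = F_{m,true}/F_m'(t) - 1$. Two exact identities follow
and are enforced by tests: when $r_w = r_c$ the adjusted and measured
curves coincide, and at every flash
$(\mathrm{NPQ_A} + 1) = (\mathrm{NPQ} + 1)(\mathrm{NPQ_A(dark)} + 1)$.

The transcription of the dark-point formula in the source protocol
contains an unbalanced parenthesis; read literally it violates the first
identity (it is nonzero when warm and cold yields agree). `npqkit`
implements the form forced by the construction above and by
$F_{m,true} = F_{m,cold}(\mathrm{NPQ_A(dark)}+1)$; the literal
transcription remains available behind `literal = TRUE` for audit and
warns when used.

Two open choices were settled as follows. The warm reference defaults to
the mean F~v~/F~m~ of all warm-treated discs of the same accession
(`warm_reference()`), because the protocol pools "warm-treated samples"
without specifying pairing; any other pooling (per replicate, per plate)
can be requested through the `by` argument. And the cold disc's own F~o~
enters the reconstruction — the formula's subscripts name it — so the
method is exact precisely when sustained quenching leaves F~o~ untouched.
The synthetic generator exposes `f_o_quench_factor` to probe what happens
when that assumption is violated.

## Induction kinetics

The light-phase rise of NPQ is summarised by a rectangular hyperbola

$$\mathrm{NPQ}(t) = \frac{A\,t}{t + K},$$

with amplitude $A$ (dimensionless), half-saturation time $K$ (minutes), and
initial slope $A/K$ (min⁻¹) reported as the *NPQ induction rate* — the
derivative of the curve at light onset. The source protocol cites a
companion method for the fit without reproducing the equation; the
rectangular hyperbola is the simplest two-parameter hyperbola consistent
with a saturating rise, and both $A$ and $A/K$ are exported so either
convention can be compared downstream. Fits are per disc
(`fit_npq_kinetics()`), and group statistics operate on per-disc rates,
matching the per-replicate presentation of the source figures.

Numerical choices: Levenberg–Marquardt least squares started from
$A_0 = \max(y)$ and $K_0$ = the interpolated time to half-maximum, bounded
to $A \in [0, 3\max(y)]$, $K \in [0.01, 100]$ min, with a bounded
quasi-Newton polish as a safety net; a curve with no positive signal
short-circuits to amplitude 0 with a `degenerate` flag rather than an
optimiser failure. Negative NPQ values (flash F~m~′ exceeding dark F~m~)
are retained, not clipped — clipping would bias the slope — and flagged
with a warning at curve computation.

For adjusted curves the dark point shifts the whole curve up by
NPQ~A~(dark), while the fitted hyperbola passes through the origin.
`fit_npq_kinetics(value = "npq_a")` therefore subtracts the per-disc dark
point before fitting (the `offset` argument), so the fit describes the
light-induced rise and its initial slope is comparable across discs with
different sustained quenching. Fitting the raw adjusted curve through the
origin instead overestimates the slope; a test demonstrates this.

Infiltration contrasts (e.g. a reductant versus water) are expressed with
`relative_to_control()` as the percentage of the control rate retained
(`100 × treated/control`), matching how such effects are usually quoted; a
`mode = "change"` flag switches to percent change.

## Reflectance indices

Sub-nanometre spectrometer output is reduced to integer-nanometre bins by
converting each wavelength to an integer and averaging within bins
(`bin_spectrum()`). "Converting to integers" is read as truncation toward
zero; rounding is available via `method = "round"`, and for smooth leaf
spectra the difference is below measurement noise. Three indices are
computed per measurement (not on averaged spectra): PRI
$(R_{531}-R_{570})/(R_{531}+R_{570})$, CRI $1/R_{510} - 1/R_{550}$, and
ARI as printed in the source protocol, $R_{800}/R_{550} - 1/R_{700}$. The
printed ARI mixes a ratio with a reciprocal where the common literature
form is $1/R_{550} - 1/R_{700}$; the printed form is the default — the
intent is not second-guessed — and the canonical form sits behind
`variant = "canonical"`.

## Quantification assays

External-standard calibration (`fit_calibration()`) is an ordinary
least-squares line with a fitted intercept (a forced-zero variant is a
flag). Quantification limits default to the assay's printed values —
21 µg/ml for lutein, antheraxanthin and zeaxanthin, 20 µg/ml for
violaxanthin, 35/25 µg/ml for chlorophyll a/b — and `quantify()` flags
below-LOQ/LOD values while *retaining* them, since downstream group means
are reported on uncensored values; censoring is deliberately out of scope.
Pigments are normalised to total chlorophyll (a + b), and the
xanthophyll-cycle pool V + A + Z is recomputed from the normalised
components, never stored independently. The pigment-per-chlorophyll ratio
is a mass ratio; a molar variant would only rescale by constant molecular
weights. Relative expression uses the ΔΔCt method with the reference taken
as the arithmetic mean of the two reference-gene Cts (Ubiquitin, EF1α) —
which, at amplification efficiency 2, is identical to the geometric mean
of the two reference expression levels — and efficiency is fixed at 2
because no efficiency correction is stated. Metabolite peak areas are
converted through their calibration curve, scaled by the 50-µl final
extract volume, and divided by the sample weight.

## The statistical route

Group comparisons follow an assumption-routed procedure: Shapiro–Wilk on
the residuals of the cell-means model and Brown–Forsythe (median-centred
Levene) across cells. If either fails at α = 0.05 a natural-log transform
is attempted (positive data only; the protocol says "data were
transformed" without naming one, and log is the standard variance
stabiliser for positive assay values); if the checks still fail the data
go down the nonparametric branch. The parametric branch runs a factorial
ANOVA omnibus and Dunnett many-to-one comparisons; the nonparametric
branch runs Kruskal–Wallis with Conover–Iman comparisons corrected by
Benjamini–Hochberg, or the rank-sum test for two-group families ("the
Wilcoxon test" is read as rank-sum for two groups and the Conover–Iman
family for many-to-one, which is what the source figure legends use).

Two comparison families are built and corrected separately, mirroring the
two annotation colours in the source figures: accessions versus the
low-tolerance control within each treatment (inter-accession), and
treatments versus the warm control within each accession
(intra-accession).

Dunnett adjusted p-values integrate the many-to-one multivariate-t
distribution (correlation $\rho_{ij} = \lambda_i\lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i+n_0)}$) by seeded quasi-Monte-Carlo with
absolute tolerance 10⁻⁴, so they are reproducible for a given seed; a
single comparison reduces analytically to the two-sided pooled t-test.
The Conover–Iman statistic is computed from the pooled tie-corrected
ranks with the Kruskal–Wallis correction factor, on $N-k$ degrees of
freedom. The three-way case (an extra factor such as infiltration) enters
the ANOVA with all interactions; whether the original analysis included
interactions is not stated, and including them is the conservative
default.

## What the synthetic generator emulates — and what it does not

Every stage is testable by parameter recovery because the generator
inverts the observation model: a disc carries sustained quenching $q_s$
(observed dark $F_m = F_m^{unq}/(1+q_s)$, F~o~ unquenched by default),
light-phase quenching rises as $q_s + At/(t+K)$, dark-phase flashes decay
toward $q_s$ by a fixed fraction of the remaining light-induced amplitude
per minute, and every reading receives multiplicative log-normal noise
(1% CV by default — fluorescence is positive and detector noise roughly
proportional). Reflectance spectra are a smooth leaf-like baseline with a
Gaussian 531-nm depression proportional to the de-epoxidation level;
assay tables are generated by inverting the ΔΔCt relation and the
calibration lines from designed fold changes and group means.

The default experiment design encodes the effect structure of the study it
emulates, fixed once: all accessions share warm-night kinetics
($A = 2$, $K = 1$ min, $q_s = 0$); after a chilling night the
high-tolerance accession carries $q_s = 0.30$ and a 66% faster
light-induced rise, the moderate accession $q_s = 0.15$, and the
low-tolerance control $q_s = 0.02$ with a slightly slowed rise, so the
adjusted induction rate is 133% higher in the high- than the low-tolerance
accession while the measured-NPQ rates of the high/moderate pair average
~44% above the control. The infiltration design retains 76% / 48% / 23% of
the water-control rate under the reductant for the three accessions.
Default replication is 8 discs per cell, within the published 4–8 range;
assay tables use 8 replicates (published 3–10). Dark-yield defaults
($F_o = 200$, $F_m = 1000$) give a warm F~v~/F~m~ of 0.8, typical of
healthy dark-adapted leaves.

What passing recovery tests do **not** show about real data: the generator
has no per-plate or spatial effects, no drift between flashes, no actinic
heterogeneity across a 96-well plate, no F~o~ quenching under sustained
NPQ (the knob exists but defaults off, and the adjustment is exact only in
that regime), and its relaxation model is a one-parameter geometric decay
rather than the multi-component relaxation of real quenching. Recovery
results certify the correctness of the estimators under the stated
observation model, not robustness to instrument artefacts.

## Problem sizes and degenerate inputs

Simulation-backed checks use sizes chosen to keep the whole suite quick
while leaving comfortable statistical margins: 200 discs for
sustained-quenching recovery (50 per level at 1% noise, bias tolerance
0.02), 100 curves for slope bias (tolerance 2%), 1000 three-group
experiments for the Dunnett family-wise error rate, 50 instances for the
fit-versus-grid-search comparison (200 × 200 grid). Degenerate inputs are
handled explicitly rather than by optimiser failure: all-zero curves
(degenerate flag), constant data (assumption checks return `NA` and route
nonparametric), all-tied ranks (degenerate error), zero chlorophyll or
zero sample weight (normalisation errors), a warm reference of exactly 1
(division-by-zero error naming the reference).

## Known limitations

* The adjusted-NPQ reconstruction is exact only if sustained quenching
  spares F~o~; if F~o~ is partially quenched the dark point is
  underestimated (the generator's `f_o_quench_factor` lets you quantify
  this for your own regime).
* The hyperbolic model has no lag or sigmoidicity; schedules with very few
  early flashes identify $A/K$ better than $A$ and $K$ separately.
* Dark-phase relaxation is stored and plotted but not modelled; no
  relaxation parameter is reported.
* The nonparametric branch tests stochastic dominance, not means; mixing
  its conclusions with parametric effect sizes requires care.
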
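# npqkit

Tidy analysis of chlorophyll-fluorescence quenching assays on leaf discs,
built for chilling-stress phenotyping of C4 grasses (and any other system
where a stress treatment induces quenching that persists through the dark
period).

Chilling slows carbon fixation faster than light capture, so chilled
leaves must dissipate absorbed energy as heat — non-photochemical
quenching (NPQ). Chilling-tolerant accessions can accumulate zeaxanthin
overnight, carrying quenching into the dark-adapted state. That sustained
quenching silently deflates the two standard PAM quantities: the maximum
PSII yield *F*v/*F*m = (*F*m − *F*o)/*F*m drops, and every Stern–Volmer
NPQ value, NPQ(t) = *F*m/*F*m′(t) − 1, is computed against an
already-quenched *F*m. `npqkit` implements the adjusted NPQ (NPQ_A) that
corrects this: warm-treated discs provide the unquenched reference yield
*r*w, the true maximum of a cold disc is reconstructed as
*F*m,true = *F*o,cold / (1 − *r*w), and

* NPQ_A(dark) = *F*m,true/*F*m,cold − 1  (the quenching already present in
  darkness),
* NPQ_A(t) = *F*m,true/*F*m′(t) − 1  (at every flash).

Around this core the package provides the full analysis graph of a
leaf-disc quenching study:

* **Kinetics** — per-disc fits of the induction curve to a rectangular
  hyperbola NPQ(t) = A·t/(t + K); the *NPQ induction rate* is the initial
  slope A/K (min⁻¹); rates relative to an infiltration control.
* **Reflectance** — integer-nm binning of hyperspectral leaf reflectance
  and the PRI, ARI and CRI indices.
* **Quantification** — external-standard calibration with LOQ/LOD
  flagging, chlorophyll and sample-weight normalisation,
  xanthophyll-pool sums, dual-reference ΔΔCt expression.
* **Statistics** — the assumption-routed workflow: Shapiro–Wilk +
  Brown–Forsythe checks, log transform or nonparametric routing, ANOVA
  with Dunnett many-to-one comparisons, Kruskal–Wallis with Conover–Iman +
  Benjamini–Hochberg.
* **Synthetic data** — seeded generators that invert the observation
  model, so every stage is verifiable by parameter recovery.

Everything is data-frame-first: functions take tidy tables, return
tibbles, and chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures.

## Worked example

A disc that came out of a chilling night with sustained quenching
q_s = 0.3 and true induction parameters A = 2, K = 1 (no noise, so the
numbers are exact):

```r
library(npqkit)

tr  <- simulate_trace(sustained_quenching = 0.3, noise_cv = 0, seed = 1)
out <- compute_npq_a(tr, warm_ref = 0.8)   # warm-reference Fv/Fm
unique(out$npq_a_dark)
#> [1] 0.3

fit <- fit_hyperbolic(out, value = "npq_a", offset = unique(out$npq_a_dark))
fit
#> <hyperbolic_fit> npq_a
#>   amplitude 2, half-time 1 min, initial slope 2 min^-1
#>   rss 4.715e-31 on 12 points; converged: TRUE
```

The dark point recovers the injected sustained quenching exactly, and the
fit recovers the designed amplitude and half-time. A full experiment —
three accessions of contrasting chilling tolerance, warm vs chilling
nights, eight discs per cell, 1% measurement noise — through the whole
pipeline:

```r
library(dplyr)
exp <- simulate_plate_experiment(seed = 42, n_reps = 8)
res <- run_npq_pipeline(pipeline_config(seed = 42), traces = exp$traces)

res$fits |>
  filter(curve_type == "npq_a") |>
  group_by(accession, treatment) |>
  summarise(rate = mean(initial_slope), se = sd(initial_slope)/sqrt(n()))
#>   accession treatment rate     se
#> 1     MsaRB  chilling 3.31 0.0211
#> 2     MsaRB      warm 2.02 0.0145
#> 3     MsiCR  chilling 1.49 0.0315
#> 4     MsiCR      warm 1.99 0.0262
#> 5      MxgI  chilling 1.68 0.0309
#> 6      MxgI      warm 1.98 0.0209

tidy(res$stats$npq_a) |>
  filter(family == "inter_accession|chilling") |>
  select(contrast, estimate, adjusted_p, stars)
#>        contrast estimate adjusted_p stars
#> 1 MsaRB - MsiCR    1.821   0.000000   ***
#> 2  MxgI - MsiCR    0.191   0.000192   ***
```

After a chilling night the high-tolerance accession's adjusted induction
rate rises from ~2.0 to ~3.3 min⁻¹ (+66%) while the low-tolerance control
falls slightly; the routed Dunnett comparisons flag both accessions
against the control within the chilling family. `run_demo()` wraps this
end to end and scores recovery against the generator's ground truth;
`run_npq_pipeline()` also accepts long-format CSV exports and a 96-well
plate layout for real instrument data.

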
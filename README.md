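# clsscreen

Analysis toolkit for **chronological lifespan (CLS) screens** in yeast that
score stationary-phase viability by propidium-iodide (PI) flow cytometry.

In such a screen, thousands of deletion strains age in 96-well plates; every
two days a sample of each culture is stained with PI — which only enters
cells with compromised membranes — and ~10,000 events are acquired per well.
`clsscreen` turns the raw per-well event tables into strain-level longevity
calls:

1. **Gating** — an Otsu threshold on pooled log10 PI intensity separates
   live (PI-negative) from dead events; each sample yields a viable
   fraction, with event-count QC.
2. **Survival curves** — viability is normalised to the logarithmic-growth
   sample of the same well, defined as 100% viable:
   *S(t) = 100 · f(t)/f(0)*.
3. **Longevity score** — the area under the survival curve (AUC, %·days),
   by the trapezoidal rule over the observed days.
4. **Classification** — wild-type, short-lived and long-lived control
   strains on every plate define three reference AUC distributions; each
   mutant is assigned the class *c* maximising the posterior

   *P(c | a) ∝ π<sub>c</sub> · t<sub>ν</sub>(a; ā<sub>c</sub>,
   s<sub>c</sub>√(1+1/n<sub>c</sub>))*,

   with equal priors and the Student-t predictive density (ν = n−1) of each
   control class — the t-test's distributional core used generatively.
5. **Enrichment** — one-sided hypergeometric over-representation of hit
   lists against GMT gene-set collections (filters: overlap ≥ 3, p < 0.05,
   enrichment ≥ 1.5; BH q reported).
6. **Redox (OxD)** — degree-of-oxidation trajectories for ratiometric H2O2
   probes from dual-excitation plate-reader series, with background
   subtraction and fully-reduced/fully-oxidised calibration.

Because raw event data for published screens of this kind are not publicly
deposited, the package ships a first-class **synthetic screen generator**
(`simulate_screen()`): Weibull survival decay per longevity archetype,
log-normal plate/replicate effects on the decay time-scale, binomial
live/dead event sampling and log-normal PI intensity mixtures, with full
ground truth for validating the pipeline.

## Worked example

Simulate a small screen (4 plates × 13 wells, controls on every plate, 40
mutants with known classes), then run the full analysis:

```r
library(clsscreen)

design  <- screen_design(plates = 4, wells_per_plate = 13,
                         events_per_sample = 2000, seed = 7)
mutants <- setNames(rep(c("average", "short_lived", "long_lived"),
                        length.out = 40),
                    paste0("mut", sprintf("%02d", 1:40)))
sim    <- simulate_screen(design, mutants)
result <- screen_pipeline(sim$events)
result
#> <cls_screen_result>
#>   gate threshold: 564.7 a.u.
#>   samples gated: 260 (0 strains excluded)
#>   control average      n = 4, area 384.4 +/- 22.3 %*days
#>   control short_lived  n = 4, area 202.6 +/- 10.2 %*days
#>   control long_lived   n = 4, area 590.5 +/- 18.4 %*days
#>   classified mutants: average = 14, short_lived = 13, long_lived = 13
```

The gate landed at 564.7 a.u., between the dim (live) and bright (dead) PI
populations; all 260 samples passed QC. The three control classes are
cleanly separated in AUC (≈ 203, 384 and 590 %·days), and the 40 mutants
were assigned 14/13/13 — exactly the simulated composition. Per-strain
posteriors:

```r
head(result$classification, 3)
#>    strain area_mean   p_average p_short_lived p_long_lived       label
#> 1:  mut01  411.0611 0.996370856  3.285541e-04 3.300590e-03     average
#> 2:  mut02  196.4447 0.001376572  9.985798e-01 4.360173e-05 short_lived
#> 3:  mut03  565.4309 0.005290890  3.493723e-05 9.946742e-01  long_lived

label_recovery(result, sim$truth)$confusion
#>              called
#> truth         average short_lived long_lived
#>   average          14           0          0
#>   short_lived       0          13          0
#>   long_lived       0           0         13
```

Every mutant recovered its true class. `plot_average_curves(result$curves)`
draws the local-regression average survival curves with their 95% bands.

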
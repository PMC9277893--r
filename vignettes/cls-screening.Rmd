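---
title: "Scoring chronological lifespan screens from PI flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chronological lifespan screens from PI flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsscreen)
```

## The measurement and the model

Chronological lifespan (CLS) is the time a non-dividing yeast population
stays alive in stationary phase. In a plate-based CLS screen, each deletion
strain is aged in a well of a 96-well plate; every two days a sample is
stained with propidium iodide (PI) — a membrane-impermeant DNA dye that only
enters cells whose membranes have failed — and run through a flow cytometer.
The PI-negative fraction of events is the viable fraction of the culture.
Because plating efficiency and staining vary, viability is expressed
relative to the logarithmic-growth sample of the same well (day 0), which is
defined to be 100% viable:

$$S(t) = 100 \cdot \frac{f(t)}{f(0)},$$

where $f(t)$ is the gated viable fraction at day $t$. A strain's longevity
is summarised by the area under its survival curve (AUC, in percent-days),
computed by the trapezoidal rule over the observed days. The AUC is a robust
scalar: it does not require choosing a survival threshold, it integrates
early and late death equally, and it is linear in survival.

Every plate carries three reference strains: a wild type (average lifespan),
a short-lived mutant and a long-lived mutant. Their replicate AUCs across
plates define three reference distributions. Each mutant is then assigned to
the class that maximises its posterior probability under equal priors:

$$P(c \mid a) = \frac{\pi_c \, L_c(a)}{\sum_j \pi_j \, L_j(a)},
\qquad \pi_c = 1/3 .$$

### The class likelihood

The class-conditional likelihood $L_c$ is the Bayesian predictive density
for a new observation from a normal population whose mean and variance are
estimated from $n_c$ control replicates: a location-scale Student-t with
$\nu = n_c - 1$ degrees of freedom, location $\bar a_c$ and scale
$s_c\sqrt{1 + 1/n_c}$. This is the distributional core of the two-sample
t-test used generatively: it widens the Gaussian by exactly the amount the
finite control sample leaves uncertain, so a screen with few control
replicates makes appropriately cautious calls. A plain-Gaussian mode
(`form = "normal"`) is kept for sensitivity analysis; with $n > 30$ controls
the two agree closely.

Posterior arithmetic is done in log space with a log-sum-exp
normalisation, so mutants with areas far outside every reference
distribution (where all three densities underflow) still classify stably.
With equal priors, equal sd and equal $n$, the decision boundary between
two adjacent classes is exactly the midpoint of their means — a property
the test suite checks by bisection.

### Ties and edge cases

When the top two posteriors differ by less than `tie_epsilon` (default
1e-6) the call is flagged ambiguous and assigned to `"average"` — the
conservative choice, since it never creates a hit. A prior of zero makes a
class unreachable. Controls with fewer than two replicates, or zero spread,
are a hard error: the reference distribution would be degenerate.

## Gating

The paper-scale screen records ~10,000 events per sample on a PE-A-like
channel. PI-positive and PI-negative events form two log-normal intensity
components, so gating happens on the log10-intensity axis. The default gate
is Otsu's threshold — the split maximising between-class variance of the
pooled log10 histogram (512 bins) — computed **globally** over a plate
batch rather than per sample. A per-sample gate would fail on fully dead or
fully live samples, which have only one population; the global gate keeps
them comparable. A fixed numeric threshold can be supplied instead
(`gate_threshold(..., method = "fixed")`), and the histogram bin count is
exposed. Events with non-positive intensity are rejected at parse time
(outside the log domain).

Samples recording fewer than `min_events` events fail QC (default 1000, a
tenth of the nominal target) and become *missing timepoints*: the survival
curve simply skips them, the trapezoid bridging the gap linearly. No value
is imputed — an imputed zero would masquerade as death. A replicate that
loses its day-0 sample cannot be anchored and is excluded with a logged
reason; a strain with day-0 viability of zero never grew and is excluded
("no growth"), matching the screen's rule of dropping strains without
growth or regrowth.

## Survival curves and averages

Normalised survival above 100% (a noisy timepoint exceeding the log
sample) is retained and flagged, not clamped: clamping would bias areas
downward asymmetrically. Areas integrate only the observed span; when
replicates end on different days a warning points to
`normalize_span = TRUE`, which reports per-day mean survival instead.

Average curves for presentation are locally weighted regressions (tricube
weights) over the pooled replicate points, defaulting to degree 2 and span
0.75; both are exposed because "local regression" admits many flavours.
The 95% band is $\hat y \pm 1.96\,\mathrm{SE}(\hat y)$ pointwise; identical
replicates give a zero-width band. Because screens sample few distinct
days with many tied replicates, the local quadratic design is singular
between grid vertices; the fit uses loess's vertex-interpolation surface
and silences only its numeric-degeneracy warnings, which are expected in
this tied design. Coverage of a known trajectory at the observed days is
verified by simulation (30 replicates, noise sd 5%, 20 seeds, ≥ 90% of
grid points inside the band).

## The synthetic screen generator

No raw per-well event data are publicly deposited for screens of this
kind, so validation runs on synthetic screens with known ground truth. The
generator emulates, in order:

1. **Survival decay.** Each archetype (average / short-lived / long-lived)
   decays as a Weibull, $v(t) = \exp(-(t/\tau_r)^k)$ — two parameters are
   enough to mimic both concave and convex control curves. Defaults:
   $\tau$ = 4.5, 2.2 and 8.5 days with shared shape $k = 1.6$, chosen so
   the three classes are clearly separated on the day {0, 2, 4, 6, 8}
   grid (about 13 pooled SDs between adjacent class AUC means under the
   default noise) — the regime the real controls were chosen to occupy,
   where the classes are distinguishable by eye.
2. **Plate and replicate effects.** Noise acts multiplicatively on the
   time-scale, $\tau_r = \tau\,e^{\varepsilon_{plate} + \varepsilon_{rep}}$
   with $\varepsilon \sim N(0, 0.02^2)$ and $N(0, 0.05^2)$ respectively —
   keeping $v \in [0,1]$ by construction. The plate-level standard-normal
   draw is shared by all wells of a plate, so co-housed strains shift
   together.
3. **Events.** Dead counts are binomial in $1 - v$; intensities come from
   the two log-normal components (log10 locations 2.0 and 3.5, sds 0.25
   and 0.3) — a dim live peak and a bright dead peak separated by 1.5
   decades, as a well-stained PI sample looks on a 4-decade channel.
4. **Layout.** Controls occupy the first three wells of every plate (one
   replicate per plate, as on the real plates); mutants fill the remaining
   wells one replicate each.

Randomness derives from per-(plate, well, timepoint) sub-streams of one
master seed via 32-bit avalanche hashing (`substream_seed()`), so a design
can grow — more plates, more wells — without perturbing wells already
simulated. The hash's avalanche property matters: structured (affinely
related) seeds give correlated Mersenne-Twister start-up draws, which
would artificially couple the replicate effects of fixed well positions.

**What the generator does not emulate:** staining or acquisition drift
within a plate, spectral spillover, doublets and debris, regrowth in
stationary phase, day-to-day batch effects beyond a scalar plate shift,
and death kinetics outside the Weibull family. Passing recovery tests on
this generator therefore demonstrates that the analysis machinery is
correct and well calibrated under its stated noise model — not that real
screens meet that model.

## Enrichment

Hit lists are tested for gene-set over-representation with a one-sided
upper-tail hypergeometric test per term, after intersecting every term
with the background. The natural background of a deletion-collection
screen is the set of strains actually analysed, not the whole genome;
it is a required argument. Rows are filtered by the screen's criteria —
minimum overlap 3, p < 0.05, minimum enrichment factor 1.5 — and
Benjamini–Hochberg q-values are reported across all tested terms but not
filtered on, matching a p-based cutoff. The p-value is enumeration-exact
(verified against all hit-draw configurations on universes up to 12
genes). No GO-graph propagation or term-redundancy collapsing is done.

## Degree of oxidation (redox module)

For a ratiometric H2O2 probe read at two excitations (400 and 485 nm), the
degree of oxidation of the probe pool is computed from the excitation
ratio $R = F_{485}/F_{400}$ after per-cycle background subtraction of a
reporter-free strain:

$$\mathrm{OxD} = \frac{R - R_{red}}
{F\,(R_{ox} - R) + (R - R_{red})},$$

with $R_{red}$ and $R_{ox}$ the ratios of fully reduced (DTT) and fully
oxidised (H2O2) control wells and $F$ an instrument correction factor
(default 1, reducing the formula to linear interpolation between the
calibration ratios — the endpoints 0 and 1 and monotonicity in $R$ hold
for any $F > 0$). Calibration ratios are medians over post-treatment
cycles, robust to the injection transient. OxD outside [0, 1] (ratios
beyond calibration) is clamped and flagged. The baseline OxD0 is the mean
OxD of the pre-treatment cycles (default 4, ~2 min each). Scale
invariance — multiplying both channels by any constant — leaves $R$ and
hence OxD unchanged.

## Numerical and validation choices

* Otsu scan: 512 bins over the observed log10 range; threshold placed on
  the bin edge after the argmax split, hence strictly inside the data
  range.
* AUC: plain trapezoid; verified against dense (10^4-point) integration of
  the piecewise-linear interpolant to 1e-9 on 1000 random curves, and
  exactly 800 / 100 on the constant and step curves.
* Posterior normalisation: max deviation from 1 is ~2e-16 over 10^5
  random areas.
* Validation problem sizes (the package's own choices): the full-scale
  demonstration uses 4 plates x 96 wells x 5 timepoints x 10,000 events
  (~1.9e7 events, about half a minute); recovery studies use 31 plates of
  13 wells at 2,000 events per sample — event count only affects binomial
  gating noise (sd ~0.005 at n = 10,000), negligible next to replicate
  noise, so smaller event counts probe the same statistics faster.
* OxD0 recovery is asserted as mean absolute error ≤ 0.01 over 100 seeds:
  with noise sd 0.01 per cycle and a 4-cycle baseline, the estimator's own
  standard error is 0.005, so individual seeds occasionally exceed 0.01 by
  construction; the mean criterion tests calibration without asserting an
  impossible per-seed bound.

## Known limitations

* Gating is single-channel with a single global threshold; no
  compensation, doublet discrimination, or per-sample mixture modelling.
* Binary FCS files are not read; events enter as long-format TSV. (An FCS
  ingestion hook was considered and left out: no FCS parser is available
  in the package's dependency footprint, and the TSV dialect is
  lossless for this analysis.)
* The classifier assigns hard labels against three parametric reference
  distributions; it does not model replicate-level variance of mutants
  (one replicate per mutant in the screen layout) and reports no FDR over
  strains.
* Enrichment matches the screen's filter semantics, not any specific web
  tool's internal background or redundancy collapsing; exact term lists
  from such tools are not reproducible here.
* The OxD formula's correction factor defaults to 1; endpoint behaviour is
  formula-independent, but published OxD values obtained with a different
  calibration convention may differ away from the endpoints.

## A minimal session

```{r example, eval = FALSE}
design <- screen_design(plates = 4, wells_per_plate = 13,
                        events_per_sample = 2000, seed = 7)
mutants <- setNames(rep(c("average", "short_lived", "long_lived"),
                        length.out = 40),
                    paste0("mut", sprintf("%02d", 1:40)))
sim <- simulate_screen(design, mutants)
result <- screen_pipeline(sim$events)
result
label_recovery(result, sim$truth)$confusion
```
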
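---
title: "Dropout-community analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout-community analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommdropout)
```

## The experimental design this package analyzes

Defined (synthetic) gut bacterial communities such as the twelve-member
Oligo-Mouse-Microbiota allow systematic presence–absence experiments: the
full consortium and twelve dropout communities, each lacking one strain, are
grown side by side and the absolute abundance of every member is measured by
strain-specific qPCR. Comparing each dropout community against the full
consortium in the same environment reveals the removed strain's ecological
role; repeating the design across culture media (or gut regions) shows
whether that role is context-dependent. `ommdropout` implements the complete
downstream analysis of such experiments, together with a ground-truth
simulator used to validate every stage.

## From raw qPCR readouts to censored absolute abundances

A qPCR readout is reported as 16S rRNA gene copies per template mass
(5 ng gDNA by default). The normalization chain multiplies by the total
extracted gDNA over the template mass (`gdna_conc * elution_volume /
template_mass`), divides by the strain's 16S copies per genome, and divides
by the sample volume or mass:

$$\mathrm{abundance} = \frac{\mathrm{copies} \cdot
  (c_\mathrm{gDNA} V_\mathrm{elution} / m_\mathrm{template})}
  {n_\mathrm{16S} \cdot \mathrm{amount}}$$

This is the only dimensionally consistent composition of the four factors
that yields copies per ml (or per g). Dividing by $n_\mathrm{16S}$ reports
genome equivalents; a flag switches to plain normalized 16S copies, since
conventions differ between laboratories.

Detection limits (DTL) are strain-specific and act on the *raw* copies
scale, before normalization. Two conventions are fixed here:

* the DTL is inclusive-detectable — a readout exactly at the limit counts
  as detected;
* censored entries are stored as value 0 with a logical flag, rather than
  `NA`. Dissimilarity analysis and medians need numeric entries, and 0 is
  the natural contribution of an undetected strain; the flag, not the
  value, drives all detection logic.

Per-strain 16S copy numbers and DTLs are assay calibrations that each
laboratory must supply (`read_roster_config()`); the values shipped with
`omm12_roster()` are documented placeholders in a realistic range.

## The r_abs statistic and relationship categories

For a removed strain $x$ and an affected strain $y$ in one environment,

$$r_\mathrm{abs} = \frac{\tilde a_y^{\,\mathrm{dropout}\,x}}
                        {\tilde a_y^{\,\mathrm{full}}}$$

where $\tilde a$ is the median over replicate wells (a mean-based variant
sits behind `use_mean`; medians are the default because they are robust to
single-well dropouts and match how such data are usually plotted).
$r_\mathrm{abs} > 1$ means $y$ rises when $x$ is removed — a negative
relationship of $x$ toward $y$; $r_\mathrm{abs} < 1$ a positive one.

Detection-limit logic overrides the ratio. The replicate-level rule is a
design choice the underlying field convention leaves open: a group counts
as **detected** when strictly more than 50% of its wells are above the DTL
and **never detected** when no well is. The rules apply in order:

1. never detected in either group → `below_DTL`;
2. never in the full consortium, detected in the dropout → `exclusion`
   ($y$ can only establish itself when $x$ is absent);
3. never in the dropout, detected in the full consortium →
   `positive_dependency` ($y$ requires $x$);
4. otherwise the sign of $r_\mathrm{abs}$ decides, with exactly 1 broken
   toward the weaker claim (`positive`) and annotated as neutral.

Sporadic detection (some wells above DTL in neither a "detected" nor a
"never" pattern) can leave the full-consortium median at 0; the ratio is
then undefined and the classification falls back to the dropout median
(positive dropout median → `negative`, both medians 0 → `below_DTL`, each
annotated). Every (x, y, environment) triple with data therefore receives
exactly one category, and all categories, p-values and ratios are invariant
to a common rescaling of abundances and DTLs.

## Significance testing and keystone impact

Replicate wells are compared with a two-sided Wilcoxon rank-sum test: exact
enumeration whenever both groups have ≤ 12 tie-free replicates, otherwise
the normal approximation with continuity correction. Identical constant
groups return p = 1. The default replicate unit is the well (N = 9: three
biological × three technical replicates); averaging technical replicates
first (`aggregate = "bio"`) is supported but leaves the exact test with
N = 3, whose smallest attainable two-sided p is 0.1 — well-level testing is
the default for exactly this reason.

`keystone_impact()` counts, per (removed strain, environment), the members
that were significantly affected. The headline count combines raw-p
Wilcoxon hits with the detection categories (exclusion, positive
dependency), because a strain pushed below the detection limit is an effect
regardless of the rank test. Both multiple-testing conventions coexist in
this literature — per-strain raw p for dropout panels, BH-adjusted p for
family-level claims — so the Wilcoxon-only and BH-adjusted counts are
always reported alongside, with BH applied within each (removed strain,
environment) family of 11 tests.

### Discreteness of the exact test, calibration, and recovery

At N = 9 wells per group the exact Wilcoxon null is discrete: the largest
attainable two-sided p below 0.05 is $2 \cdot P(W \le 17) = 0.0400$. Two
consequences are worth stating because the test suite checks them:

* **Calibration.** Under a null generator (dropout and full drawn from the
  same observation distribution) the per-strain false-positive rate
  concentrates at the exact size 0.040, not at the nominal 0.05. The
  calibration test therefore uses binomial bounds around the exact size and
  additionally checks the rate never exceeds the nominal level.
* **Exact-count recovery.** With 3 planted ≥ 4-fold effects among 11
  strains, individual detection power is ~1, but the probability that none
  of the 8 unaffected strains produces a false positive is
  $(1 - 0.04)^8 \approx 0.72$ (≈ 0.89 with BH inside the family). The
  probability of recovering the planted count *exactly* in ≥ 95% of runs is
  therefore out of reach for any method that tests at α = 0.05 with nine
  wells; `keystone_recovery_rates()` reports the exact-match rates under
  both conventions together with the planted-detection power, and the test
  suite documents the resulting behavior rather than hiding it.

## Community structure

Bray–Curtis dissimilarities are computed on absolute abundances (not
relative!) via `vegan::vegdist`, by default without transformation —
matching the convention of working directly on absolute profiles — with a
`log10(x + DTL)` variant behind a flag. Two aggregation levels are
supported: per-well points, and the median profile per community ×
environment that dropout-panel ordinations typically display.

PCoA is classical metric scaling (double centering + eigendecomposition).
Negative eigenvalues are retained in the report but excluded from
coordinates and explained-variance fractions; each axis's sign is fixed by
making its largest-magnitude coordinate positive, so results are
reproducible across platforms.

Confidence ellipses are bivariate-normal, from each group's sample mean and
covariance on the first two axes at the $\chi^2_2$ 0.95 quantile (5.991).
The t-based alternative (which widens small-group ellipses) is a defensible
variant; the normal/χ² form was chosen and is stated here because the
convention is rarely reported. A sample is an outlier when its squared
Mahalanobis distance to its own group exceeds the quantile; singular group
covariances are ridge-regularized (`1e-9 · trace`) with a warning. On
Gaussian groups the flag rate converges to 1 − level.

PERMANOVA uses the one-way pseudo-F from within/between sums of squared
dissimilarities, `p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` with 9999
permutations by default and exhaustive enumeration on small instances
(`exhaustive = TRUE`). Samples are put in canonical order before permuting
and every pairwise comparison draws from a substream derived from the pair's
label, so p-values are invariant to input order and to which comparisons are
run. Pairwise p-values are BH-adjusted. The implementation is cross-checked
against `vegan::adonis2` in the test suite.

## Metabolite profiles and host readouts

Feature tables (samples × features, NA = not detected) are filtered by
missingness: features with strictly more than 80% NA are dropped.
Consumption/production calls compare spent community supernatants with
fresh-medium references by two-sided Welch t-test — Welch because spent and
fresh intensities rarely share a variance; the choice of raw-intensity
testing is the default, with a log-mode flag that makes calls invariant to
global rescaling. Missing values are imputed as 0 only for dissimilarity
analysis, never for the t-tests. No multiple-testing correction is applied
to the calls by default (per-metabolite annotations are conventionally
raw-p); the BH column is emitted alongside.

Host readouts are small and fully specified: the composite cecal
histopathology score sums submucosal edema (0–3), PMN infiltration (0–4),
goblet-cell loss (0–3) and epithelial damage (0–3) into 0–13, banded 0–3 /
4–8 / 9–13 (no / mild / profound inflammation), and the cecal-to-body-weight
ratio is a plain quotient. Group comparisons reuse the shared Welch t-test.

## The ground-truth simulator

The generator is a generalized Lotka–Volterra serial-dilution batch model.
It is test scaffolding with known ground truth — the analysis makes no
dynamical inference claim. Within one 24 h passage:

$$\frac{dx_i}{dt} = x_i\big(\mu_i\,g_i(\mathrm{pH}) + \textstyle\sum_j a_{ij}x_j
  + y_i R\big) - \sum_p k_{pi}\,x_p\,x_i, \qquad
  \frac{dR}{dt} = -c\,x_\mathrm{deg}R$$

with pH an algebraic function of state:
$\mathrm{pH} = \mathrm{pH}_0 - \gamma(R_0 - R) - \sum_i w_i\,x_i/(x_i+h)$.
Every 24 h the culture is diluted 1:100 into fresh medium (resource reset),
for 4 passages (96 h); populations below the extinction floor (0.01
copies/ml) are set to exact 0 at passage boundaries. $g_i$ is a logistic
switch at strain $i$'s pH threshold with steepness 8 — smooth rather than a
hard cutoff, so the stiff-safe adaptive integrator (`deSolve::ode`, lsoda,
rtol 1e-8) never crosses a discontinuity; tightening rtol to 1e-11 moves
endpoints by < 1e-6 relative.

Two mechanism plugins mirror the known environment-dependent keystone
mechanisms:

* **bacteriocin** — a producer strain kills sensitive strains by mass
  action ($k\,x_p\,x_t$), an enterocin-like interference interaction;
* **exclusive-resource acidification** — one strain exclusively degrades a
  polysaccharide pool (inulin-like, 2 g/L fresh), gains extra growth, and
  the fermentation acids lower the pH by γ per g/L consumed, excluding
  pH-sensitive strains.

The observation model applies the qPCR chain in reverse: true abundances →
copies per template (quantized to 6 significant digits, the instrument's
reporting precision) → multiplicative lognormal noise (sdlog 0.2) →
DTL censoring → normalization. Biological replicates get independently
jittered inocula (lognormal sdlog 0.1); technical replicates share the
trajectory and differ only in observation noise, an idealization of wells
seeded from the same inoculum stock. pH measurements carry Gaussian noise
(sd 0.05). All randomness flows through named substreams of one master
seed (`derive_seed()`), so any single source can be frozen and results do
not depend on evaluation order.

### Preset scenarios and their calibration

The presets encode the study conditions: 12 strains, ≥ 2 media with
distinct interaction sets, 3 × 3 replicates, 96 h/1:100 passaging,
strain-specific DTLs, lognormal noise. Growth rates (0.25–0.6 h⁻¹) and
carrying capacities (2×10⁸–2×10⁹ copies/ml) are realistic for dense
anaerobic batch culture. Interaction strengths and acid weights were set
once so that the combined two-media scenario reproduces the magnitudes
reported for this design — median ΔpH ≈ −0.95 (full consortium, glucose
medium), ≈ −1.2 (producer dropout), ≈ −1.35 (full, polysaccharide medium),
≈ −0.46 (degrader dropout), and affected-species counts 5/5 (producer),
1/4 (degrader), 2/1 (acetogen) across the two media — and were not revisited
afterwards. `combined_two_media` carries both mechanisms; the single-mechanism
presets (`AF_like_bacteriocin`, `APF_like_acidification`) deliberately carry
only their own mechanism so that ablation and context-dependence checks
isolate one cause at a time. `neutral` has no interactions at all: every
r_abs is exactly 1 under a noise-free observation model.

What the generator deliberately does not emulate: host-derived factors
(antimicrobial peptides, immune feedback), oxygen and pH regulation
dynamics, spatial structure, higher-order (non-pairwise) interactions
beyond the two mechanism plugins, and compositional sequencing artifacts.
Passing tests on this generator therefore demonstrate that the pipeline
recovers planted effects under the study's noise and censoring model — not
that real communities satisfy gLV dynamics.

## Problem sizes and determinism

The shipped analyses use the sizes of the underlying design: 13 communities
× 9 wells × 2 media (234 samples) for the main experiment; 1000
simulated null datasets for calibration; 200 planted-effect datasets for
recovery; 100 seeded replicates for the bacteriocin ablation; 9999
permutations for the headline PERMANOVA. Re-running any script with the
same seed reproduces every number; `run_full_analysis()` records the seed,
parameter digest and audit counts (censored entries, dropped features,
flagged outliers) in its manifest.

## Known limitations

* The detection rule (">50% of wells") is one of several defensible
  operationalizations of "not detectable"; with 9 wells the distinction
  between 4/9 and 5/9 detected is noise-sensitive near the DTL.
* Exact-count keystone recovery is bounded by the family-wise
  false-positive rate, as derived above; claims about the *number* of
  affected species at N = 9 carry an irreducible ±1 uncertainty.
* The observation model treats technical replicates as exchangeable with
  biological ones in the N = 9 well-level convention, as the underlying
  design does; a nested random-effects treatment is out of scope.
* PERMANOVA assumes exchangeability of samples under the null; with
  strongly unbalanced dispersion between media the pseudo-F conflates
  location and dispersion effects, as it does in every implementation.
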
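# ommdropout

Analysis of single-species **dropout experiments** in defined (synthetic)
gut bacterial communities — the design in which the full consortium (e.g.
the twelve-member Oligo-Mouse-Microbiota, OMM12) and a series of communities
each lacking one member are grown side by side, and every strain's absolute
abundance is measured by strain-specific qPCR. The package is written for
microbial ecologists who run such experiments across culture media or gut
regions and want to quantify strain relationships, identify keystone
species, and test how both depend on the environment.

## What it computes

**Absolute abundances.** Raw qPCR readouts (16S copies per 5 ng gDNA) are
normalized by extract concentration, elution volume, template mass, the
strain's 16S copies per genome and the sample amount, with strain-specific
detection limits (DTL) applied on the raw copies scale. Censored values are
carried as 0 plus a flag.

**Strain relationships.** For a removed strain *x* and an affected strain
*y* in one environment,

    r_abs = median(abundance of y in the dropout lacking x)
            / median(abundance of y in the full consortium)

r_abs > 1 is a *negative* relationship of *x* toward *y* (y rises when x is
removed), r_abs < 1 a *positive* one. Detection-limit logic overrides the
ratio: *exclusion* (y detected only when x is absent), *positive dependency*
(y detectable only when x is present), *below_DTL* (never seen). Shifts are
tested with a two-sided Wilcoxon rank-sum test (exact for ≤ 12 tie-free
replicates per group), BH-adjusted within each (x, environment) family.

**Keystone impact.** Per (removed strain, environment): the number and
identity of species significantly affected (raw-p Wilcoxon hits plus
detection-category calls; Wilcoxon-only and BH-adjusted counts reported
alongside).

**Community structure.** Bray–Curtis dissimilarity on absolute abundances,
PCoA, 95% confidence ellipses per group with Mahalanobis outlier flagging,
and one-way PERMANOVA (pseudo-F, 9999 permutations, pairwise mode with BH;
exhaustive enumeration on small instances).

**Environmental modification.** ΔpH = pH(spent supernatant) − pH(fresh
medium), and metabolite consumption/production calls from feature tables
(>80%-NA filter, Welch t-test of spent vs. fresh).

**Host readouts.** Composite cecal histopathology score (four sub-scores,
0–13, banded no/mild/profound inflammation) and cecal-to-body-weight ratio.

**Ground-truth simulator.** A generalized Lotka–Volterra serial-dilution
batch model (96 h, 1:100 every 24 h) with two mechanism plugins —
bacteriocin interference and exclusive polysaccharide degradation →
acidification → pH exclusion — plus the full qPCR observation model. It
generates complete synthetic experiments with known interaction signs, used
to validate every pipeline stage.

## Worked example

Simulate a bacteriocin-producer experiment (full consortium + all twelve
dropouts, 9 wells each) and analyze it:

```r
library(ommdropout)
scenario   <- preset_scenario("AF_like_bacteriocin")
experiment <- run_experiment(scenario, seed = 1)
experiment$abundance
#> abundance table: 1296 entries, 117 samples, 12 strains, 108 censored (8.3%)

rel <- relationship_matrix(experiment$abundance, alpha = 0.05)
subset(rel, focal_x == "E.fa" & affected_y %in% c("B.an", "L.re", "T.mu"))
#>    focal_x affected_y environment    r_abs  category        p_raw   p_adjusted significant
#> 80    E.fa       L.re          AF 4.631468  negative 4.113534e-05 0.0001131222        TRUE
#> 81    E.fa       B.an          AF       NA exclusion 1.610013e-04 0.0003542029        TRUE
#> 86    E.fa       T.mu          AF 1.063501  negative 6.048128e-01 0.7392156863       FALSE
```

Reading the output: removing E.fa lets L.re rise 4.6-fold (a negative
relationship of E.fa toward L.re, exact Wilcoxon p = 4.1e-05); B.an is
*excluded* by E.fa — detected in no full-consortium well but in every
dropout well (the bacteriocin mechanism); T.mu is unaffected (r_abs ≈ 1,
p = 0.60). Keystone impact and environmental modification:

```r
keystone_impact(rel)[1:3, 1:5]
#>   focal_x environment n_affected n_affected_wilcoxon n_affected_wilcoxon_bh
#> 8    E.fa          AF          6                   6                      6
#> 5    B.co          AF          2                   2                      2
#> 2   A.mur          AF          1                   1                      0

summarize_delta_ph(experiment$ph)[c(8, 5), ]
#>   community environment median_delta_ph n
#> 8 drop_E.fa          AF      -1.1964328 9
#> 5 drop_B.co          AF      -0.6992765 9
```

The producer tops the ranking (five mechanistically planted effects plus,
at this seed, one borderline noise hit — at nine wells per group the exact
test's false-positive rate is 4% per strain, an uncertainty the package
reports rather than hides), and communities lacking the producer acidify
the medium more strongly (ΔpH −1.20 vs. −0.94 for the full consortium).

## The analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's own study on simulated data; each writes its tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | two-media dropout experiment (234 samples) + fixture bundle |
| `02_relationships.R` | r_abs table, keystone ranking, media-conserved pairs |
| `03_ordination.R` | Bray–Curtis/PCoA, 95% ellipses, outliers, PERMANOVA |
| `04_environment.R` | ΔpH summaries and metabolite consumption/production calls |
| `05_report.R` | orchestrated end-to-end run with audit manifest + host readouts |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

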
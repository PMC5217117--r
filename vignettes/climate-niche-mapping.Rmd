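---
title: "Climate-niche association mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-niche association mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemap)
```

## The problem

Wild isolates of selfing nematodes such as *Caenorhabditis elegans* are
collected around the world, each with a recorded location and (often
imprecise) date of isolation. If alleles influence which climatic niche a
strain can colonize, then the climate at the isolation site is itself a
heritable quantitative trait: strains carrying a niche-adapting allele
should be found, on average, at warmer (or drier, or higher) sites.
`nichemap` implements the full chain needed to test this idea:

1. turn raw weather-station observations into per-strain climate
   phenotypes over windows centered on the isolation date;
2. map those phenotypes against genome-wide marker genotypes with a
   kinship-corrected mixed model;
3. fine-map significant intervals by rank correlation with
   functional-impact variants; and
4. estimate temperature-dependent relative fitness from two-strain
   competition assays read out by droplet digital PCR.

Because real station archives and strain panels are large external
resources, the package also ships a first-class synthetic-world generator
with planted ground truth, so every stage is testable end to end.

## Climate phenotypes

**Isolation dates.** Strains carry a date at day, month, or year
precision. Month-precision dates anchor on the first of the month;
year-precision dates anchor on January 1. Analysis windows are 91 days
("3-month"), 365 days ("one-year"), and 1095 days ("three-year"), centered
on the anchor (half the duration before it); fixed day counts avoid
calendar-month arithmetic and keep runs deterministic. Eligibility grows
with window length: the 3-month window requires the exact day of
isolation, the one-year window day or month, the three-year window accepts
year-only records. Strains without a location are always excluded.

**Station assignment.** Each strain is assigned the nearest weather
station by haversine distance on a sphere of radius 6371.0088 km, among
stations that pass quality control *for that strain's window*: every
calendar month overlapping the window must have at least 10 recordings of
any type at the station. Assignment is repeated independently per window,
so a close station with only a few months of data can serve the 3-month
window while a farther station serves the one-year window. There is no
maximum assignment distance; equidistant stations are broken by
lexicographic station id for determinism. `station_agreement()` provides
the rank-correlation sanity check between neighboring stations that
justifies using a possibly distant station.

**Aggregation is two-stage.** Recordings are first collapsed to daily
mean, minimum, maximum, and variance per parameter; the phenotype is then
the unweighted mean of in-window daily values. This matters: stations
report at different cadences, and pooling recordings directly would weight
dense days more heavily. The suite asserts on an unbalanced fixture that
the two-stage and pooled answers differ and that the two-stage one is
produced. "Variance" is read as the within-day variance of recordings,
averaged over days — parallel to how daily minima and maxima are treated;
the across-day variance of daily means is a defensible alternative reading
and both are computable from the daily table.

**Units.** Precipitation arrives as a depth over a variable accumulation
period and is converted to a per-hour rate before averaging; temperatures
in Fahrenheit or tenths of a degree are converted to Celsius. Qualitative
parameters are dropped. Missing values are explicit `NA`, never 0 — zero
is a valid temperature. Wind direction is averaged arithmetically on
degrees, reproducing the naive treatment typical of these pipelines; a
circular mean would be statistically cleaner but would change the trait
definition.

**Coverage filter.** A trait column is kept only if strictly more than
90% of strains have a value — a trait present in 134 of 149 strains
(89.9%) is dropped. Geographic traits (latitude, longitude, their absolute
values, provider-estimated elevation) join the table for every located
strain. Elevation lookup is a pluggable provider: the synthetic world's
exact field, or inverse-distance-weighted interpolation of station catalog
elevations (power 2, 6 neighbors), which admits a DEM in real use and
returns `NA` — not zero — outside coverage.

## The mixed model

For a trait vector $y$ over $n$ strains, the null model is

$$y = X\beta + u + e,\qquad u \sim N(0, \sigma_g^2 K),\quad
  e \sim N(0, \sigma_e^2 I),$$

with $K$ the realized-relationship (VanRaden) matrix computed from a dense
marker set: haploid 0/1 genotypes are recoded to $-1/1$, centered by
$2p-1$, and cross-multiplied with normalizer $2\sum_k p_k(1-p_k)$. Missing
genotypes are mean-imputed per marker and monomorphic markers skipped.
Because the strains are selfed isotypes there are no heterozygotes, and
duplicate strains attain the diagonal value exactly.

Variance components are estimated by REML in the EMMA fashion: the
restricted likelihood is profiled over $\delta = \sigma_e^2/\sigma_g^2$ on
the spectrum of $SKS$ (with $S$ the projection orthogonal to $X$), using a
100-point grid over $\log_{10}\delta \in [-5, 5]$ followed by
derivative-based root refinement in every bracketing interval. When $K
\propto I$ the two components are unidentifiable and the profile is flat;
among near-optimal grid points the largest $\delta$ is returned, i.e. the
no-genetic-variance reading, which is the conservative interpretation.

Single-marker tests use the P3D approximation by default: variance
components from the null fit are held fixed, data are rotated by the
eigenvectors of $K$ and weighted by $(\sigma_g^2 d_i +
\sigma_e^2)^{-1/2}$, and the marker coefficient receives an ordinary
$t$-test with $n-2$ degrees of freedom. With $K = I$ and $\sigma_g^2 = 0$
this collapses exactly (to $10^{-10}$) onto the OLS $t$-test, which the
suite asserts. An exact per-marker REML refit is available behind
`exact = TRUE`; at $n \approx 150$ the difference is negligible and the
P3D scan is vectorised over all markers. Markers need a minor allele
frequency of at least 5% (computed over non-missing strains) to be tested;
trait values are used untransformed and outliers are deliberately kept —
outlier-driven peaks are a finding to inspect, not to erase. Strains
missing the trait are dropped listwise per trait.

Significance uses the Bonferroni threshold $-\log_{10}(\alpha/m)$ over the
$m$ tested markers. Significant markers on a chromosome whose
within-chromosome index gap is at most a merge radius (default 50 markers)
form one QTL; the peak is the largest $-\log_{10}p$ (leftmost on ties) and
the interval spans the outermost significant markers padded by the radius.
This interval rule is a declared package convention — confidence-interval
algorithms for such scans are tool-specific — and both radius and
$\alpha$ are exposed in the configuration. Peak-genotype splits (REF vs
ALT group sizes, means, medians, quartiles) and LD $r^2$ between peaks
(squared Pearson correlation of 0/1 genotype vectors, equal to
$D^2/(pq(1-p)(1-q))$ for haploid coding) accompany each QTL.

## Fine mapping

Within a QTL interval (1-based, inclusive on both ends, matching the
conventional printed form of genomic intervals), variants annotated with
moderate or severe functional impact are rank-correlated with the trait;
genes are ranked by their best $|\rho|$. Note that for a binary genotype
the definitional Spearman correlation is capped below 1 by ties (about
0.866 for a balanced split of a monotone trait), so rankings — not
absolute magnitudes — are the meaningful output. The candidate shortlist
takes the top 5% of interval genes by default; an absolute-$\rho$ cutoff
is available, since any such threshold is a study-specific choice.

## Competition fitness

Two strains seeded in equal numbers compete over serial culture
transfers; allele counts $(\text{count}_A, \text{count}_B)$ are read by
ddPCR after transfers 2, 4, and 6. Under a constant per-transfer relative
fitness $w$ of strain B, the A-allele frequency decays logistically:

$$\operatorname{logit}(p_t) = \operatorname{logit}(p_0) - t\,\log w.$$

Each replicate is fit by weighted least squares on the logit scale with
the intercept fixed at $\operatorname{logit}(0.5)$ — the seeding ratio is
part of the design, and using it reduces variance; a free-intercept option
exists. Weights are the delta-method information $n_t p_t(1-p_t)$ when
counts are available. Boundary frequencies (0 or 1) receive the Haldane
continuity correction (+0.5 per allele count). Replicates are pooled by
the mean of per-replicate $\log w$ with its standard error. The estimator
is exactly label-symmetric ($\hat w \mapsto 1/\hat w$ under allele swap)
and consistent as droplet counts grow; a noiseless decay from 0.5 to 0.01
over six transfers gives the closed form $\hat w = (0.99/0.01)^{1/6}
\approx 2.151$. Fitness is reported per culture transfer with 1 =
neutrality; a per-generation rescaling would require assuming generations
per transfer and is left to the user.

## The synthetic world

`generate_world()` emulates the essential statistical features of the
real setting at desk scale:

- **Genotypes.** Balding–Nichols structure: ancestral frequencies
  Uniform(0.05, 0.95), subpopulation frequencies
  Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, haploid 0/1 strains on six chromosomes
  with uniformly spaced markers, each marker assigned a synthetic gene and
  impact class. A planted causal marker gets an intermediate ancestral
  frequency (Uniform(0.3, 0.7)) so its contrast is observable in a
  150-strain panel.
- **Climate field.** Long-run site temperature falls linearly with
  absolute latitude (0.45 °C/degree from 26 °C at a sea-level equator) and
  elevation (6.5 °C/km over a smooth 0–500 m field); a hemisphere-phased
  seasonal sinusoid (amplitude 6 °C) and AR(1) daily noise (sd 2 °C,
  autocorrelation 0.7 — weather persists, which is what makes 3-month and
  3-year windows genuinely different) sit on top. Relative humidity
  declines linearly with temperature (−1.3 %/°C from 95%), so the
  abs-latitude–temperature and temperature–humidity correlations are
  negative by construction, as in real climate data.
- **Habitat choice.** The planted association biases *where strains are
  found*, not the weather: a strain's preferred temperature is Normal
  (world mean, 3 °C) shifted by the causal effect per alternative allele,
  and the strain settles near the best-matching station. The 3 °C
  preference spread is a design choice: it represents a temperate species
  with a defined niche and gives the 150-strain, 2000-marker default world
  about 90% power to detect a 5 °C planted effect at the Bonferroni
  threshold, so the pipeline's recovery properties are testable with
  modest replicate counts.
- **Imperfections.** A configurable fraction of station-months is thinned
  below 10 recordings to exercise quality control, and isolation-date
  precision is sampled day/month/year in configurable proportions
  (defaults mirror a typical curated panel, roughly 122:16:7).

What the generator does *not* emulate: coastlines and land masks, real
coalescent linkage disequilibrium (markers are exchangeable given the
subpopulation, so interval fine mapping faces no correlated-neighbor
decoys), instrument biases, and spatially correlated station outages.
Passing tests therefore demonstrate the correctness and calibration of
the machinery under a faithful statistical cartoon, not performance on
real archives.

## Numerical choices and degenerate inputs

- Every generator is a pure function of (config, seed); RNG state is
  saved and restored around generation.
- Ties in station distance and QTL peaks break deterministically
  (lexicographic id; leftmost position).
- A day with a single recording has variance 0, not `NA`; a window with
  no overlapping days yields `NA`, which the coverage filter then sees.
- Constant traits and non-PSD kinship matrices are errors; constant
  markers are flagged with $p = 1$ rather than failing a scan.
- Zero-total ddPCR time points are dropped; an all-boundary trajectory
  without counts is an error.

## Problem sizes used in validation

The shipped validation uses worlds of 150 strains x 2000 markers x 100
stations with daily temperature over five years (about 180k observation
rows), 50 replicates for planted-effect recovery, 200 REML fits for
heritability recovery, and pooled null scans of 1000 markers across five
worlds — sizes chosen so the entire suite re-runs comfortably on a
laptop-class single core while leaving the statistical assertions
well-powered.

## Known limitations

- The QTL interval rule is a convention, not an inference; intervals
  should be read as reporting windows.
- The 3-month window is ±45 days around the anchor; a "3 months
  following isolation" reading is equally defensible for seasonal
  questions and can be emulated by shifting the anchor.
- Arithmetic wind-direction averaging is retained for fidelity; treat
  wind-direction traits with suspicion near the 0/360 wrap.
- P3D holds variance components fixed across markers; for very strong
  single-marker effects the exact refit gives slightly different
  estimates (flag available).

## A worked miniature

```{r example, eval = FALSE}
cfg <- world_config(n_strains = 150, n_markers = 2000, n_stations = 100,
                    causal_marker_index = 1000, causal_effect_degC = 5,
                    seed = 42)
w <- generate_world(cfg, params = "temp")
obs <- harmonize_units(w$obs)
tab <- build_trait_table(w$records, w$stations, obs, "three_year",
                         elevation_provider = synthetic_elevation_provider(w))
scan <- gwas_scan(setNames(tab$temp_mean_three_year, rownames(tab)),
                  w$genotypes)
summary(scan)
plot(scan)
```
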
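---
title: "Methods: spatial-scale analysis of halite endolith microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-scale analysis of halite endolith microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloscape)
```

## The problem

Endolithic microbial communities colonise the pore space of halite (NaCl)
nodules in hyperarid salt flats. Their composition varies across nested
spatial scales — between regions of a salar tens of kilometres apart, between
hill sites hundreds of metres apart, between nodules metres apart, and
between vertical positions centimetres apart inside a single nodule. Two
families of processes shape this heterogeneity: deterministic responses to
water availability (dew and fog delivered by coastal air masses, retained as
brine by deliquescence) and to the steep light gradient inside the salt
matrix, and stochastic community drift amplified by dispersal limitation
between physically isolated rocks.

`haloscape` implements the full analysis chain needed to quantify both:
environmental event statistics from humidity loggers, intra-nodule
photosynthetically active radiation (PAR) estimation from transmission
spectra, cell-density estimation from epifluorescence counts, alpha/beta
diversity, and the inferential layer (PERMANOVA, Kruskal–Wallis, ANCOM,
slice-standardised vertical gradients, distance-scale decay). A
synthetic-data module generates the whole nested design with known ground
truth, so every statistical claim the pipeline can make is validated by
parameter recovery rather than by eye.

## Sensor series and dew/fog events

Loggers record relative humidity and temperature every 30 minutes. A *dew*
event is a maximal run of samples with RH strictly above 95%; a *fog* event
uses the 99% threshold, so every fog interval is nested inside a dew
interval. Design choices the data do not dictate, and how we fixed them:

* **Strict inequality** at the threshold: a sample at exactly 95% does not
  trigger an event.
* **Day counting**: a calendar day counts once per event type no matter how
  many events touch it; an event spanning midnight counts toward both days.
  Both conventions are configurable in spirit (events carry their exact
  start/end, so any other day rule can be derived from the event list).
* **No minimum duration and no gap merging**: the simplest maximal-run rule.
  Gaps (explicit `NA` rows on the regular grid) terminate runs and never
  count as above threshold; irregular timestamps are refused with advice to
  resample, rather than silently reindexed.

Smoothed daily profiles use a Gaussian-kernel local polynomial regression
(`kernel_smooth()`). Degree 0 is the local average used for
abundance-versus-depth curves; degree 6 matches the polynomial order used
for daily climate profiles. A local polynomial of degree *q* reproduces any
polynomial of degree ≤ *q* exactly on noiseless input, which the test suite
uses as its correctness oracle. Rank-deficient local systems fall back to
the highest identifiable degree at that query point and say so in the
output.

## Light and PAR inside the nodule

Effective transmission is the pointwise ratio of an intra-nodule
measurement to the unfiltered lamp spectrum, linearly interpolated to a
common grid and restricted to a 500–900 nm analysis window where the
detector response is reliable. Band-integrated PAR uses trapezoidal
integration of the transmitted solar intensity over 400–700 nm divided by
the incident solar integral, multiplied by the midday maximum PAR
(default 2100 µmol m⁻² s⁻¹).

Two windows conflict: the analysis window starts at 500 nm while the PAR
band starts at 400 nm. We integrate over the intersection actually covered
by the data, attach the effective band to the result, and refuse to
extrapolate. The isotropy correction — light scatters inside the salt, so a
downward-aimed probe still sees ~30% of the upward intensity, giving a
factor 1 + 0.30 = 1.3 — is available but **off by default**
(`correction = 1` in `estimate_par()`), since it is an optional adjustment
whose inclusion in any published figure is generally ambiguous.
Bottom-position PAR is not modelled at all: direct lab transmission
measurements cannot reproduce the field's lateral and under-nodule
scattering there.

## Cell density

Per-image DAPI counts scale to cells per gram by
`count × (filter_area / eFOV) × (volume_total / volume_filtered) / mass`,
with defaults eFOV 0.203 mm², filter 226.98 mm², 2 ml filtered and 0.5 g of
halite. **`volume_total` is a required experimental fact, not a constant**:
the shipped default of 10 ml is only a documented convention, and absolute
densities scale linearly with it. Outlier rejection is deliberately
one-pass — mean and SD are computed once over all per-image densities and
values beyond 2 SD are dropped without iterating — because iterative
trimming at 2 SD is not what "discarding replicates outside two standard
deviations of the mean" describes, and can cascade (the test suite contains
a worked example where iteration would discard a legitimate replicate).

## Diversity

All dissimilarity and alpha metrics are implemented from first principles
and cross-checked in the tests against independent brute-force enumeration
(and against `vegan`, `picante` and `stats::cmdscale` where those offer an
equivalent):

* Bray–Curtis: Σ|aᵢ−bᵢ| / Σ(aᵢ+bᵢ).
* Weighted UniFrac: Σ over branches of length × |P_a − P_b|, where P_x is
  the fraction of sample x's reads descending from the branch. The
  **unnormalized** variant is the default (the convention of the QIIME
  lineage this analysis follows); the normalized variant is a flag. On a
  unit-branch star tree the unnormalized value equals the L1 distance
  between relative-abundance vectors, which is the closed form the property
  tests use.
* Faith PD: total branch length of the minimal rooted subtree spanning the
  tips present (the root is included).
* Shannon uses log base 2 (bits), Pielou is Shannon / log₂(richness) and is
  reported missing for single-taxon samples.
* PCoA double-centres −D²/2 and eigen-decomposes. Negative eigenvalues
  (expected for Bray–Curtis) are reported, never clipped; variance
  proportions are over positive eigenvalues only.
* Rarefaction subsamples without replacement to exact depth, drops and
  lists shallower samples, and is deterministic under its seed. "auto"
  depth is the minimum sample total, mirroring choosing the sampling depth
  from the lowest-coverage sample.

## Inference

* **PERMANOVA** computes the one-way pseudo-F from within/among sums of
  squared dissimilarities and permutes labels freely (no strata), with
  p = (1 + #{F* ≥ F}) / (1 + n_perm). Calibration is checked empirically:
  on exchangeable null communities the type-I error at α = 0.05 must sit
  inside [0.03, 0.07] over 500 simulations with 199 permutations each.
* **ANCOM**: for each taxon, every pairwise additive log-ratio (pseudocount
  1) is tested for a group difference (two-group t-test by default,
  Wilcoxon by flag), Benjamini–Hochberg corrected *within the taxon's
  family*; W is the number of rejections, flagged at W ≥ 0.7 (n_taxa − 1).
  All four internals are configurable because the upstream pipeline's
  choices are not documented anywhere authoritative.
* **Slice standardisation** divides each relative abundance by its taxon's
  within-slice mean, making every taxon average exactly 1 per slice — an
  identity the tests assert to machine precision. Taxa absent from a slice
  become missing, not infinite.
* **Position tests** are two-sided t-tests pairing top/middle/bottom values
  on the slice they came from; zero-variance contrasts are flagged
  "degenerate" rather than given a fabricated p-value. Raw p-values are
  always reported alongside BH-adjusted ones, because the analyses this
  mirrors report raw thresholds.
* **Distance trends** combine a Spearman test of standardised abundance
  against distance-to-surface, a paired near-surface (< 1.5 cm) versus
  interior contrast, and an order-0 kernel curve. The default smoother
  bandwidth is 0.5 cm — half the width of a sampled position band. We
  verified on noiseless expected curves that wider bandwidths (≥ 0.75 cm)
  let boundary bias at the deep edge of the sampled range drag an interior
  maximum at 2.5 cm past 3 cm; 0.5 cm keeps the recovered maximum inside
  its true band.
* **Scale decay** classifies each sample pair by the finest shared nesting
  level — same nodule and position (~3 cm), same nodule (~10 cm), same site
  (~10 m), same region (~300 m), different region (~20 km) — from the
  design labels, not from coordinates, and compares adjacent classes with
  two-sided t-tests. The classes partition all fully-labelled pairs;
  excluded pairs are counted, not dropped silently.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* the nested design (defaults 2 regions × 2 sites × 6 nodules × 3 slices ×
  top/middle/bottom, 5000 reads, 12 taxa);
* a logistic-normal-multinomial count model: per-taxon log abundance =
  baseline + β_RH·RH + β_L·L + independent Gaussian community-drift effects
  at region/site/nodule/slice level + residual, then multinomial sampling
  on the softmax. This is the minimal generative model producing
  compositional data with nested drift; nothing finer is claimed for it.
* drift SDs 0.9 / 0.5 / 0.35 / 0.15 / 0.10 from region down to residual —
  strictly decreasing toward finer levels, the regime in which drift alone
  produces distance decay of similarity;
* water availability as a Gaussian bump in depth centred 2.5 cm below the
  surface (width 1.2 cm), so humidity-tracking taxa peak 2–3 cm in, plus
  region offsets 0.25 apart on the unit RH index (the more humid region
  mirrors a ~11% RH difference scaled to that index);
* light as log-PAR, −k·depth-from-top with k = 1.8 cm⁻¹, which puts the
  middle/top PAR ratio near 2% — the order observed for nodule interiors;
* the surface phototroph's light coefficient (0.10) is solved from the
  model's noiseless expectation so that its expected top-versus-middle
  relative-abundance ratio, *including* compositional renormalisation
  against the humidity-boosted interior taxa, is 1.8 (+80%) at
  representative probe depths of 1 and 3 cm;
* diel RH/temperature sinusoids with injected dew/fog events that force RH
  above the respective thresholds for exactly their stated span, so
  detection can be compared to truth exactly;
* Beer–Lambert spectra and Poisson field counts whose estimators round-trip
  their generating parameters.

What it does **not** emulate: read-level sequencing error, chimeras or
primer artifacts; rain events; taxon–taxon interactions; overdispersion
beyond the logistic-normal variance; realistic phylogenetic signal in the
effect structure (trees are random). Passing the recovery tests therefore
shows the *statistics* behave as claimed under a plausible data-generating
process, not that real nodules satisfy that process.

## Validation problem sizes

The test suite and acceptance script run the full chain at sizes chosen to
give stable Monte-Carlo estimates while staying comfortably interactive:
500 null simulations (18 samples, 199 permutations) for PERMANOVA
calibration; 100 replicates of the local design (6 nodules × 3 slices × 3
positions = 54 samples) for vertical-gradient recovery, requiring ≥ 90%
sign-correct significant recovery; 20 replicates of the full 216-sample
design for scale-decay monotonicity; ≥ 100 random small instances per
brute-force oracle comparison at 10⁻⁸ tolerance.

## Known limitations

* Absolute cell densities are undefined without the true suspension volume
  (see above).
* Bottom-position PAR is out of scope by design.
* PERMANOVA permutes freely; for strongly nested designs a restricted
  permutation scheme would be more conservative, and the pseudo-F of
  duplicated samples illustrates why (duplication never lowers it).
* ANCOM's W has no universal null distribution; the cutoff fraction is a
  convention, not a guarantee.
* The headline numbers of any particular field study (specific W values,
  dissimilarity means, dew-day counts) depend on its raw reads, sensor logs
  and spectra; with synthetic inputs this package reproduces the *behaviour*
  of the methods, and exact magnitudes only where arithmetic fixes them
  (e.g. the 1.3 isotropy factor from a 30% up/down ratio).
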
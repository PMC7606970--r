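# haloscape

Spatial-scale analysis of endolithic microbial communities in desert halite
nodules.

Halite (NaCl) nodules in hyperarid salt flats host microbial communities in
their pore space. Their composition varies across nested spatial scales —
regions of a salar ~20 km apart, hill sites ~300 m apart, nodules ~10 m
apart, and vertical positions centimetres apart inside a single nodule —
under two kinds of forcing: deterministic gradients (water availability
from dew/fog and deliquescence; a steep light gradient through the salt)
and stochastic community drift amplified by dispersal limitation between
isolated rocks. `haloscape` is for microbial ecologists who want to run
that whole analysis chain, end to end, with every statistical component
validated against ground truth on synthetic data.

## What's inside

**Environmental sensors** — dew/fog event detection on 30-min RH/T logger
series (dew: RH > 95%, fog: RH > 99%; events are maximal above-threshold
runs), site comparisons, diel profiles, and a Gaussian-kernel local
polynomial smoother (`kernel_smooth`, degree 0 = local average, degree 6
for climate curves).

**Light / PAR** — effective transmission T(λ) = measured(λ)/source(λ) on a
500–900 nm analysis window; band-integrated PAR reduction
ratio = ∫T·S dλ / ∫S dλ over 400–700 nm; PAR = ratio × PAR_max (default
2100 µmol m⁻² s⁻¹) × correction, with the isotropy correction
1 + I_down/I_up (= 1.3 at the typical 30% ratio) off by default;
standardisation of profiles to the mean "top" profile; narrow-band ratios
(e.g. chlorophyll *a*, 680 nm).

**Biomass** — cells/g = count × (A_filter/eFOV) × (V_total/V_filtered) / m,
with one-pass 2-SD replicate rejection.

**Diversity (first principles, oracle-tested)** — Bray-Curtis
Σ|aᵢ−bᵢ|/Σ(aᵢ+bᵢ); weighted UniFrac Σ_b ℓ_b·|P_a(b) − P_b(b)|
(unnormalized default, normalized flag); Faith PD; Shannon (bits), Simpson,
Pielou; rarefaction without replacement; PCoA with negative eigenvalues
reported, never clipped.

**Community statistics** — one-way PERMANOVA
(pseudo-F = (SSA/(a−1))/(SSW/(n−a)), permutation p); Kruskal–Wallis;
ANCOM's W (pairwise log-ratio tests, BH-corrected per taxon family);
slice standardisation (within-slice taxon mean = 1); paired
position tests; Spearman + smoothed distance-to-surface trends; pairwise
dissimilarity pooled by spatial-scale class (3 cm / 10 cm / 10 m / 300 m /
20 km) with adjacent-class tests; replicate noise floors.

**Synthetic data** — a logistic-normal-multinomial generator over the
nested design with humidity- and light-responsive taxa, nested drift,
injected sensor events, Beer–Lambert spectra and Poisson field counts, all
seeded and returning ground truth for recovery testing.

## Worked example

```r
library(haloscape)

# simulate the intra-nodule study: 6 nodules x 3 slices x 3 positions
des <- design_spec(1, 1, 6, 3, reads_per_sample = 5000, n_taxa = 12)
md  <- generate_metadata(des, seed = 1)
sim <- generate_counts(md, default_effects(12), des, seed = 2)

# vertical gradient: slice-standardise and test top vs middle
rel <- sim$counts / rowSums(sim$counts)
std <- slice_standardize(rel, setNames(paste(md$nodule, md$slice), md$sample_id))
pt  <- position_test(std, setNames(md$position, md$sample_id))
pt[1:4, c("taxon", "mean_diff", "t", "p")]
#>   taxon mean_diff     t        p
#> 1 ASV01     0.546  5.42 4.62e-05
#> 2 ASV02    -0.362 -5.16 7.92e-05
#> 3 ASV03    -0.298 -5.11 8.64e-05
#> 4 ASV04    -0.235 -3.05 7.20e-03
```

ASV01 is the simulated surface phototroph: its slice-standardised abundance
is higher at the top than the middle (positive `mean_diff`, p < 0.001),
while the humidity-tracking interior taxa ASV02–ASV04 go the other way.

```r
# distance decay across scale classes (full 2-region design)
desF <- design_spec(2, 2, 6, 3, reads_per_sample = 5000, n_taxa = 12)
mdF  <- generate_metadata(desF, seed = 3)
simF <- generate_counts(mdF, default_effects(12), desF, seed = 4)
scale_decay(bray_curtis(simF$counts), mdF)$summary
#>   scale n_pairs  mean     sd
#> 1  3 cm     216 0.101 0.0352
#> 2 10 cm     648 0.121 0.0476
#> 3  10 m    4860 0.216 0.0650
#> 4 300 m    5832 0.287 0.0759
#> 5 20 km   11664 0.397 0.0773
```

Mean Bray-Curtis dissimilarity rises monotonically from samples a few
centimetres apart inside one nodule to samples in different regions —
distance decay of similarity produced by nested drift.

```r
# dew/fog events from a sensor series with two injected events
ev <- data.frame(type = c("dew", "fog"), day = c(3, 9),
                 start_hour = c(1, 2), duration_h = c(3, 6))
s <- generate_sensor_series(14, events = ev, seed = 5, noise_sd_rh = 0.5)
detect_events(s$series, threshold = 95)$summary
#> $threshold 95; $n_events 2; $n_days 2; $mean_duration_h 4.5; $max_duration_h 6

# PAR inside a nodule at a 0.00224 reduction ratio, with isotropy correction
estimate_par(0.00224, par_max = 2100,
             correction = isotropy_correction(0.30, 1))$par
#> [1] 6.1152
```

The fog event (RH > 99%) is found by the dew detector too (99 > 95), so two
dew days are reported; event durations are recovered exactly. The PAR call
shows the full arithmetic: 0.00224 × 2100 × 1.3.

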
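# phytotrack

Provenance attribution for open-ocean eukaryotic phytoplankton communities
profiled by 18S rRNA gene metabarcoding, plus Lagrangian water-mass
backtracking.

## What it does, and for whom

A station sampled over a year, from the surface layer down to the
abyssopelagic zone, yields a table of sequence variants (SVs) by samples.
Two questions drive the analysis:

* **Temporal provenance.** For each month's surface community, how much of it
  (reads or richness) is carried by SVs already detected in earlier months,
  versus SVs detected for the first time — candidate allochthonous arrivals
  such as coastal diatoms entrained by currents?
* **Vertical provenance.** For each depth zone, how much of the community is
  carried by SVs first seen in the surface layer — the fingerprint of export
  by the biological carbon pump — versus SVs first appearing at depth?

Both are answered by *first-detection attribution*: with groups (months, or
zones ordered surface → abyssopelagic) totally ordered, an SV's origin is the
earliest group where its summed count is positive, and each target group's
community is partitioned by origin,

    fraction(target, origin) = sum of weights of target SVs with that origin
                               / total weight in the target,

with weights equal to read counts (`basis = "reads"`) or 1 per present SV
(`basis = "richness"`). Fractions sum to 1 for every non-empty target.

Around this core the package provides the standard steps — phytoplankton
taxon filtering (dinoflagellates and flagged heterotrophs excluded),
rarefaction to a common read depth, representative-SV extraction (≥ 5% of a
sample's reads), vertical occurrence-pattern classification, Bray–Curtis
dissimilarity and PERMANOVA — and a deterministic RK4 Lagrangian integrator
that backtracks particles through layered 2-D gridded velocity fields
(NetCDF) to ask where the sampled water came from. Synthetic generators for
communities with planted provenance structure and analytic velocity fields
with closed-form trajectories make every stage verifiable offline.

Intended users: microbial oceanographers and bioinformaticians working with
amplicon time series plus reanalysis velocity products.

## Worked example

```r
library(phytotrack)

sc  <- community_scenario(allochthonous_read_fraction = 0.5, seed = 42)
sim <- generate_community(sc)                 # counts, meta, taxonomy, truth
phyto <- filter_phytoplankton(sim$counts, sim$taxonomy)

months  <- levels(sim$meta$month)
surface <- select_samples(sim$meta, zone = "surface", fraction = "large")
sel <- lapply(months, function(m)
  intersect(select_samples(sim$meta, month = m), surface))
names(sel) <- months

attribution <- attribute_temporal(phyto, months, selector = sel, basis = "reads")
subset(attribution, target == "2011-02")
#>    target  origin basis  fraction
#> 2 2011-02 2010-11 reads 0.5103817
#> 3 2011-02 2011-02 reads 0.4896183
```

The generator planted allochthonous taxa carrying 50% of February's surface
phytoplankton reads; attribution recovers 49.0% first-detected-in-February
against 51.0% carried over from November — the planted value up to
multinomial noise (sd ≈ 0.5%).

```r
fld <- generate_field("uniform", list(u0 = 0.1, v0 = 0),
                      lon_range = c(135, 150), lat_range = c(25, 35))
p  <- seed_grid(c(145, 30), half_width = 0.25, spacing = 0.025,
                level = 0, t0 = 90 * 86400)   # 441 particles
tr <- integrate_backward(fld, p, 90 * 86400, 3 * 3600, store_every = 720)
head(final_positions(tr), 3)
#>        lon   lat status
#> 1 136.6952 29.75 active
#> 2 136.7202 29.75 active
#> 3 136.7452 29.75 active
```

A steady 0.1 m s⁻¹ eastward current places the water sampled at the station
~8.1° to the west 90 days earlier (u·T / (R cos φ)), which the integrator
reproduces to better than 1e-6 relative error.

A thin command-line front end over the same functions lives at
`inst/cli/phytotrack.R` (subcommands `filter-taxa`, `rarefy`,
`attribute-temporal`, `attribute-vertical`, `representative`, `patterns`,
`permanova`, `backtrack`, `simulate-community`, `simulate-field`).

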
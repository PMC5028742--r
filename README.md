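# ednadiv

Occupancy-filtered diversity analysis for environmental-DNA (eDNA)
metabarcoding surveys with nested, replicated sampling designs.

## The problem

eDNA metabarcoding can census hundreds of animal taxa from a litre of
water, which makes it attractive for asking how human land use reshapes
nearby ecological communities. But the raw OTU-by-replicate read table is
not yet data you can do ecology on: PCR contamination creates false
detections, uneven sequencing depth distorts richness, and the sampling
design is nested (site pairs along an urbanization gradient > sites >
transects > water samples > PCR replicates), so naive analyses
pseudoreplicate. `ednadiv` implements the full chain from raw counts to
gradient inference, for studies that pair more- and less-urbanized sites
and use watershed imperviousness (%) as the urbanization proxy:

1. **Decontamination** — per OTU, detections across the K PCR replicates
   of each water sample are modelled as a two-component binomial mixture
   with occupancy probability ψ, true-detection probability p11 and
   false-positive probability p10:
   `L = prod_i [ψ·Bin(y_i; K, p11) + (1−ψ)·Bin(y_i; K, p10)]`.
   Detections whose posterior probability of true presence falls below a
   threshold (default 0.8) are zeroed.
2. **Normalization** — every replicate is rarefied (hypergeometric
   subsampling) to the smallest surviving replicate total; replicates are
   then averaged per water sample and converted to presence/absence.
3. **Diversity** — alpha richness (OTU and family level), within-site
   Whittaker beta `β_w = S/ᾱ − 1`, Raup-Crick null-model dissimilarity
   (richness-conditioned, occupancy-frequency-weighted, rescaled to
   [−1, 1]), bootstrap gamma accumulation curves with `a + b·ln(m)` fits,
   and a nested PERMANOVA partitioning Jaccard distance among sites,
   transects within sites, and PCR replicates, with restricted
   permutations per stratum.
4. **Life histories** — family trait sets (Category × Habitat × Mobility)
   expand into niche triples; niche richness and niches-per-family
   (redundancy) per site.
5. **Association** — per-OTU logistic regression of presence on
   imperviousness (with separation detection and a penalized fallback),
   Poisson richness trends, exact binomial tests, and site-mean OLS.

A synthetic-study generator (`simulate_study()`) emulates the whole
design with known ground truth — site pools, transect communities,
contamination events — so every stage is validated by parameter recovery,
not just by running without error.

## Worked example

```r
library(ednadiv)

study <- simulate_study(fixture_config(), seed = 7)   # counts, design, taxonomy, traits, truth
cfg <- pipeline_config(study$counts, study$design, study$taxonomy, study$traits,
                       out_dir = "run1", n_draws = 20, n_perm = 199,
                       n_null = 199, n_boot = 200, seed = 11)
bundle <- run_pipeline(cfg)
cat(pipeline_report(bundle), sep = "\n")
```

```
eDNA diversity pipeline report
sites: 8 in 4 pairs; bottles: 24; replicates: 96

site  pair   urban  imperviousness  alpha_otu  alpha_family  beta_w     niche_richness  niches_per_family
P1L   pair1  less    7.30            45.3       22.7          0.765      40              1.143
P1M   pair1  more   59.86           148.7       51.7          0.318      40              0.714
...
variance partition (Jaccard, nested PERMANOVA):
  among sites: 56.6%; transects within sites: 39.2%; PCR replicates: 4.2%
richness ~ imperviousness: slope 1.843 (R2 0.99, p 1.25e-07)
within-site beta ~ imperviousness: slope -0.0068 (R2 0.91, p 0.000222)
OTUs associated with imperviousness at p<0.01: 18 positive, 0 negative
```

Reading this: richness *rises* along the urbanization gradient (the
generator was configured with a positive richness slope, and the fitted
slope of 1.84 OTUs per % imperviousness recovers it after detection and
rarefaction losses), while within-site beta *falls* — transects at urban
sites become compositionally more similar (homogenization). Most
community variance sits among sites and among transects within sites,
with only ~4% attributable to PCR replicates, and 18 OTUs are
individually, positively associated with imperviousness at p < 0.01.

A thin CLI wraps the same functions
(`Rscript inst/cli/edna.R simulate|run|report`, YAML configs).

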
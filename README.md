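# picodepth

Depth-stratified community structure and rRNA:rDNA relative activity of
marine picoeukaryotes, as a tested, reusable R pipeline.

Global ocean surveys sequence the 18S rRNA gene (V4) from both DNA and
RNA extracts of the same water samples: the DNA survey describes who is
there, the RNA survey who is making ribosomes. `picodepth` is for
microbial ecologists working with such paired amplicon OTU tables across
water-column layers (surface, deep chlorophyll maximum, mesopelagic,
bathypelagic). It covers the whole downstream analysis once OTU tables
exist: rarefaction, alpha/beta diversity with permutation tests,
per-OTU relative-activity ratios and their layer contrasts, oxygen
minimum zone (OMZ) and deep scattering layer (DSL) comparisons,
generalized UniFrac over a supplied phylogeny — plus a synthetic-data
generator with known ground truth, so every stage is testable at desk
scale.

## The core statistic

For OTU *i* detected in both templates of one water sample, with
relative abundances $p^{RNA}_i$ and $p^{DNA}_i$ after rarefaction, the
relative activity is

$$r_i = \frac{p^{RNA}_i}{p^{DNA}_i}$$

with $r > 1$ *hyperactive*, $r < 1$ *hypoactive*, $r \approx 1$
*average* (default band 0.5–2). OTUs seen in only one template of a
pair yield no ratio — zeros exclude, they are never turned into 0, ∞,
or a pseudo-count. Ratios pool by taxonomic group and layer; pairwise
two-sided Wilcoxon rank-sum tests (Benjamini–Hochberg adjusted) flag
the layers where a group is significantly more or less active. Because
both surveys are compositions, ratios carry only *relative* information:
contrasts across layers within a group are interpretable, absolute
activities and cross-group levels are not (rDNA copy number differs by
orders of magnitude across lineages).

Community structure uses the standard ecology stack behind a uniform
interface: Bray–Curtis dissimilarity, NMDS, ANOSIM (Clarke's R, 1,000
permutations), PERMANOVA with sequential sums of squares, Shannon
diversity and richness (all via vegan), and generalized UniFrac

$$d^{(\alpha)} = \frac{\sum_i b_i (p_{Ai}+p_{Bi})^\alpha\,|p_{Ai}-p_{Bi}|/(p_{Ai}+p_{Bi})}{\sum_i b_i (p_{Ai}+p_{Bi})^\alpha},\qquad \alpha = 0.5 \text{ by default,}$$

implemented in-package (no installed package provides the
$\alpha$-parameterized form).

## Worked example

Simulate the default survey — 13 stations × 7 depths across three ocean
basins, rDNA and rRNA templates, 680 OTUs in 17 named groups, 25,000
reads per sample — then run the activity analysis:

```r
library(picodepth)

paths <- simulate_dataset("demo", seed = 1)
tab  <- read_otu_table(paths$combined)
meta <- read_metadata(paths$metadata)
tax  <- read_taxonomy(paths$taxonomy)
tab
#> OTU table: 680 OTUs x 182 samples, 4550000 reads

rar    <- rarefy(tab, seed = 1)
halves <- split_by_template(rar, meta)
rel    <- lapply(halves, relative_abundance)

# photic vs aphotic community differentiation (rRNA survey)
bc <- bray_curtis(rel$rRNA)
m  <- meta[match(labels(bc), meta$sample_id), ]
anosim_test(bc, ifelse(m$layer %in% c("surface", "DCM"),
                       "photic", "aphotic"), seed = 1)
#> $statistic
#> [1] 0.6460102
#> $p_value
#> [1] 0.000999001

# per-OTU rRNA:rDNA ratios and their layer medians
recs <- activity_ratios(rel$rDNA, rel$rRNA, pair_samples(meta), tax)
nrow(recs)
#> [1] 50791
round(sapply(split(recs$ratio, factor(recs$layer, PICO_LAYERS)), median), 2)
#>      surface          DCM  mesopelagic bathypelagic
#>         1.39         1.16         2.33         1.00

layer_contrasts(recs)
#> Layer contrasts for 17 groups (alpha = 0.05 , BH adjusted)
#>   Bicosoecida                  high: mesopelagic; low: bathypelagic
#>   Chrysophyceae                high: bathypelagic; low: DCM
#>   Ciliophora                   high: mesopelagic; low: bathypelagic
#>   ...
```

Reading the output: ANOSIM R = 0.65 (p ≈ 0.001) says photic and aphotic
communities are strongly separated in the rRNA survey. The pooled ratio
medians peak in the mesopelagic (2.33) and fall to parity in the
bathypelagic, and the per-group contrasts recover the simulated truth:
every heterotrophic group is flagged significantly high in the
mesopelagic and low in the bathypelagic, the phototrophs peak at the
DCM, while the always-on mixotrophs (Chrysophyceae, Dinoflagellata,
RAD-B) *appear* most active in the bathypelagic — the compositional
mirror image of everyone else shutting down, and a caution for
interpreting real ratio data.

`run_pipeline(pipeline_config(...))` chains every stage (read → rarefy →
split → diversity → activity → biogeography → zones → phylo), writes
per-stage TSVs with all thresholds echoed in their headers, and records
a YAML manifest of parameters and seeds; reruns with the same seed are
byte-identical.

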
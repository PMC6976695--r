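---
title: "Depth-stratified community structure and rRNA:rDNA relative activity: methods"
author: "picodepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-stratified community structure and rRNA:rDNA relative activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picodepth)
```

## The analysis

`picodepth` analyses paired DNA- and RNA-derived 18S amplicon OTU tables
from ocean surveys sampled across depth layers (surface, deep chlorophyll
maximum, mesopelagic, bathypelagic). Three questions drive the design:

1. **Vertical community structure.** After rarefying all samples to a
   common sequencing depth, Bray–Curtis dissimilarities feed NMDS
   ordination, ANOSIM (photic vs aphotic grouping) and PERMANOVA
   (environmental terms). Shannon diversity and OTU richness summarize
   alpha diversity per sample.
2. **Relative metabolic activity.** Ribosome content tracks protein
   synthesis, so for an OTU detected in both the rDNA and rRNA survey of
   the same water sample, the ratio of its relative abundances,
   $r = p_{\mathrm{RNA}} / p_{\mathrm{DNA}}$, is a proxy for the
   relative activity of that taxon in that sample. Ratios above 1 flag
   *hyperactive*, below 1 *hypoactive*, and near 1 *average* activity.
   Ratios pool within taxonomic group and water layer; two-sided
   Wilcoxon rank-sum tests compare layers pairwise, and a layer is
   flagged significantly high (low) for a group when its median exceeds
   (falls below) every other layer's and all its pairwise tests pass the
   adjusted significance level.
3. **Mesopelagic special zones.** The oxygen minimum zone (OMZ,
   mesopelagic water with O$_2$ < 2 mg L$^{-1}$, strict inequality) and
   the deep scattering layer (DSL, an acoustic observation carried here
   as a metadata flag) are each contrasted against the remaining
   mesopelagic samples: per-group abundance ratios, activity ratios, and
   a rank-sum test on per-sample richness.

A phylogeny over the OTUs (supplied as newick; the package does not
infer trees) supports generalized UniFrac distances among the OTU sets
preferentially active in each layer.

## Key modelling decisions

**Ratios are compositional.** Both surveys renormalize to 1, so only
*contrasts* of activity between taxa are observable: multiplying the
whole community's activity by a constant changes nothing. This has two
user-facing consequences. First, ratios say nothing about absolute
activity; rDNA copy number varies enormously across eukaryote lineages,
so cross-group ratio comparisons are confounded and the package only
interprets within-group contrasts across layers. Second, a group's
apparent activity rises when the rest of the community shuts down — in
the simulator's bathypelagic, groups that keep activity constant show
ratios well above 1 because most of the community is suppressed. This is
a property of the data type, not an artifact.

**Zeros exclude, never inflate.** A ratio exists only where an OTU is
detected in both templates of a pair; no pseudo-counts are added
anywhere. The exclusion is decided per paired sample (the only reading
that keeps every stored ratio finite); a whole-dataset pre-filter is
available as an option. The cost is a detection-conditioning bias: for
rare OTUs the requirement of presence in both templates pulls ratio
medians toward 1, which is why very sparse data blunt layer contrasts.

**Wilcoxon tests are unpaired and BH-adjusted.** Layers contain
different numbers of pairs, so a paired test is impossible. The six
pairwise layer comparisons per group are Benjamini–Hochberg adjusted;
both raw and adjusted p-values are reported because the choice of
correction is a convention, not a discovery.

**The "average" activity band.** "Near 1" needs an operational width;
the default band (0.5, 2) — within two-fold of parity — is a mandatory,
echoed configuration parameter, not a detected constant.

**ANOSIM reports R.** The statistic is Clarke's R on mid-ranked
dissimilarities, in $[-1, 1]$, with a one-sided permutation p-value
$(\#\{R^\ast \ge R\} + 1)/(n_{\mathrm{perm}} + 1)$. Survey literature
sometimes prints ANOSIM effect sizes labelled $R^2$; this package
reports R.

**PERMANOVA uses sequential sums of squares** in the user's term order,
permuting raw rows; explained plus residual $R^2$ sum to 1. Marginal
(Type III) partitioning is not offered, so term order matters and should
be stated alongside results.

**Rarefaction is without replacement** (multivariate hypergeometric per
sample, via `vegan::rrarefy`), to the minimum column sum by default.
Samples below the target depth are dropped and recorded, never padded.

**Generalized UniFrac.** For two communities A, B with per-branch
descendant proportions $p_{Ai}, p_{Bi}$ and branch lengths $b_i$,

$$d^{(\alpha)} = \frac{\sum_i b_i (p_{Ai}+p_{Bi})^\alpha
  \left|\frac{p_{Ai}-p_{Bi}}{p_{Ai}+p_{Bi}}\right|}
  {\sum_i b_i (p_{Ai}+p_{Bi})^\alpha}, \qquad \alpha \in [0,1],$$

computed by a single post-order accumulation; $\alpha = 0.5$ by default
(down-weighting abundant lineages), $\alpha = 1$ recovering weighted
normalized UniFrac. Branches subtending no abundance contribute nothing;
the root has no branch; multifurcations are accepted; unrooted input is
midpoint-rooted with a warning. The distance is invariant to rescaling
all branch lengths.

**Layer boundaries.** Surface $\le$ 10 m; DCM is an explicit metadata
flag (its depth varies by station, so it is never inferred from depth);
mesopelagic (200, 1000] m; bathypelagic (1000, 4000] m. Sublayer splits
default to 500 m (mesopelagic) and 2000 m (bathypelagic); the literature
describes sublayers without fixing bounds, so both are configurable.

## The synthetic survey generator

`sim_design()` and `simulate_tables()` generate a paired rDNA/rRNA
survey with known ground truth, defaulting to the canonical design of 13
stations across three ocean basins, each with 7 depths (surface, DCM,
two mesopelagic, three bathypelagic) and both templates — 91 water
samples, 182 sequenced samples, 25,000 reads each.

The generative model, per water sample:

1. each group's expected mass in a layer follows its depth archetype
   (increase with depth / decrease with depth / mesopelagic peak / DCM
   peak), with a 17-group default roster of named picoeukaryote
   lineages;
2. OTU masses within a group are log-normal (sd `otu_sigma`, default 1),
   drawn once as a reference community, then perturbed per sample by
   log-normal between-station drift whose sd grows with depth
   (`decay_rate`: 0.30, 0.35, 0.60, 1.00 by layer) — this produces the
   widening of between-station dissimilarity in the dark ocean;
3. the normalized masses are the latent "cell" proportions, shared by
   both templates;
4. rDNA proportions multiply in per-group rDNA copy factors (MALV-I ×10,
   MALV-II ×8, others 1), emulating the chronic overrepresentation of
   marine alveolates in DNA surveys;
5. rRNA proportions multiply in group-by-layer activity factors:
   heterotrophic groups ×3 in the mesopelagic and ×0.3 in the
   bathypelagic; phototrophic groups ×2 at the DCM and ×0.5 in the
   bathypelagic; mixotrophic groups constant;
6. in OMZ samples (designated Pacific stations, mesopelagic depths with
   simulated O$_2$ < 2 mg L$^{-1}$), ciliate-, dinoflagellate- and
   MALV-II-like groups are enriched ×4;
7. reads are multinomial at the configured depth (a
   Dirichlet-multinomial overdispersion switch exists but is off by
   default, keeping sampling expectations closed-form).

Because ratios are compositional (above), step 5 only works if some of
the community is *unaffected*: the mixotrophic groups — which dominate
the simulated bathypelagic — and the phototrophs are the reference frame
against which the heterotrophs' mesopelagic peak and bathypelagic trough
become observable. All effect sizes are generator conventions chosen for
testability; the source surveys report no quantitative depth-response
effect sizes.

**What the generator does not emulate.** Real amplicon surveys carry
tens of thousands of OTUs in an extremely heavy-tailed abundance
spectrum; most OTUs are rare enough to be detected at a single station.
At desk scale (680 OTUs, 25,000 reads/sample) detection saturates —
nearly every simulated OTU is found at every station — so
occupancy-driven statistics (declining prevalence curves, the structure
of layer-shared OTU counts) do not emerge under the defaults. They are
exercised instead under a sparse-sampling configuration (1,000
reads/sample, `otu_sigma = 2.5`, one depth per layer so detection effort
is balanced). Raising `otu_sigma` under the default depth instead
degrades the activity analysis through detection conditioning, which is
the generator faithfully reproducing a real limitation of ratio data.
Passing tests on synthetic data therefore demonstrate the machinery and
its statistical calibration, not field performance on real surveys.

## Numerical conventions

* All randomness is seeded; rarefaction, simulation, NMDS, ANOSIM and
  PERMANOVA are deterministic given their seed, and full pipeline reruns
  are byte-identical.
* NMDS: Kruskal stress-1, monotone regression, 20 random starts by
  default (via `vegan::metaMDS`).
* Ties: dissimilarity ranks use mid-ranks; an OTU whose maximum median
  activity is tied between layers is flagged ambiguous and excluded from
  layer sets rather than assigned arbitrarily.
* Degenerate inputs error early with located messages: duplicate ids,
  negative or non-integer counts, empty samples, water-mass fractions
  off unity, missing branch lengths, unnormalized abundance vectors
  (tolerance 1e-6).
* Groups with zero abundance on one side of a zone contrast are reported
  with a reason code, never as an infinite ratio. Fully tied rank-sum
  comparisons report p = 1.
* The share filter for zone contrasts (default 0.05% of mesopelagic
  reads) and the activity band are echoed into every output header.

## Problem sizes used in the test suite

The suite runs the full default design (13 × 7, two templates, 680
OTUs, 25,000 reads) for parameter-recovery and distance-decay checks (20
replicate simulations each), 2,000 small structureless replicates for
type-I-error calibration of ANOSIM and the layer contrasts, and
enumeration-scale fixtures (6 samples, ≤6-tip trees) for the
permutation and UniFrac oracles. These sizes were chosen so the whole
suite completes in a couple of minutes while keeping every Monte-Carlo
acceptance margin comfortably away from its threshold.

## Known limitations

* rRNA:rDNA ratios are relative activity proxies only; no growth-rate or
  absolute-activity inference is attempted, and cross-group comparisons
  are confounded by rDNA copy number.
* The per-pair exclusion rule biases rare-OTU ratios toward 1; analyses
  of very sparse groups should be read with that in mind.
* PERMANOVA percentages depend on term order (sequential SS).
* The DSL is a metadata flag; no acoustic processing is included.
* No FASTQ processing, OTU clustering, taxonomic assignment or tree
  inference — tables, taxonomy and tree are inputs.
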
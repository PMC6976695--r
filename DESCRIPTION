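Package: picodepth
Title: Depth-Stratified Community Structure and rRNA:rDNA Relative
    Activity of Marine Picoeukaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired DNA- and RNA-derived 18S amplicon
    OTU tables from depth-stratified marine surveys. Provides readers and
    writers for OTU count tables, sample metadata and taxonomy maps;
    rarefaction and relative-abundance transforms; alpha and beta
    diversity with permutation tests (ANOSIM, PERMANOVA) and NMDS
    ordination; per-OTU rRNA:rDNA relative-activity ratios with
    layer-wise contrasts; horizontal-structure summaries (dissimilarity
    distributions, prevalence curves, layer-restricted OTUs); oxygen
    minimum zone and deep scattering layer contrasts; generalized UniFrac
    over a supplied phylogeny; and a synthetic-data generator that
    emulates the statistical structure of a global paired rDNA/rRNA
    survey for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
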
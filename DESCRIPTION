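Package: ednadiv
Title: Occupancy-Filtered Diversity Analysis for eDNA Metabarcoding Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing environmental DNA (eDNA) metabarcoding
    surveys with nested, replicated sampling designs (site pair > site >
    transect > water sample > PCR replicate). Implements occupancy-model
    decontamination of OTU detections via a two-component binomial mixture
    over PCR replicates, rarefaction to a common sequencing depth,
    hierarchical alpha/beta/gamma diversity with Raup-Crick null models and
    nested PERMANOVA variance partitioning, life-history niche expansion
    and redundancy metrics, and per-OTU association tests along an
    urbanization gradient. Includes a synthetic-study generator with known
    ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
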
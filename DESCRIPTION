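Package: crisprascreen
Title: Simulation and Hit Calling for In Vivo CRISPR Activation Screens
Version: 1.0.0
Authors@R:
    person("crisprascreen", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for pooled in vivo CRISPR activation (CRISPRa) screens read
    out by guide-RNA amplicon sequencing, with an emphasis on tail-vein
    experimental-metastasis designs where a severe engraftment bottleneck is
    followed by positive selection. Provides a guide library data model, a
    seed-deterministic screen simulator (Poisson transduction, hypergeometric
    aliquot sampling, per-cell lung-survival bottleneck, lognormal clonal
    outgrowth, Dirichlet-multinomial sequencing), exact-match FASTQ
    demultiplexing and guide quantification, control-replicate read filtering
    and total-count normalization, a percentile-rank hit caller based on
    per-sample z-scores and cross-mouse recurrence, a joint guide-efficacy by
    gene-effect bilinear model with a timepoint contrast ranking, and
    representation/enrichment quality control with an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
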
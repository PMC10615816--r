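Package: melonmeta
Title: Meta-QTL Integration of Published Melon QTLs on a Single Physical Reference
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates quantitative trait loci (QTLs) published across many
    independent melon mapping studies onto one physical reference genome.
    QTL intervals are lifted to physical coordinates from alignments of their
    1-kb flanking sequences (PAF format), over-wide intervals are removed by a
    quarter-chromosome filter, and the projected landscape is summarized:
    per-chromosome counts, 5-Mb QTL hotspot clusters, same-trait overlap
    groups and cross-trait co-localizations. Consensus meta-QTLs are then
    estimated per trait and chromosome with a Gaussian mixture model with
    known per-observation variances (derived from confidence-interval widths),
    the number of components selected by the Akaike information criterion, and
    consensus positions obtained by inverse-variance weighting. A fully
    seeded synthetic-data generator produces ground-truthed QTL tables and
    flank alignments so the whole pipeline can be exercised and scored without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
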
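Package: skipticr
Title: Detection of Constitutive Exon Skipping Driven by Elevated Nuclear
    TDP-43
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Junction-level quantification of exon inclusion (percent
    spliced-in, PSI) from splice-junction read counts, classification of
    constitutive exons that become aberrantly skipped ("skiptic" exons)
    when nuclear TDP-43 protein is elevated, UG/GU dinucleotide repeat
    metaprofiles around splice sites, nonsense-mediated decay prediction
    for skipped exons, and an arithmetic dose model linking construct
    expression, passive nuclear diffusion, and exon-skipping response.
    Includes seed-deterministic synthetic-data generators with truth
    tables for every stage and an end-to-end pipeline driver.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
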
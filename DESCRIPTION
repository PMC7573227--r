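Package: taxbridge
Title: Unify Amplicon Taxonomic Profiles for Downstream Analysis Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads operational taxonomic unit (OTU) and amplicon sequence
    variant (ASV) abundance tables produced by three upstream marker-gene
    (16S/18S/ITS) processing dialects (per-rank provider tables, single
    semicolon-lineage ASV tables, and QIIME 2 feature-table exports including
    .qza containers) into one canonical feature-table model; validates sample
    metadata, repairs taxonomic lineages to a strict hierarchy, collapses
    counts to a chosen rank, rarefies by repeated subsampling without
    replacement, and splits representative-sequence FASTA files with their
    paired abundance tables under an upload size limit. Writes correctly
    formatted inputs for STAMP (SPF profiles), ranacapa, Cytoscape edge
    lists, QIIME 2, and spreadsheet pivot analysis, and carries the inferred
    functional leg: merging chunked KO/pathway abundance results, parsing
    KEGG BRITE .keg hierarchies, annotating KO tables, and exporting
    functional profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    tools,
    utils,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
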
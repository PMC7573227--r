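# taxbridge

Marker-gene (16S/18S/ITS) microbiome studies rarely end in the pipeline
that produced them. Sequencing providers and denoising pipelines hand back
OTU/ASV abundance tables in mutually incompatible layouts — per-rank
provider tables, single semicolon-lineage ASV tables, QIIME 2 exports and
`.qza` containers — while the analysis and visualization tools researchers
actually want to use (STAMP, ranacapa, Cytoscape, QIIME 2, spreadsheet
pivot tables, functional-inference web servers) each demand their own input
format and their own formatting rules. Bridging them by hand means hours of
error-prone reformatting.

`taxbridge` unifies these dialects into one canonical feature-table model,
applies the validation/repair/resampling steps the downstream tools
require, and writes correctly formatted inputs for every target — including
the inferred-functional leg: splitting sequence uploads under a server's
size limit, merging the per-chunk result archives, and annotating KO
abundance tables against the KEGG BRITE hierarchy. It is aimed at
microbiome researchers (and instructors of classroom research courses) who
receive processed taxonomic profiles and want to analyze them in GUI/web
tools without writing conversion scripts.

## The model and core computations

A profile is a feature × sample matrix of non-negative integer counts; each
feature carries a **lineage**: a fixed 7-rank taxonomy path
(kingdom/domain, phylum, class, order, family, genus, species) in which
unclassified ranks are explicit markers, never blanks.

* **Strict hierarchy.** A lineage is *strict* iff no classified rank lies
  below an unclassified one — formally, for classified indicator
  `c(r) ∈ {0,1}` over ranks `r = 1..7`, strictness is `c` non-increasing.
  STAMP rejects profiles violating this (e.g. *Proteobacteria,
  Gammaproteobacteria, Enterobacteriales, unclassified, Escherichia,
  unclassified*: family unclassified, genus classified). `repair_lineage()`
  restores strictness either by **fill** (interior gaps become named
  placeholders `unclassified_<nearest classified ancestor>`, preserving the
  deeper classification) or **truncate** (everything from the shallowest
  gap down becomes `unclassified`).
* **Rarefaction.** Each sample is subsampled without replacement to a
  common depth `d`; with `k ≤ 10` iterations the per-feature counts are
  averaged over independent draws and rounded half-up. Samples with total
  `< d` are dropped with a warning. With `k = 1`, every rarefied column
  sums to exactly `d`.
* **Size-constrained co-chunking.** Representative sequences and their
  abundance table are split greedily, in input order, so that every
  serialized FASTA chunk stays ≤ 10 MB (the functional-inference server's
  upload cap), each chunk paired with the sub-table of exactly its
  features. Chunks partition the input.
* **Functional annotation.** Per-chunk KO/pathway result tables are merged
  by element-wise sum over the union of IDs; a KEGG BRITE `.keg` file is
  parsed into KO → (description, level-A/B/C category paths); each KO row
  gains its annotation (lexicographically first path as primary, full list
  as a sidecar), without ever altering an abundance value.

## Worked example

```r
library(taxbridge)

# the classic problematic lineage: genus below an unclassified family
x <- lineage(c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
               "Enterobacteriales", NA, "Escherichia", NA))
lineage_is_strict(x)
#> [1] FALSE
repair_lineage(x, mode = "fill")
#> [1] "Bacteria"                       "Proteobacteria"
#> [3] "Gammaproteobacteria"            "Enterobacteriales"
#> [5] "unclassified_Enterobacteriales" "Escherichia"
#> [7] NA
```

The family gap becomes a named placeholder so the genus survives; the
trailing `NA` renders as the literal label `unclassified` in every output
file. A full run, using the package's synthetic dataset generator:

```r
fx <- generate_fixture("demo", dialect = "anacapa", n_samples = 12,
                       n_features = 100, gap_prob = 0.2, seed = 1)
tb <- read_anacapa(fx$files$table)
tb
#> feature_table: 100 features x 12 samples (anacapa rank ladder)
#>   total count: 35809
#>   strict lineages: 20 / 100

run <- run_community(list(dialect = "anacapa", table = fx$files$table,
                          metadata = fx$files$metadata, seqs = fx$files$seqs,
                          rarefy_depth = 1000, rarefy_iters = 3, seed = 1,
                          out = "demo_out"))
run
#> run folder: demo_out/output/20260924-043425Z
#> 11 files written; 0 warnings
head(run$manifest, 3)
#>                            file  bytes                              md5
#> 1 cytoscape/community_edges.tsv  26874 fd083d1fe9c8f28d0b16f2ea80800a16
#> 2      excel/community_long.tsv 167415 6139f5531dff3b15556c999d894f8b98
#> 3    piphillin/piphillinotu.csv   3940 f26bbb54eb899de73920d308eb98023f
```

With `gap_prob = 0.2` only 20/100 generated lineages start out strict; the
run repairs all of them before writing. Averaging 3 rarefaction iterations
leaves column totals within rounding of the requested depth (here
1002, 992, 1001, ... for depth 1000). The timestamped run folder holds one
subfolder per target (`excel`, `stamp`, `ranacapa`, `cytoscape`, `qiime2`,
`piphillin`, `functional`) and a `manifest.tsv` of every file with its byte
count and MD5 digest; re-running the same config, seed and timestamp
reproduces the manifest digest-for-digest. `run_functional()` does the same
for the inferred-function half (result archives + `.keg` hierarchy in,
annotated STAMP/long/edge-list files out). A thin command-line wrapper
lives at `inst/cli/taxbridge.R`.

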
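---
title: "Unifying amplicon taxonomic profiles: model, repair, resampling and export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unifying amplicon taxonomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxbridge)
```

## The problem and the canonical model

Marker-gene profiling pipelines disagree about everything except the
underlying object: a matrix of non-negative integer counts, features
(OTUs/ASVs) by samples, each feature labeled with a taxonomy path.
`taxbridge` fixes one canonical in-memory model and treats every upstream
dialect as a reader into it and every downstream tool as a writer out of
it.

A **lineage** is always length 7 (kingdom/domain, phylum, class, order,
family, genus, species — the two ladder spellings differ only in the label
of rank 1). Unclassified ranks are explicit `NA` markers. On ingest, the
tokens `unclassified`, `unknown`, `na`, the empty string (case-insensitive)
and bare rank prefixes such as `g__` all count as unclassified: blank cells
*must* be recognized at parse time because several downstream tools reject
blank labels outright, and a blank that survives ingestion would surface as
a malformed profile much later. Inputs annotated below 7 ranks are
right-padded with markers; deeper annotations (sub-species) are truncated
with a warning, since none of the supported downstream formats can carry
them.

Counts are stored as integers and fractional cells are rejected rather
than rounded. Relative-abundance tables look superficially identical to
count tables, but silently rounding them would corrupt every downstream
statistic (rarefaction in particular is meaningless on percentages), so
the package refuses and asks the user for the count-scaled delivery.

## Strict-hierarchy repair

Tree-structured profile tools require that classification not resume below
a gap: with classified-indicator $c(r)\in\{0,1\}$ over ranks $r=1..7$, a
lineage is *strict* iff $c$ is non-increasing. The canonical failure is
*..., Enterobacteriales, unclassified, Escherichia, unclassified*: the
family is unclassified while the genus is not, so the genus has no
well-defined parent.

Two repair modes are offered:

* **fill** (default): each interior gap becomes the named placeholder
  `unclassified_<nearest classified ancestor>`; trailing gaps keep the
  literal label `unclassified`. Fill is the default because the deeper
  classification (the genus, in the example) is real information worth
  preserving; the placeholder names a definite node with a unique parent,
  so the repaired profile is a well-formed tree. Consecutive gaps share
  the same nearest ancestor and therefore the same placeholder at
  successive ranks, which is still a single chain in the tree. A lineage
  whose *first* rank is a gap with classification below it gets the
  placeholder root `unclassified_root`.
* **truncate**: everything at or below the shallowest gap becomes
  `unclassified`. This is the conservative option for users who distrust
  resumed classifications; it discards the deeper names.

Both modes are total and idempotent, and `repair` followed by the strict
predicate is `TRUE` for every one of the $2^7$ classified/unclassified
patterns — this is tested exhaustively, not sampled.

## Rank collapsing

`collapse_table()` merges features sharing an identical lineage prefix
down to the chosen rank, summing counts. It requires strict lineages:
collapsing across an interior gap would pool unrelated taxa under one
`unclassified` label, so non-strict input is an error that points at
`repair_table()` rather than a silent repair. Sample totals are conserved
exactly — an invariant shared by every writer, since reformatting must
never change the data.

## Rarefaction

Unequal sequencing effort is normalized by subsampling each sample's
counts without replacement to a user-chosen depth, with 1–10 iterations
(the cap is a protocol constant; an eleventh iteration is rejected, not
clamped). Choices the interface leaves open were resolved as follows:

* **Averaging across iterations.** Iterations are averaged per feature and
  rounded half-up to integers, giving one output table. Averaging is the
  variance-reduction reading of repeated rarefaction and keeps the output
  type identical to the input's; keeping iterations separate would push
  the aggregation burden onto every downstream tool.
* **Rounding.** Half-up (`floor(x + 0.5)`) rather than banker's rounding:
  deterministic, direction-consistent, and exact for the
  single-iteration case (integers pass through untouched, so every
  column sums to exactly the depth when `iterations = 1`).
* **Features averaging to zero are dropped**, as all-zero rows carry no
  signal and inflate downstream sparsity.
* **Samples below depth are dropped with a warning**, not an error —
  matching common practice; a depth exceeding *every* sample total is an
  error because the result would be empty.
* **Determinism.** One seed governs the whole operation; the same
  (table, depth, iterations, seed) reproduces bit-identical output. The
  RNG state of the calling session is saved and restored.

## Size-constrained co-chunking

The functional-inference upload path caps FASTA files at 10 MB. Records
are packed greedily in input order: a chunk closes when the next record
would push its serialized size past the cap. Greedy first-fit is chosen
over bin-packing deliberately: it is deterministic, order-preserving, and
the chunk count only matters to the user uploading files, not to
correctness. Sizes are measured on the package's canonical FASTA
serialization (`>id`, sequence on one line, LF endings) using
$2^{20}$-byte megabytes — these are exactly the bytes written to disk, and
hence exactly what the server sees. The limit is enforced on the FASTA
only; the paired abundance CSV gets a warning if it happens to exceed the
cap, since the cap is documented for the sequence file. A single record
larger than the cap is an unrecoverable error naming the record. Single
chunks are written as `piphillinseqs.fasta`/`piphillinotu.csv`; multiple
chunks follow the numbered convention `piphillinseqs<i>.fasta` /
`piphillinotu.csv<i>.csv` expected by the established upload workflow
(the doubled extension is intentional fidelity to that convention).

## Metadata validation

Validation never throws — it returns a report with four lists (IDs missing
from the table, missing from the metadata, containing disallowed
characters, duplicated), and `ok` iff all are empty. The allowed alphabet
is letters, digits and underscore; the ranacapa target additionally flags
periods explicitly, because that tool is the one that hard-fails on them.
Orchestrated runs abort on a failed report *before* any file is written:
partially populated run folders are worse than no folder.

## Export formats

All writers emit UTF-8, LF-terminated delimited text and are
byte-deterministic on the same input. Where a matching reader exists
(ranacapa-style, QIIME 2 export, SPF read as generic TSV), write-then-read
is cell-exact; this round-trip is part of the test suite. SPF hierarchy
columns are named `Level_1..Level_7` (STAMP accepts arbitrary hierarchy
names). The ranacapa writer emits raw counts, not relative abundances,
since the tool rarefies internally. Cytoscape edge lists hold one unique
(sample, label) pair per row with the count as weight; zero cells are
omitted and duplicate labels at a shallow rank are aggregated. Run folders
are `<base>/output/<YYYYMMDD-HHMMSSZ>/` in UTC with collision suffixes
`-1`, `-2`, ..., and a `manifest.tsv` (file, bytes, MD5) for
reproducibility checks; the timestamp is injectable so that identical runs
can be compared digest-for-digest.

## The inferred-functional leg

Result archives (`.tar`/`.tar.gz`) are scanned for members whose *content*
looks like an abundance table — a first column of `K#####` KO numbers or
5-digit pathway IDs — because archive layouts vary and filenames are not
contractual. Per-chunk tables merge by element-wise sum over the union of
IDs (checked associative and commutative in tests); mismatched sample sets
or mixed gene/pathway merges are errors.

The KEGG BRITE `.keg` file is parsed offline: `A`/`B`/`C` lines open
category levels, `D` lines carry `K##### symbol; description` entries
(HTML tags stripped, trailing `[EC:...]` brackets removed, the description
taken after the first semicolon). Offline-first is a deliberate trade: a
packaged or user-supplied hierarchy file makes annotation deterministic
and testable without network access, at the cost of the "always current"
property of live queries — users who need currency can supply a freshly
downloaded file through the same interface. A KO under several categories
uses the lexicographically first (A, B, C) path for its primary row — a
deterministic tie-break that gives STAMP the single parent it needs —
with the complete path list written to a sidecar file. KOs missing from
the hierarchy degrade to `unannotated` rather than erroring, and
annotation never modifies an abundance cell.

## The synthetic dataset generator

`generate_fixture()` is the package's test substrate and a convenient
demo source. It emulates: hierarchically consistent taxonomies (each
label embeds its parent's, so prefix equality means genuine shared
ancestry); independent per-rank unclassified gaps with probability
`gap_prob` (0.2 by default — gappy enough that repair matters, low enough
that deep structure survives); Poisson counts with mean 30 per cell
(12 samples × 100 features by default, giving ~3,000-count samples, small
but in the shape of real shallow surveys); uniform random DNA sequences;
and, on request, a `.keg` hierarchy, a result archive, a `.qza` container
and metadata with a deliberately invalid sample ID. Generation is
deterministic in the seed down to archive bytes (member timestamps are
pinned).

What it does **not** emulate — and what passing tests therefore do not
show about real data: compositional correlation between taxa, realistic
abundance skew (log-normal tails, zero inflation), chimeras or
contamination, phylogenetic signal in the sequences, or provider-specific
header quirks beyond the frozen layouts. The per-rank provider dialect in
particular has no public schema; the generator freezes one plausible
layout (a taxon-path column plus per-sample counts), and the
reconstruction of lineages from name-only per-rank files — by exact
count-vector matching, with ambiguous ranks left unclassified — is a
documented heuristic, not a claim about any provider's actual linkage.

## Numerical and degenerate-input choices

* Delimiter sniffing: tab preferred, comma fallback, decided per file from
  the header line (the supported dialects mix both without declaring).
* Empty tables round-trip as header-only files; empty FASTA parses to an
  empty sequence set.
* Feature IDs for the per-rank dialect (which has none) are synthesized as
  `F` + zero-padded row index, deterministic in input order.
* `.qza` support is read-only extraction of the packaged text export; no
  artifact provenance semantics.
* External alignment/tree building (MAFFT, FastTree) is an adapter: absent
  tools skip the step with a warning, present tools must return a tree
  whose leaves are exactly the sequence IDs.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale defaults: exhaustive
$2^7$-pattern repair checks; 50 × 8 randomized tables for round-trip and
conservation properties; a ~30 MB generated sequence set (308 records of
100 KB) for the upload-chunking bound; and 100 × 12 end-to-end runs,
executed twice to assert digest-identical manifests. The full suite runs
in well under a minute on one CPU.

## Known limitations

* Per-rank provider deliveries with layouts other than the frozen fixture
  dialect may need manual column renaming before ingest.
* BIOM-HDF5 inputs are out of scope (text exports only), as are raw-read
  processing, diversity statistics (delegated to the downstream tools) and
  normalizations other than rarefaction.
* The functional leg annotates against whatever `.keg` snapshot it is
  given; stale snapshots yield stale annotations.
* Pathway-level annotation matches C-level categories by 5-digit number
  and is best-effort; unmatched pathways pass through as `unannotated`.
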
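# Canonical in-memory model shared by every other module. No I/O here.
#
# A lineage is a character vector of length 7 where NA marks an unclassified
# rank; classified entries hold the bare taxon name (rank prefixes such as
# "g__" are stripped on ingest). A feature table stores a feature x sample
# integer count matrix plus one lineage per feature.

#' Taxonomic rank ladders
#'
#' Seven ordered ranks, most to least inclusive. Two spellings are in common
#' use among upstream pipelines: provider-style per-rank tables label the top
#' rank *kingdom*, ASV pipelines label it *domain*. Index semantics are
#' identical; only the label of rank 1 differs.
#'
#' @param style `"mrdna"` (kingdom...species) or `"anacapa"`
#'   (domain...species).
#' @return Character vector of length 7.
#' @examples
#' rank_ladder("anacapa")
#' @export
rank_ladder <- function(style = c("mrdna", "anacapa")) {
  style <- match.arg(style)
  first <- if (style == "mrdna") "kingdom" else "domain"
  c(first, "phylum", "class", "order", "family", "genus", "species")
}

#' Number of ranks in the ladder
#' @keywords internal
N_RANKS <- 7L

# Tokens treated as "unclassified" on ingest. Blank cells must be recognized
# here: downstream profile tools reject blank taxon labels outright.
.unclassified_tokens <- c("unclassified", "unknown", "na", "")

#' Is a taxon label an unclassified marker?
#'
#' Case-insensitive match of `"unclassified"`, `"unknown"`, `"na"`, the empty
#' string, and bare rank-prefix tokens such as `"g__"` or `"s__"`.
#'
#' @param x character vector of raw labels.
#' @return logical vector.
#' @export
is_unclassified_label <- function(x) {
  x <- trimws(as.character(x))
  is.na(x) |
    tolower(x) %in% .unclassified_tokens |
    grepl("^[A-Za-z]__$", x)
}

#' Build a canonical lineage from raw labels
#'
#' Normalizes a vector of taxon labels to the fixed 7-rank representation:
#' unclassified markers (see [is_unclassified_label()]) become `NA`, rank
#' prefixes (`k__`, `p__`, ...) are stripped, missing trailing ranks are
#' right-padded with `NA`, and more than 7 entries (e.g. subspecies) are
#' truncated with a warning.
#'
#' @param labels character vector of taxon labels, shallowest first.
#' @return character vector of length 7 with `NA` for unclassified ranks.
#' @examples
#' lineage(c("Bacteria", "Proteobacteria"))
#' @export
lineage <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) > N_RANKS) {
    warning("lineage has ", length(labels), " segments; truncating to ",
            N_RANKS, call. = FALSE)
    labels <- labels[seq_len(N_RANKS)]
  }
  out <- rep(NA_character_, N_RANKS)
  if (length(labels)) {
    cleaned <- trimws(labels)
    cleaned <- sub("^[A-Za-z]__", "", cleaned)
    cleaned <- trimws(cleaned)
    uncls <- is_unclassified_label(labels)
    out[seq_along(labels)] <- ifelse(uncls, NA_character_, cleaned)
  }
  out
}

#' Strict-hierarchy predicate
#'
#' A lineage is *strict* when no classified rank sits deeper than an
#' unclassified one, i.e. the unclassified ranks form a (possibly empty)
#' suffix. Profile tools that model taxonomy as a tree require this: a
#' classified genus under an unclassified family has no well-defined parent.
#'
#' @param x a lineage (length-7 character vector, `NA` = unclassified) or a
#'   feature x 7 character matrix of lineages.
#' @return logical; one value per lineage.
#' @examples
#' lineage_is_strict(lineage(c("Bacteria", "Proteobacteria",
#'   "Gammaproteobacteria", "Enterobacteriales", NA, "Escherichia", NA)))
#' @export
lineage_is_strict <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, lineage_is_strict))
  stopifnot(length(x) == N_RANKS)
  cls <- which(!is.na(x))
  unc <- which(is.na(x))
  length(cls) == 0L || length(unc) == 0L || max(cls) < min(unc)
}

#' Construct a feature table
#'
#' The central container: a feature (OTU/ASV) x sample matrix of non-negative
#' integer counts, each feature carrying a 7-rank lineage.
#'
#' @param counts numeric matrix (features x samples) with unique non-empty
#'   rownames (feature IDs) and colnames (sample IDs). Values must be
#'   non-negative integers; fractional values (e.g. percentage-style provider
#'   tables) are rejected rather than silently rounded.
#' @param lineages character matrix (features x 7), `NA` marking unclassified
#'   ranks; or `NULL` for all-unclassified lineages.
#' @param rank_style which rank ladder labels apply, see [rank_ladder()].
#' @return An object of class `feature_table`.
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 3L), 2, 2,
#'             dimnames = list(c("F1", "F2"), c("S1", "S2")))
#' feature_table(m)
#' @export
feature_table <- function(counts, lineages = NULL,
                          rank_style = c("anacapa", "mrdna")) {
  rank_style <- match.arg(rank_style)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have feature IDs as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (length(counts)) {
    if (any(is.na(counts)) || any(counts < 0))
      stop("counts must be non-negative and non-missing")
    if (any(counts != floor(counts)))
      stop("counts must be integers; fractional values found ",
           "(percentage-style tables are not accepted)")
  }
  storage.mode(counts) <- "integer"
  if (is.null(lineages)) {
    lineages <- matrix(NA_character_, nrow(counts), N_RANKS)
  } else {
    lineages <- as.matrix(lineages)
    if (nrow(lineages) != nrow(counts) || ncol(lineages) != N_RANKS)
      stop("lineages must be a ", nrow(counts), " x ", N_RANKS, " matrix")
  }
  rownames(lineages) <- rownames(counts)
  colnames(lineages) <- rank_ladder(rank_style)
  structure(list(counts = counts, lineages = lineages,
                 rank_style = rank_style),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples (", x$rank_style, " rank ladder)\n", sep = "")
  cat("  total count:", sum(x$counts), "\n")
  strict <- if (nrow(x$counts)) sum(lineage_is_strict(x$lineages)) else 0L
  cat("  strict lineages:", strict, "/", nrow(x$counts), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Feature and sample accessors
#' @param table a `feature_table`.
#' @return character vector of IDs.
#' @export
feature_ids <- function(table) rownames(table$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(table) UseMethod("sample_ids")

#' @export
sample_ids.feature_table <- function(table) colnames(table$counts)

#' @export
sample_ids.functional_table <- function(table) colnames(table$counts)

#' Per-sample sequencing depth
#'
#' Column sums of the count matrix. Conserved by all reformatting/export
#' operations; changed only by rarefaction and subsetting.
#'
#' @param table a `feature_table`.
#' @return named integer vector, one total per sample.
#' @export
sample_totals <- function(table) colSums(table$counts)

#' Construct sample metadata
#'
#' Per-sample attribute records keyed by sample ID.
#'
#' @param df data.frame whose first column (or a column named `sample_id`)
#'   holds sample IDs; remaining columns are attributes.
#' @return object of class `sample_metadata` (a data.frame with a guaranteed
#'   `sample_id` first column).
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1L]
  ids <- as.character(df[[idcol]])
  if (any(is.na(ids) | ids == ""))
    stop("empty sample ID in metadata")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(names(df) == "" | is.na(names(df))))
    stop("metadata has empty column names")
  df <- df[, c(idcol, setdiff(names(df), idcol)), drop = FALSE]
  names(df)[1L] <- "sample_id"
  df$sample_id <- ids
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a sequence set
#'
#' Ordered FASTA-like records. Sequences are unrestricted text; IDs are
#' unique.
#'
#' @param sequences named character vector (names = record IDs).
#' @return object of class `sequence_set`.
#' @export
sequence_set <- function(sequences) {
  sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) && (is.null(names(sequences)) ||
                            any(names(sequences) == "")))
    stop("every sequence needs a non-empty ID")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence IDs: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  structure(sequences, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x), "records,",
      sum(fasta_record_bytes(x)), "serialized bytes\n")
  invisible(x)
}

#' Serialized FASTA byte size per record
#'
#' Byte length of each record in the package's canonical serialization:
#' `">id\n<sequence>\n"` (header line, sequence on one line, LF endings).
#' Upload size limits are enforced against these bytes.
#'
#' @param seqs a `sequence_set`.
#' @return integer vector of byte counts, one per record.
#' @export
fasta_record_bytes <- function(seqs) {
  if (!length(seqs)) return(integer(0))
  nchar(names(seqs), type = "bytes") + nchar(unclass(seqs), type = "bytes") + 3L
}

#' Construct a functional abundance table
#'
#' KO (gene) or pathway x sample abundance matrix as returned by functional
#' inference servers. Gene tables have IDs matching `K` + 5 digits; anything
#' else is treated as a pathway table.
#'
#' @param counts non-negative numeric matrix with KO/pathway rownames and
#'   sample colnames.
#' @param tag `"gene"`, `"pathway"`, or `NULL` to infer from the IDs.
#' @return object of class `functional_table`.
#' @export
functional_table <- function(counts, tag = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have KO/pathway IDs as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate KO/pathway IDs")
  if (length(counts) && (any(is.na(counts)) || any(counts < 0)))
    stop("abundances must be non-negative and non-missing")
  storage.mode(counts) <- "double"
  is_gene <- grepl("^K[0-9]{5}$", rownames(counts))
  if (is.null(tag)) {
    tag <- if (nrow(counts) == 0 || all(is_gene)) "gene" else "pathway"
  }
  tag <- match.arg(tag, c("gene", "pathway"))
  if (tag == "gene" && nrow(counts) > 0 && !all(is_gene))
    stop("gene table has non-KO IDs: ",
         paste(utils::head(rownames(counts)[!is_gene], 5), collapse = ", "))
  structure(list(counts = counts, tag = tag), class = "functional_table")
}

#' @export
print.functional_table <- function(x, ...) {
  cat("functional_table (", x$tag, "): ", nrow(x$counts), " IDs x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Construct a BRITE hierarchy
#'
#' Maps each KEGG Orthology (KO) identifier to a description and one or more
#' (levelA, levelB, levelC) category paths of the KEGG BRITE functional
#' hierarchy.
#'
#' @param paths data.frame with columns `ko`, `levelA`, `levelB`, `levelC`;
#'   one row per (KO, path).
#' @param descriptions named character vector, KO -> description.
#' @return object of class `brite_hierarchy`.
#' @export
brite_hierarchy <- function(paths, descriptions) {
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  stopifnot(all(c("ko", "levelA", "levelB", "levelC") %in% names(paths)))
  missing_desc <- setdiff(unique(paths$ko), names(descriptions))
  if (length(missing_desc))
    stop("KOs without description: ", paste(missing_desc, collapse = ", "))
  if (any(descriptions == "" | is.na(descriptions)))
    stop("empty KO description")
  structure(list(paths = paths, descriptions = descriptions),
            class = "brite_hierarchy")
}

#' @export
print.brite_hierarchy <- function(x, ...) {
  cat("brite_hierarchy:", length(x$descriptions), "KOs,",
      nrow(x$paths), "category paths\n")
  invisible(x)
}

# Render a lineage (or lineage matrix) for writers: NA -> "unclassified".
render_lineage <- function(x) {
  x[is.na(x)] <- "unclassified"
  x
}
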
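# Readers for the three upstream taxonomic-profile dialects, FASTA, and
# functional-inference result archives. Everything lands in the canonical
# types from profile_model.R.

# split on ";" keeping trailing empty segments (strsplit drops them)
split_lineage_string <- function(x) {
  parts <- strsplit(paste0(x, "\x01"), ";", fixed = TRUE)[[1L]]
  n <- length(parts)
  parts[n] <- sub("\x01$", "", parts[n])
  parts
}

# Coerce the sample columns of a raw data.frame to integer counts, with
# cell-coordinate errors for non-numeric or fractional values.
parse_count_matrix <- function(df, sample_cols, path) {
  m <- matrix(0L, nrow(df), length(sample_cols),
              dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    col <- df[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(as.character(col)) != "")
    if (length(bad))
      stop("non-numeric count in ", basename(path), " at row ", bad[1L],
           ", column '", sample_cols[j], "': '", col[bad[1L]], "'")
    num[is.na(num)] <- 0
    if (any(num != floor(num)))
      stop("fractional count in ", basename(path), " at row ",
           which(num != floor(num))[1L], ", column '", sample_cols[j],
           "' (percentage-style tables are not accepted)")
    m[, j] <- as.integer(num)
  }
  m
}

#' Read provider-style per-rank OTU tables
#'
#' Some sequencing providers deliver one abundance table per taxonomic rank
#' (kingdom, phylum, ..., species), each with a taxon-name column followed by
#' per-sample count columns. This reader takes the deepest provided rank file
#' as the feature set and reconstructs each feature's lineage: if the taxon
#' column holds semicolon-joined paths those are used directly; otherwise
#' ancestors are recovered from the shallower rank files by exact count-vector
#' match (a shallower taxon whose per-sample counts equal the feature's own
#' must contain exactly that feature), with ambiguous ranks left unclassified.
#'
#' @param per_rank_files named character vector or list mapping rank names
#'   (any subset of the ladder, see [rank_ladder()]) to file paths.
#' @param rank_style rank ladder spelling, default `"mrdna"`.
#' @return A [feature_table()] at the deepest provided rank. Feature IDs are
#'   synthesized as `F` + zero-padded row index (the dialect has none).
#' @export
read_mrdna <- function(per_rank_files, rank_style = "mrdna") {
  ladder <- rank_ladder(rank_style)
  ranks <- names(per_rank_files)
  unknown <- setdiff(ranks, ladder)
  if (length(unknown))
    stop("unknown rank names: ", paste(unknown, collapse = ", "))
  idx <- match(ranks, ladder)
  ord <- order(idx)
  ranks <- ranks[ord]
  idx <- idx[ord]
  paths <- unlist(per_rank_files, use.names = FALSE)[ord]

  tables <- lapply(paths, read_delim_table)
  names(tables) <- ranks
  deepest <- tables[[length(tables)]]
  deepest_path <- paths[length(paths)]
  sample_cols <- names(deepest)[-1L]
  for (k in seq_along(tables)) {
    if (!identical(names(tables[[k]])[-1L], sample_cols))
      stop("inconsistent sample columns across rank files: ",
           basename(paths[k]), " does not match ", basename(deepest_path))
  }

  n <- nrow(deepest)
  fid <- sprintf(paste0("F%0", max(3L, nchar(n)), "d"), seq_len(n))
  counts <- parse_count_matrix(deepest, sample_cols, deepest_path)
  rownames(counts) <- fid

  taxa <- as.character(deepest[[1L]])
  lin <- matrix(NA_character_, n, N_RANKS)
  if (n > 0) {
    if (any(grepl(";", taxa, fixed = TRUE))) {
      # taxon column carries full paths
      for (i in seq_len(n)) lin[i, ] <- lineage(split_lineage_string(taxa[i]))
    } else {
      deep_idx <- idx[length(idx)]
      for (i in seq_len(n)) {
        if (!is_unclassified_label(taxa[i]))
          lin[i, deep_idx] <- sub("^[A-Za-z]__", "", trimws(taxa[i]))
      }
      # recover ancestors from shallower rank files by count-vector identity
      if (length(tables) > 1L) {
        for (k in seq_len(length(tables) - 1L)) {
          tk <- tables[[k]]
          ck <- parse_count_matrix(tk, sample_cols, paths[k])
          keys <- apply(ck, 1L, paste, collapse = "\r")
          feat_keys <- apply(counts, 1L, paste, collapse = "\r")
          for (i in seq_len(n)) {
            hits <- which(keys == feat_keys[i])
            if (length(hits) == 1L && !is_unclassified_label(tk[[1L]][hits]))
              lin[i, idx[k]] <- sub("^[A-Za-z]__", "",
                                    trimws(as.character(tk[[1L]][hits])))
          }
        }
      }
    }
  }
  feature_table(counts, lin, rank_style = rank_style)
}

#' Read an ASV table with a semicolon lineage column
#'
#' The ASV-pipeline dialect: one delimited-text table with an ASV-ID column,
#' a single `sum.taxonomy` column holding the full semicolon-joined lineage,
#' and one count column per sample. Blank lineage segments become
#' unclassified; lineages longer than 7 ranks are truncated with a warning.
#'
#' @param path delimited-text file (tab or comma separated).
#' @return A [feature_table()] with ASV IDs preserved as feature IDs.
#' @export
read_anacapa <- function(path) {
  df <- read_delim_table(path)
  taxcol <- which(names(df) == "sum.taxonomy")
  if (!length(taxcol))
    taxcol <- grep("taxonomy", names(df), ignore.case = TRUE)
  if (!length(taxcol))
    stop("no 'sum.taxonomy' lineage column found in ", basename(path))
  taxcol <- taxcol[1L]
  sample_cols <- names(df)[-c(1L, taxcol)]
  if (!length(sample_cols))
    stop("no sample count columns found in ", basename(path))
  counts <- parse_count_matrix(df, sample_cols, path)
  rownames(counts) <- as.character(df[[1L]])
  lin <- matrix(NA_character_, nrow(df), N_RANKS)
  tax <- as.character(df[[taxcol]])
  for (i in seq_len(nrow(df))) {
    if (!is.na(tax[i]) && nzchar(tax[i]))
      lin[i, ] <- lineage(split_lineage_string(tax[i]))
  }
  feature_table(counts, lin, rank_style = "anacapa")
}

# locate + read the text feature-table export inside a .qza zip container
extract_qza_table <- function(path) {
  members <- utils::unzip(path, list = TRUE)$Name
  candidates <- members[grepl("/data/", members) &
                          grepl("\\.(tsv|txt)$", members)]
  exdir <- tempfile("qza")
  dir.create(exdir)
  for (mem in candidates) {
    utils::unzip(path, files = mem, exdir = exdir)
    f <- file.path(exdir, mem)
    first <- readLines(f, n = 2L, warn = FALSE)
    if (any(startsWith(first, "#OTU ID"))) return(f)
  }
  stop("no feature-table export found in ", basename(path),
       "; archive members: ", paste(members, collapse = ", "))
}

#' Read a QIIME 2 feature-table export or .qza artifact
#'
#' Accepts either (a) a delimited-text feature-table export whose header line
#' starts with `#OTU ID`, or (b) a `.qza` zip container, from which the text
#' export under the artifact's internal `data/` directory is extracted.
#' Lineages come from a separate taxonomy mapping file (feature ID, taxon
#' string, optional confidence column which is ignored); without one, all
#' lineages are unclassified and a warning is recorded.
#'
#' @param path feature-table export or `.qza` file.
#' @param taxonomy optional taxonomy mapping file path.
#' @return A [feature_table()].
#' @export
read_qiime2 <- function(path, taxonomy = NULL) {
  f <- if (grepl("\\.qza$", path, ignore.case = TRUE))
    extract_qza_table(path) else path
  lines <- readLines(f, warn = FALSE)
  hdr <- which(startsWith(lines, "#OTU ID"))
  if (!length(hdr))
    stop("no '#OTU ID' header line found in ", basename(path))
  sep <- if (grepl("\t", lines[hdr[1L]])) "\t" else ","
  df <- utils::read.table(text = lines[hdr[1L]:length(lines)], sep = sep,
                          header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  sample_cols <- names(df)[-1L]
  counts <- parse_count_matrix(df, sample_cols, path)
  rownames(counts) <- as.character(df[[1L]])

  lin <- matrix(NA_character_, nrow(df), N_RANKS)
  if (is.null(taxonomy)) {
    warning("no taxonomy mapping supplied for ", basename(path),
            "; all lineages unclassified", call. = FALSE)
  } else {
    tx <- read_delim_table(taxonomy)
    lookup <- stats::setNames(as.character(tx[[2L]]), as.character(tx[[1L]]))
    for (i in seq_len(nrow(df))) {
      t <- lookup[rownames(counts)[i]]
      if (!is.na(t) && nzchar(t))
        lin[i, ] <- lineage(trimws(split_lineage_string(t)))
    }
  }
  feature_table(counts, lin, rank_style = "anacapa")
}

#' Read FASTA into a sequence set
#'
#' Record IDs are the header token before the first whitespace; wrapped
#' sequence lines are concatenated. Duplicate IDs are an error.
#'
#' @param path FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(sequence_set(character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA ", basename(path), ": ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequence_set(stats::setNames(as.character(set), ids))
}

#' Write a sequence set as FASTA
#'
#' Canonical serialization: `>id` header, sequence on a single line, LF line
#' endings. [fasta_record_bytes()] measures exactly these bytes.
#'
#' @param seqs a [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", unclass(seqs)), con,
               sep = "\n", useBytes = TRUE)
  invisible(path)
}

# does a parsed member look like a KO-gene or pathway abundance table?
classify_functional_ids <- function(ids) {
  if (!length(ids)) return(NA_character_)
  if (all(grepl("^K[0-9]{5}$", ids))) return("gene")
  if (all(grepl("^(ko|map|path:ko|path:map)?[0-9]{5}$", ids))) return("pathway")
  NA_character_
}

#' Read a functional-inference result archive
#'
#' Functional inference servers return `.tar` (optionally gzip-compressed)
#' archives holding KO and/or pathway abundance tables (IDs in rows, samples
#' in columns). Members are recognized by content shape — a first column of
#' KO numbers (`K` + 5 digits) or pathway IDs — not by filename.
#'
#' @param path `.tar` or `.tar.gz` archive.
#' @return list of [functional_table()], one per recognized member, each
#'   tagged `"gene"` or `"pathway"`.
#' @export
read_piphillin_tar <- function(path) {
  exdir <- tempfile("piph")
  dir.create(exdir)
  utils::untar(path, exdir = exdir)
  members <- list.files(exdir, recursive = TRUE, full.names = TRUE)
  members <- members[file.info(members)$isdir == FALSE]
  out <- list()
  for (f in members) {
    df <- tryCatch(read_delim_table(f), error = function(e) NULL)
    if (is.null(df) || ncol(df) < 2L || nrow(df) == 0L) next
    ids <- as.character(df[[1L]])
    tag <- classify_functional_ids(ids)
    if (is.na(tag)) next
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    out[[length(out) + 1L]] <- functional_table(m, tag = tag)
  }
  if (!length(out))
    stop("no KO/pathway abundance table recognized in ", basename(path),
         "; members: ",
         paste(list.files(exdir, recursive = TRUE), collapse = ", "))
  out
}
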
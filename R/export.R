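# Writers for every downstream analysis/visualization target, plus the
# timestamped run-folder layout. All output is UTF-8 with LF line endings
# and byte-identical across repeated runs on the same input.

first_strict_violation <- function(lin) {
  # rank index of the shallowest unclassified entry with a classified entry
  # below it, or NA if strict
  unc <- which(is.na(lin))
  cls <- which(!is.na(lin))
  if (!length(unc) || !length(cls) || max(cls) < min(unc)) return(NA_integer_)
  min(unc[unc < max(cls)])
}

#' Write a STAMP profile (SPF)
#'
#' Tab-separated profile: seven hierarchy columns (`Level_1`..`Level_7`)
#' followed by one count column per sample, one row per feature. STAMP
#' enforces a strict hierarchy and rejects blank taxon labels, so this
#' writer refuses non-strict input rather than silently repairing it — call
#' [repair_table()] first. Unclassified trailing ranks render as the literal
#' label `unclassified`.
#'
#' @param table a [feature_table()] with strict lineages.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spf <- function(table, path) {
  strict <- if (nrow(table$counts)) lineage_is_strict(table$lineages) else
    logical(0)
  if (any(!strict)) {
    bad <- which(!strict)[1L]
    rank <- first_strict_violation(table$lineages[bad, ])
    stop("feature '", feature_ids(table)[bad], "' is classified below an ",
         "unclassified ", rank_ladder(table$rank_style)[rank],
         "; STAMP rejects such profiles - repair the table first")
  }
  lin <- render_lineage(table$lineages)
  colnames(lin) <- paste0("Level_", seq_len(N_RANKS))
  df <- data.frame(lin, table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_lf(df, path)
  invisible(path)
}

#' Write a Cytoscape edge list
#'
#' Network input: one row per (sample, node) pair with the abundance as edge
#' weight. Node labels are the lineage label at `rank` for taxonomic tables
#' (duplicate labels at that rank are aggregated by summing) or the row IDs
#' for functional tables. Zero-weight pairs are omitted; (source, target)
#' pairs are unique.
#'
#' @param x a [feature_table()] (strict lineages required) or
#'   [functional_table()].
#' @param path output file.
#' @param rank label level for taxonomic input (name or index, default
#'   species); ignored for functional tables.
#' @return `path`, invisibly.
#' @export
write_cytoscape <- function(x, path, rank = N_RANKS) {
  if (inherits(x, "feature_table")) {
    ladder <- rank_ladder(x$rank_style)
    idx <- if (is.numeric(rank)) as.integer(rank) else match(rank, ladder)
    if (is.na(idx) || idx < 1L || idx > N_RANKS) stop("unknown rank: ", rank)
    if (nrow(x$counts) && !all(lineage_is_strict(x$lineages)))
      stop("non-strict lineages; repair the table first")
    labels <- render_lineage(x$lineages[, idx])
    counts <- x$counts
  } else if (inherits(x, "functional_table")) {
    labels <- rownames(x$counts)
    counts <- x$counts
  } else stop("x must be a feature_table or functional_table")

  rows <- list()
  for (j in seq_len(ncol(counts))) {
    w <- rowsum(counts[, j], labels, reorder = FALSE)
    nz <- which(w[, 1L] != 0)
    if (length(nz))
      rows[[length(rows) + 1L]] <- data.frame(
        source = colnames(counts)[j], target = rownames(w)[nz],
        weight = w[nz, 1L], stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               weight = numeric(0))
  rownames(df) <- NULL
  write_tsv_lf(df, path)
  invisible(path)
}

#' Write ranacapa input files
#'
#' ranacapa (a Shiny biodiversity explorer built around the ASV-table
#' convention) takes a taxonomy table with an ASV-ID column, a single
#' semicolon-joined `sum.taxonomy` lineage column and per-sample counts,
#' plus a matching metadata file. Sample IDs are validated first: ranacapa
#' accepts underscores but not periods.
#'
#' @param table a [feature_table()].
#' @param meta a [sample_metadata()] covering the table's samples.
#' @param dir output directory (created if needed).
#' @return character vector of the two paths written, invisibly.
#' @export
write_ranacapa <- function(table, meta, dir) {
  report <- validate_samples(meta, table, target = "ranacapa")
  if (!report$ok) {
    e <- simpleError(paste0(
      "sample validation failed for ranacapa: ",
      paste(c(
        if (length(report$bad_character_ids))
          paste0("bad characters in [",
                 paste(report$bad_character_ids, collapse = ", "), "]"),
        if (length(report$missing_in_table))
          paste0("missing in table [",
                 paste(report$missing_in_table, collapse = ", "), "]"),
        if (length(report$missing_in_metadata))
          paste0("missing in metadata [",
                 paste(report$missing_in_metadata, collapse = ", "), "]"),
        if (length(report$duplicates))
          paste0("duplicates [",
                 paste(report$duplicates, collapse = ", "), "]")),
        collapse = "; ")))
    e$report <- report
    class(e) <- c("taxbridge_validation_error", class(e))
    stop(e)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- apply(render_lineage(table$lineages), 1L, paste, collapse = ";")
  df <- data.frame(ASV_ID = feature_ids(table),
                   sum.taxonomy = unname(tax), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(table$counts) == 0L)
    df <- data.frame(ASV_ID = character(0), sum.taxonomy = character(0),
                     stats::setNames(as.data.frame(
                       matrix(integer(0), 0, ncol(table$counts))),
                       sample_ids(table)),
                     check.names = FALSE)
  tab_path <- file.path(dir, "ranacapa_taxonomy.tsv")
  meta_path <- file.path(dir, "ranacapa_metadata.tsv")
  write_tsv_lf(df, tab_path)
  write_tsv_lf(as.data.frame(meta), meta_path)
  invisible(c(tab_path, meta_path))
}

#' Write QIIME 2 import files
#'
#' Emits the delimited-text trio QIIME 2's importers accept: a feature table
#' with a leading `#OTU ID` header, a metadata file with a `sample-id`
#' leading column, a taxonomy mapping (feature -> semicolon lineage), and
#' optionally a newick tree copied verbatim (after checking its leaves are a
#' subset of the feature IDs).
#'
#' @param table a [feature_table()].
#' @param meta a [sample_metadata()].
#' @param dir output directory.
#' @param tree optional newick string (or `NULL`).
#' @return character vector of the paths written, invisibly.
#' @export
write_qiime2_inputs <- function(table, meta, dir, tree = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ft <- data.frame(feature_ids(table), table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(ft)[1L] <- "#OTU ID"
  ft_path <- file.path(dir, "feature-table.tsv")
  write_tsv_lf(ft, ft_path)

  tax <- data.frame(
    feature_ids(table),
    apply(render_lineage(table$lineages), 1L, paste, collapse = ";"),
    stringsAsFactors = FALSE)
  names(tax) <- c("Feature ID", "Taxon")
  tax_path <- file.path(dir, "taxonomy.tsv")
  write_tsv_lf(tax, tax_path)

  md <- as.data.frame(meta)
  names(md)[1L] <- "sample-id"
  md_path <- file.path(dir, "metadata.tsv")
  write_tsv_lf(md, md_path)

  paths <- c(ft_path, tax_path, md_path)
  if (!is.null(tree)) {
    phy <- ape::read.tree(text = tree)
    extras <- setdiff(phy$tip.label, feature_ids(table))
    if (length(extras))
      stop("tree leaves not among feature IDs: ",
           paste(extras, collapse = ", "))
    tree_path <- file.path(dir, "tree.nwk")
    write_lines_lf(tree, tree_path)
    paths <- c(paths, tree_path)
  }
  invisible(paths)
}

#' Write a long-format table for spreadsheet pivot analysis
#'
#' One row per (sample, feature) pair with nonzero count: columns
#' `SampleID`, the 7 rank labels, `Count`. Ready for pivot tables
#' summarizing community profiles at any taxonomic level.
#'
#' @param table a [feature_table()].
#' @param path output file.
#' @param rank optional rank to collapse to before writing (see
#'   [collapse_table()]); `NULL` writes feature-level rows.
#' @return `path`, invisibly.
#' @export
write_excel_long <- function(table, path, rank = NULL) {
  if (!is.null(rank)) table <- collapse_table(table, rank)
  ladder <- rank_ladder(table$rank_style)
  lin <- render_lineage(table$lineages)
  rows <- list()
  for (j in seq_len(ncol(table$counts))) {
    nz <- which(table$counts[, j] != 0)
    if (length(nz)) {
      block <- data.frame(SampleID = sample_ids(table)[j],
                          lin[nz, , drop = FALSE],
                          Count = table$counts[nz, j],
                          check.names = FALSE, stringsAsFactors = FALSE)
      names(block)[2:8] <- ladder
      rows[[length(rows) + 1L]] <- block
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(character(0), 0, 9)),
                    c("SampleID", ladder, "Count"))
  rownames(df) <- NULL
  write_tsv_lf(df, path)
  invisible(path)
}

#' Write functional-inference upload files
#'
#' Splits the representative sequences and their abundance table into sets
#' respecting the inference server's 10 MB FASTA upload limit (see
#' [chunk_for_upload()]) and writes each set. A single chunk is written as
#' `piphillinseqs.fasta` + `piphillinotu.csv`; k > 1 chunks follow the
#' numbered convention `piphillinseqs<i>.fasta` + `piphillinotu.csv<i>.csv`.
#' The CSV's first column repeats the FASTA header IDs verbatim.
#'
#' @param seqs a [sequence_set()].
#' @param table the matching [feature_table()].
#' @param dir output directory.
#' @param max_bytes FASTA chunk cap, default 10 * 2^20.
#' @return character vector of paths written, invisibly.
#' @export
write_piphillin_inputs <- function(seqs, table, dir, max_bytes = 10 * 2^20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chunks <- chunk_for_upload(seqs, table, max_bytes = max_bytes)
  k <- length(chunks)
  paths <- character(0)
  for (i in seq_len(k)) {
    fa <- if (k == 1L) "piphillinseqs.fasta" else
      sprintf("piphillinseqs%d.fasta", i)
    cs <- if (k == 1L) "piphillinotu.csv" else
      sprintf("piphillinotu.csv%d.csv", i)
    fa_path <- file.path(dir, fa)
    cs_path <- file.path(dir, cs)
    write_fasta(chunks[[i]]$seqs, fa_path)
    tb <- chunks[[i]]$table
    df <- data.frame(OTU_ID = feature_ids(tb), tb$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_lf(df, cs_path, sep = ",")
    if (file.size(cs_path) > max_bytes)
      warning("abundance chunk ", cs, " exceeds ", max_bytes,
              " bytes; the upload limit applies to the FASTA", call. = FALSE)
    paths <- c(paths, fa_path, cs_path)
  }
  invisible(paths)
}

RUN_SUBDIRS <- c("excel", "stamp", "ranacapa", "cytoscape", "qiime2",
                 "piphillin", "functional")

#' Create a timestamped run folder
#'
#' Creates `<base>/output/<YYYYMMDD-HHMMSSZ>/` (UTC) holding one subfolder
#' per export target: excel, stamp, ranacapa, cytoscape, qiime2, piphillin,
#' functional. An existing folder is never overwritten; collisions get
#' suffixes `-1`, `-2`, ...
#'
#' @param base_dir base directory.
#' @param time POSIXct timestamp to use (defaults to now; injectable for
#'   reproducible layouts).
#' @return the run-folder path.
#' @export
make_run_folder <- function(base_dir, time = Sys.time()) {
  stamp <- format(time, "%Y%m%d-%H%M%SZ", tz = "UTC")
  root <- file.path(base_dir, "output")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  run <- file.path(root, stamp)
  i <- 0L
  while (dir.exists(run)) {
    i <- i + 1L
    run <- file.path(root, paste0(stamp, "-", i))
  }
  ok <- dir.create(run, recursive = TRUE)
  if (!ok) stop("cannot create run folder under ", base_dir)
  for (d in RUN_SUBDIRS) dir.create(file.path(run, d))
  run
}
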
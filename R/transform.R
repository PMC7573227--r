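# Validation, strict-hierarchy repair, rank collapsing, rarefaction, and
# size-constrained FASTA/abundance co-chunking.

#' Validate sample metadata against a feature table
#'
#' Checks that metadata and abundance table carry consistent sample
#' identifiers and that IDs use only characters the downstream target
#' accepts (letters, digits, underscore; ranacapa notably rejects periods).
#' Validation never throws: it returns a report.
#'
#' @param meta a [sample_metadata()].
#' @param table a [feature_table()].
#' @param target downstream tool name; `"ranacapa"` activates the
#'   period-rejection rule (periods are outside the allowed alphabet for
#'   every target, but ranacapa is the tool that hard-fails on them).
#' @return object of class `validation_report`: list with `ok`,
#'   `missing_in_table`, `missing_in_metadata`, `bad_character_ids`,
#'   `duplicates`. `ok` is `TRUE` iff all four lists are empty.
#' @export
validate_samples <- function(meta, table, target = "generic") {
  meta_ids <- as.character(meta$sample_id)
  table_ids <- sample_ids(table)
  all_ids <- unique(c(meta_ids, table_ids))
  bad <- all_ids[grepl("[^A-Za-z0-9_]", all_ids)]
  if (identical(target, "ranacapa"))
    bad <- unique(c(bad, all_ids[grepl(".", all_ids, fixed = TRUE)]))
  rep_ <- list(
    ok = FALSE,
    missing_in_table = setdiff(meta_ids, table_ids),
    missing_in_metadata = setdiff(table_ids, meta_ids),
    bad_character_ids = bad,
    duplicates = unique(c(meta_ids[duplicated(meta_ids)],
                          table_ids[duplicated(table_ids)])),
    target = target)
  rep_$ok <- !length(rep_$missing_in_table) &&
    !length(rep_$missing_in_metadata) &&
    !length(rep_$bad_character_ids) && !length(rep_$duplicates)
  structure(rep_, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report (target:", x$target, ") ok:", x$ok, "\n")
  for (f in c("missing_in_table", "missing_in_metadata",
              "bad_character_ids", "duplicates")) {
    if (length(x[[f]]))
      cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Repair a lineage to a strict hierarchy
#'
#' Downstream profile tools require that no rank be classified beneath an
#' unclassified one. Two repair modes:
#' \describe{
#'   \item{fill}{each *interior* unclassified rank (one with a classified
#'     rank somewhere below it) becomes the named placeholder
#'     `unclassified_<nearest classified ancestor>`, preserving the deeper
#'     classification; trailing unclassified ranks keep the literal label
#'     `unclassified`.}
#'   \item{truncate}{everything at or below the shallowest unclassified rank
#'     becomes `unclassified`, discarding any deeper classification.}
#' }
#' Either way the result passes [lineage_is_strict()] and no rank renders
#' blank.
#'
#' @param lin lineage vector (length 7, `NA` = unclassified) or a
#'   features x 7 lineage matrix.
#' @param mode `"fill"` (default) or `"truncate"`.
#' @return repaired lineage(s), same shape as the input.
#' @examples
#' x <- lineage(c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
#'                "Enterobacteriales", NA, "Escherichia", NA))
#' repair_lineage(x)            # family -> unclassified_Enterobacteriales
#' repair_lineage(x, "truncate") # genus Escherichia discarded
#' @export
repair_lineage <- function(lin, mode = c("fill", "truncate")) {
  mode <- match.arg(mode)
  if (is.matrix(lin)) {
    out <- t(apply(lin, 1L, repair_lineage, mode = mode))
    if (nrow(lin) == 0L) out <- lin
    dimnames(out) <- dimnames(lin)
    return(out)
  }
  stopifnot(length(lin) == N_RANKS)
  unc <- is.na(lin)
  if (!any(unc)) return(lin)
  if (mode == "truncate") {
    lin[seq(min(which(unc)), N_RANKS)] <- NA_character_
    return(lin)
  }
  # fill: interior gaps get a named placeholder from the nearest classified
  # ancestor; a leading gap (no ancestor) gets the bare placeholder root
  deepest_classified <- if (all(unc)) 0L else max(which(!unc))
  for (i in seq_len(N_RANKS)) {
    if (unc[i] && i < deepest_classified) {
      anc <- which(!unc[seq_len(i)])
      lin[i] <- if (length(anc))
        paste0("unclassified_", lin[max(anc)]) else "unclassified_root"
    }
  }
  lin
}

#' Repair every lineage in a feature table
#'
#' @param table a [feature_table()].
#' @param mode see [repair_lineage()].
#' @return the table with all lineages strict.
#' @export
repair_table <- function(table, mode = c("fill", "truncate")) {
  table$lineages <- repair_lineage(table$lineages, mode = match.arg(mode))
  table
}

#' Collapse a feature table at a taxonomic rank
#'
#' Features sharing an identical lineage prefix down to `rank` are merged by
#' summing their counts. Sample totals are unchanged. Lineages must already
#' be strict (see [repair_table()]); collapsing across an interior gap would
#' silently conflate unrelated taxa.
#'
#' @param table a [feature_table()] with strict lineages.
#' @param rank rank name (from the table's ladder) or index 1-7.
#' @return collapsed [feature_table()]; groups appear in first-occurrence
#'   order and feature IDs are the rank-level labels (made unique).
#' @export
collapse_table <- function(table, rank) {
  ladder <- rank_ladder(table$rank_style)
  idx <- if (is.numeric(rank)) as.integer(rank) else match(rank, ladder)
  if (is.na(idx) || idx < 1L || idx > N_RANKS)
    stop("unknown rank: ", rank)
  if (nrow(table$counts) == 0L) return(table)
  strict <- lineage_is_strict(table$lineages)
  if (!all(strict))
    stop("non-strict lineage at feature(s) ",
         paste(utils::head(feature_ids(table)[!strict], 5), collapse = ", "),
         "; repair the table first (see repair_table)")
  prefix <- table$lineages[, seq_len(idx), drop = FALSE]
  key <- apply(render_lineage(prefix), 1L, paste, collapse = ";")
  groups <- unique(key)
  counts <- matrix(0L, length(groups), ncol(table$counts),
                   dimnames = list(NULL, colnames(table$counts)))
  lin <- matrix(NA_character_, length(groups), N_RANKS)
  for (g in seq_along(groups)) {
    rows <- which(key == groups[g])
    counts[g, ] <- as.integer(colSums(table$counts[rows, , drop = FALSE]))
    lin[g, seq_len(idx)] <- table$lineages[rows[1L], seq_len(idx)]
  }
  labels <- render_lineage(lin[, idx])
  rownames(counts) <- make.unique(labels, sep = "_")
  feature_table(counts, lin, rank_style = table$rank_style)
}

#' Rarefy a feature table
#'
#' Normalizes unequal sequencing depth by subsampling each sample's counts
#' without replacement to a common `depth`. Samples whose total is below
#' `depth` are dropped with a warning. With `iterations > 1` the per-feature
#' counts are averaged over independent draws and rounded half-up; features
#' rounding to zero everywhere are dropped. Results are reproducible given
#' `(seed, depth, iterations)`.
#'
#' @param table a [feature_table()].
#' @param depth target depth per sample (>= 1).
#' @param iterations number of independent subsampling draws, 1-10.
#' @param seed integer RNG seed.
#' @return rarefied [feature_table()]; dropped sample IDs are attached as
#'   attribute `"dropped_samples"`.
#' @export
rarefy <- function(table, depth, iterations = 1L, seed = 1L) {
  if (length(iterations) != 1L || is.na(iterations) ||
      iterations != floor(iterations) || iterations < 1L || iterations > 10L)
    stop("iterations must be an integer between 1 and 10")
  if (length(depth) != 1L || is.na(depth) || depth < 1L ||
      depth != floor(depth))
    stop("depth must be a positive integer")
  totals <- sample_totals(table)
  keep <- totals >= depth
  if (!any(keep))
    stop("rarefaction depth ", depth, " exceeds every sample total (max ",
         if (length(totals)) max(totals) else 0, ")")
  dropped <- names(totals)[!keep]
  if (length(dropped))
    warning("dropping ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "), call. = FALSE)
  counts <- table$counts[, keep, drop = FALSE]
  acc <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      pool <- rep.int(seq_len(nrow(counts)), counts[, j])
      for (it in seq_len(iterations)) {
        drawn <- if (length(pool) == depth) pool else
          sample(pool, depth, replace = FALSE)
        acc[, j] <- acc[, j] + tabulate(drawn, nbins = nrow(counts))
      }
    }
  })
  out <- round_half_up(acc / iterations)
  storage.mode(out) <- "integer"
  keep_feat <- rowSums(out) > 0L
  res <- feature_table(out[keep_feat, , drop = FALSE],
                       table$lineages[keep_feat, , drop = FALSE],
                       rank_style = table$rank_style)
  attr(res, "dropped_samples") <- dropped
  res
}

#' Split sequences and their abundance table under an upload size limit
#'
#' Web inference servers cap uploaded FASTA size (10 MB for the supported
#' server). Records are packed greedily in input order: a chunk grows until
#' adding the next record would push its serialized FASTA past `max_bytes`.
#' Each chunk is paired with the sub-table of exactly its features (all
#' samples retained). Chunks partition the input: union = input, pairwise
#' disjoint, order preserved.
#'
#' @param seqs a [sequence_set()]; every table feature must have a record.
#' @param table a [feature_table()] whose feature IDs match `seqs` IDs.
#' @param max_bytes chunk size cap on serialized FASTA bytes
#'   (default 10 * 2^20, i.e. 10 MB).
#' @return list of `list(seqs = sequence_set, table = feature_table)` pairs.
#' @export
chunk_for_upload <- function(seqs, table, max_bytes = 10 * 2^20) {
  fids <- feature_ids(table)
  missing_seq <- setdiff(fids, names(seqs))
  if (length(missing_seq))
    stop("features without a sequence record: ",
         paste(utils::head(missing_seq, 10), collapse = ", "))
  seqs <- sequence_set(unclass(seqs)[fids])  # align order to the table
  sizes <- fasta_record_bytes(seqs)
  too_big <- which(sizes > max_bytes)
  if (length(too_big))
    stop("record exceeds max_bytes (", max_bytes, "): ",
         names(seqs)[too_big[1L]], " (", sizes[too_big[1L]], " bytes)")
  if (!length(seqs)) return(list(list(seqs = seqs, table = table)))

  chunk_id <- integer(length(seqs))
  cur <- 1L; acc <- 0
  for (i in seq_along(seqs)) {
    if (acc + sizes[i] > max_bytes && acc > 0) { cur <- cur + 1L; acc <- 0 }
    chunk_id[i] <- cur
    acc <- acc + sizes[i]
  }
  lapply(seq_len(cur), function(k) {
    rows <- which(chunk_id == k)
    list(seqs = sequence_set(unclass(seqs)[rows]),
         table = feature_table(table$counts[rows, , drop = FALSE],
                               table$lineages[rows, , drop = FALSE],
                               rank_style = table$rank_style))
  })
}
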
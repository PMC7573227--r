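# The inferred-function leg: merge chunked inference results, parse the
# KEGG BRITE hierarchy, annotate KO abundance tables, and export functional
# profiles.

#' Merge functional tables returned for separate upload chunks
#'
#' When the input was split to respect the upload size limit, the server
#' returns one abundance table per chunk. Merging is an element-wise sum
#' over the union of KO/pathway IDs (a KO can be predicted from features in
#' two chunks); an ID absent from a chunk contributes zero. All tables must
#' share the same sample set and the same gene/pathway tag.
#'
#' @param tables list of [functional_table()].
#' @return a single merged [functional_table()]; IDs in first-appearance
#'   order, samples in the first table's order.
#' @export
merge_chunk_results <- function(tables) {
  stopifnot(length(tables) >= 1L)
  tags <- vapply(tables, function(t) t$tag, character(1))
  if (length(unique(tags)) > 1L)
    stop("cannot merge gene and pathway tables together")
  ref <- sample_ids(tables[[1L]])
  for (t in tables[-1L]) {
    s <- sample_ids(t)
    if (!setequal(s, ref))
      stop("sample sets differ between chunk results: ",
           paste(c(setdiff(ref, s), setdiff(s, ref)), collapse = ", "))
  }
  ids <- unique(unlist(lapply(tables, function(t) rownames(t$counts))))
  m <- matrix(0, length(ids), length(ref), dimnames = list(ids, ref))
  for (t in tables)
    m[rownames(t$counts), ref] <- m[rownames(t$counts), ref] +
      t$counts[, ref, drop = FALSE]
  functional_table(m, tag = tags[1L])
}

strip_html <- function(x) gsub("<[^>]+>", "", x)

#' Parse a KEGG BRITE hierarchy file
#'
#' Reads the `.keg` text convention: lines prefixed `A`/`B`/`C` open nested
#' category levels and `D` lines carry KO gene entries of the form
#' `K##### <symbol>; <description>`. Each KO is mapped to its description
#' and every (levelA, levelB, levelC) category path under which it appears.
#' Categories with no KO descendants do not appear in the mapping. Malformed
#' `D` lines are skipped and counted in the `"skipped"` attribute.
#'
#' @param path `.keg` file.
#' @return a [brite_hierarchy()].
#' @export
parse_brite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  curA <- curB <- curC <- NA_character_
  ko <- a <- b <- cc <- desc <- character(0)
  skipped <- 0L
  for (line in lines) {
    if (!nzchar(line)) next
    tag <- substr(line, 1L, 1L)
    body <- trimws(strip_html(substr(line, 2L, nchar(line))))
    if (tag == "A") { curA <- body; curB <- curC <- NA_character_ }
    else if (tag == "B") { if (nzchar(body)) { curB <- body; curC <- NA_character_ } }
    else if (tag == "C") { if (nzchar(body)) curC <- body }
    else if (tag == "D") {
      m <- regmatches(body, regexec("^(K[0-9]{5})\\s+(.*)$", body))[[1L]]
      if (length(m) < 3L || !nzchar(trimws(m[3L]))) { skipped <- skipped + 1L; next }
      entry <- trimws(m[3L])
      entry <- sub("\\s*\\[[^]]*\\]\\s*$", "", entry)  # trailing [EC:...]
      d <- if (grepl(";", entry, fixed = TRUE))
        trimws(sub("^[^;]*;", "", entry)) else entry
      if (!nzchar(d)) { skipped <- skipped + 1L; next }
      ko <- c(ko, m[2L]); a <- c(a, curA); b <- c(b, curB); cc <- c(cc, curC)
      desc <- c(desc, d)
    }
  }
  if (!length(ko))
    stop("no KO entries (D lines) parsed from ", basename(path))
  paths <- unique(data.frame(ko = ko, levelA = a, levelB = b, levelC = cc,
                             stringsAsFactors = FALSE))
  rownames(paths) <- NULL
  descriptions <- tapply(desc, ko, function(x) x[1L])
  h <- brite_hierarchy(paths, descriptions[unique(ko)])
  attr(h, "skipped") <- skipped
  h
}

#' Annotate a functional table against a BRITE hierarchy
#'
#' Each KO row gains (levelA, levelB, levelC, description) columns. A KO
#' listed under several BRITE paths uses the lexicographically first path
#' for its primary row; the full path list is kept as a sidecar mapping.
#' KOs absent from the hierarchy are labeled `unannotated` at all levels.
#' Pathway-tagged tables are matched against C-level category names by the
#' 5-digit pathway number where possible. Abundance values are never
#' altered.
#'
#' @param fn a [functional_table()].
#' @param brite a [brite_hierarchy()].
#' @return object of class `annotated_functional`: list with `table` (the
#'   input, untouched), `annotation` (data.frame: id, levelA, levelB,
#'   levelC, description, one row per table row), and `paths` (sidecar
#'   data.frame of all BRITE paths for the table's KOs).
#' @export
annotate_functional <- function(fn, brite) {
  ids <- rownames(fn$counts)
  ann <- data.frame(id = ids,
                    levelA = "unannotated", levelB = "unannotated",
                    levelC = "unannotated", description = "unannotated",
                    stringsAsFactors = FALSE)
  if (fn$tag == "gene") {
    for (i in seq_along(ids)) {
      hits <- brite$paths[brite$paths$ko == ids[i], , drop = FALSE]
      if (!nrow(hits)) next
      key <- paste(hits$levelA, hits$levelB, hits$levelC, sep = "\r")
      best <- hits[order(key)[1L], ]
      ann$levelA[i] <- best$levelA
      ann$levelB[i] <- best$levelB
      ann$levelC[i] <- best$levelC
      ann$description[i] <- unname(brite$descriptions[ids[i]])
    }
    sidecar <- brite$paths[brite$paths$ko %in% ids, , drop = FALSE]
  } else {
    num <- sub("^(ko|map|path:ko|path:map)", "", ids)
    cnum <- sub("^([0-9]{5}).*$", "\\1", brite$paths$levelC)
    for (i in seq_along(ids)) {
      hit <- which(cnum == num[i])
      if (!length(hit)) next
      best <- brite$paths[hit[1L], ]
      ann$levelA[i] <- best$levelA
      ann$levelB[i] <- best$levelB
      ann$levelC[i] <- best$levelC
      ann$description[i] <- best$levelC
    }
    sidecar <- brite$paths[cnum %in% num, , drop = FALSE]
  }
  rownames(sidecar) <- NULL
  structure(list(table = fn, annotation = ann, paths = sidecar),
            class = "annotated_functional")
}

#' @export
print.annotated_functional <- function(x, ...) {
  n_ann <- sum(x$annotation$levelA != "unannotated")
  cat("annotated_functional: ", nrow(x$annotation), " ", x$table$tag,
      " rows, ", n_ann, " annotated\n", sep = "")
  invisible(x)
}

#' Write functional-profile analysis files
#'
#' Emits three views of an annotated functional table:
#' \itemize{
#'   \item `functional.spf` — STAMP profile with hierarchy columns levelA,
#'     levelB, levelC, then `KO description`, then samples. Strict by
#'     construction: every KO carries exactly one primary path.
#'   \item `functional_long.tsv` — spreadsheet-ready long table (SampleID,
#'     KO, levels, Description, Count; zero cells omitted).
#'   \item `functional_cytoscape.tsv` — weighted edge list sample ->
#'     annotated gene label (zeros omitted).
#'   \item `annotation_paths.tsv` — sidecar listing every BRITE path per KO.
#' }
#'
#' @param annotated an [annotate_functional()] result.
#' @param dir output directory.
#' @return character vector of paths written, invisibly.
#' @export
write_functional_outputs <- function(annotated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- annotated$table
  ann <- annotated$annotation
  label <- paste(ann$id, ann$description)

  spf <- data.frame(Level_A = ann$levelA, Level_B = ann$levelB,
                    Level_C = ann$levelC, Gene = label, fn$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  spf_path <- file.path(dir, "functional.spf")
  write_tsv_lf(spf, spf_path)

  rows <- list()
  for (j in seq_len(ncol(fn$counts))) {
    nz <- which(fn$counts[, j] != 0)
    if (length(nz))
      rows[[length(rows) + 1L]] <- data.frame(
        SampleID = sample_ids(fn)[j], KO = ann$id[nz],
        Level_A = ann$levelA[nz], Level_B = ann$levelB[nz],
        Level_C = ann$levelC[nz], Description = ann$description[nz],
        Count = fn$counts[nz, j], stringsAsFactors = FALSE)
  }
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(SampleID = character(0), KO = character(0),
               Level_A = character(0), Level_B = character(0),
               Level_C = character(0), Description = character(0),
               Count = numeric(0))
  rownames(long) <- NULL
  long_path <- file.path(dir, "functional_long.tsv")
  write_tsv_lf(long, long_path)

  labeled <- fn
  rownames(labeled$counts) <- label
  cyto_path <- file.path(dir, "functional_cytoscape.tsv")
  write_cytoscape(labeled, cyto_path)

  paths_path <- file.path(dir, "annotation_paths.tsv")
  write_tsv_lf(annotated$paths, paths_path)

  invisible(c(spf_path, long_path, cyto_path, paths_path))
}
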
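# Orchestration of the two-part protocol: (1) community-profile file
# production, (2) inferred-functional file production. Plus the external
# aligner/tree adapter. The Rscript CLI under inst/cli/ is a thin wrapper
# over these functions.

COMMUNITY_TARGETS <- c("excel", "stamp", "ranacapa", "cytoscape", "qiime2",
                       "piphillin")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

config_default <- function(config, field, default) {
  if (is.null(config[[field]])) default else config[[field]]
}

validation_abort <- function(report) {
  e <- simpleError(paste0(
    "sample validation failed: ",
    paste(c(
      if (length(report$missing_in_table))
        paste0("metadata IDs missing from table [",
               paste(report$missing_in_table, collapse = ", "), "]"),
      if (length(report$missing_in_metadata))
        paste0("table IDs missing from metadata [",
               paste(report$missing_in_metadata, collapse = ", "), "]"),
      if (length(report$bad_character_ids))
        paste0("bad characters in [",
               paste(report$bad_character_ids, collapse = ", "), "]"),
      if (length(report$duplicates))
        paste0("duplicates [", paste(report$duplicates, collapse = ", "),
               "]")),
      collapse = "; ")))
  e$report <- report
  class(e) <- c("taxbridge_validation_error", class(e))
  stop(e)
}

ingest_community_input <- function(config) {
  dialect <- match.arg(config$dialect, c("anacapa", "qiime2", "mrdna"))
  switch(dialect,
         anacapa = read_anacapa(config$table),
         qiime2 = read_qiime2(config$table, taxonomy = config$taxonomy),
         mrdna = read_mrdna(config$rank_files))
}

finish_run <- function(run_dir, steps, warnings) {
  write_lines_lf(c(paste("step:", steps),
                   if (length(warnings)) paste("warning:", warnings)),
                 file.path(run_dir, "run.log"))
  manifest <- build_manifest(run_dir)
  write_manifest(manifest, run_dir)
  structure(list(run_dir = run_dir, manifest = manifest,
                 warnings = warnings),
            class = "taxbridge_run")
}

#' @export
print.taxbridge_run <- function(x, ...) {
  cat("run folder:", x$run_dir, "\n")
  cat(nrow(x$manifest), "files written;", length(x$warnings), "warnings\n")
  invisible(x)
}

#' Produce all community-profile analysis files
#'
#' Runs the first half of the protocol end to end: ingest the chosen
#' dialect, validate sample metadata (aborting before anything is written
#' if validation fails), repair lineages to a strict hierarchy, optionally
#' rarefy, then write every requested export target into a fresh
#' timestamped run folder with a manifest (`manifest.tsv`: file, bytes,
#' MD5) and a step log.
#'
#' @param config list or YAML file path. Fields: `dialect`
#'   (anacapa/qiime2/mrdna), `table` (path; `rank_files` named list for
#'   mrdna; `taxonomy` optional for qiime2), `seqs` (FASTA path, optional),
#'   `metadata` (path), `targets` (subset of
#'   excel/stamp/ranacapa/cytoscape/qiime2/piphillin; default all),
#'   `repair_mode` (fill/truncate), `rarefy_depth` (optional),
#'   `rarefy_iters` (1-10), `seed`, `max_upload_mb` (default 10), `tree`
#'   (logical: run the external aligner/tree adapter), `out` (base output
#'   dir), `time` (injectable timestamp).
#' @return object of class `taxbridge_run`: `run_dir`, `manifest`,
#'   `warnings`.
#' @export
run_community <- function(config) {
  config <- read_config(config)
  targets <- config_default(config, "targets", COMMUNITY_TARGETS)
  unknown <- setdiff(targets, COMMUNITY_TARGETS)
  if (length(unknown)) stop("unknown targets: ", paste(unknown, collapse = ", "))
  repair_mode <- config_default(config, "repair_mode", "fill")
  seed <- config_default(config, "seed", 1L)
  max_bytes <- config_default(config, "max_upload_mb", 10) * 2^20
  iters <- config_default(config, "rarefy_iters", 1L)
  if (!is.null(config$rarefy_iters) &&
      (iters < 1L || iters > 10L || iters != floor(iters)))
    stop("rarefy_iters must be an integer between 1 and 10")
  out <- config_default(config, "out", ".")
  time <- config_default(config, "time", Sys.time())

  warns <- character(0)
  note <- function(w) { warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning") }
  steps <- character(0)
  step <- function(s) { steps <<- c(steps, s); message("[taxbridge] ", s) }

  withCallingHandlers({
    step("ingest")
    table <- ingest_community_input(config)
    meta <- sample_metadata(read_delim_table(config$metadata))
    seqs <- if (!is.null(config$seqs)) read_fasta(config$seqs)

    step("validate")
    target_tool <- if ("ranacapa" %in% targets) "ranacapa" else "generic"
    report <- validate_samples(meta, table, target = target_tool)
    if (!report$ok) validation_abort(report)

    step(paste0("repair (", repair_mode, ")"))
    table <- repair_table(table, mode = repair_mode)

    if (!is.null(config$rarefy_depth)) {
      step(paste0("rarefy (depth ", config$rarefy_depth, ", ", iters,
                  " iteration(s))"))
      table <- rarefy(table, depth = config$rarefy_depth,
                      iterations = iters, seed = seed)
    }

    run_dir <- make_run_folder(out, time = time)
    if ("excel" %in% targets) {
      step("write excel")
      write_excel_long(table, file.path(run_dir, "excel",
                                        "community_long.tsv"))
    }
    if ("stamp" %in% targets) {
      step("write stamp")
      write_spf(table, file.path(run_dir, "stamp", "community.spf"))
    }
    if ("ranacapa" %in% targets) {
      step("write ranacapa")
      write_ranacapa(table, meta, file.path(run_dir, "ranacapa"))
    }
    if ("cytoscape" %in% targets) {
      step("write cytoscape")
      write_cytoscape(table, file.path(run_dir, "cytoscape",
                                       "community_edges.tsv"))
    }
    if ("qiime2" %in% targets) {
      step("write qiime2")
      tree <- NULL
      if (isTRUE(config$tree) && !is.null(seqs))
        tree <- align_and_tree(seqs)
      write_qiime2_inputs(table, meta, file.path(run_dir, "qiime2"),
                          tree = tree)
    }
    if ("piphillin" %in% targets) {
      if (is.null(seqs)) {
        warning("no sequences supplied; skipping piphillin target",
                call. = FALSE)
      } else {
        step("write piphillin")
        write_piphillin_inputs(seqs, table,
                               file.path(run_dir, "piphillin"),
                               max_bytes = max_bytes)
      }
    }
    step("manifest")
    finish_run(run_dir, steps, warns)
  }, warning = note)
}

#' Produce all inferred-functional analysis files
#'
#' Runs the second half of the protocol: ingest one or more
#' functional-inference result archives, merge per-chunk tables, parse the
#' BRITE hierarchy, annotate, and write the functional export files into a
#' fresh timestamped run folder (gene outputs under `functional/`, pathway
#' outputs under `functional/pathways/`).
#'
#' @param config list or YAML file path. Fields: `tars` (character vector
#'   of `.tar`/`.tar.gz` paths), `keg` (BRITE `.keg` path), `out`, `time`.
#' @return object of class `taxbridge_run`.
#' @export
run_functional <- function(config) {
  config <- read_config(config)
  if (is.null(config$tars) || !length(config$tars))
    stop("no result archives supplied (config$tars)")
  if (is.null(config$keg) || !file.exists(config$keg))
    stop("BRITE hierarchy file not found: ",
         if (is.null(config$keg)) "(none supplied)" else config$keg)
  out <- config_default(config, "out", ".")
  time <- config_default(config, "time", Sys.time())

  warns <- character(0)
  note <- function(w) { warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning") }
  steps <- character(0)
  step <- function(s) { steps <<- c(steps, s); message("[taxbridge] ", s) }

  withCallingHandlers({
    step("ingest archives")
    tables <- unlist(lapply(config$tars, read_piphillin_tar),
                     recursive = FALSE)
    tags <- vapply(tables, function(t) t$tag, character(1))

    step("merge chunks")
    gene <- if (any(tags == "gene"))
      merge_chunk_results(tables[tags == "gene"])
    pathway <- if (any(tags == "pathway"))
      merge_chunk_results(tables[tags == "pathway"])
    if (is.null(gene)) stop("no gene-tagged KO table found in the archives")

    step("parse BRITE hierarchy")
    brite <- parse_brite(config$keg)

    step("annotate")
    ann_gene <- annotate_functional(gene, brite)

    run_dir <- make_run_folder(out, time = time)
    step("write functional outputs")
    write_functional_outputs(ann_gene, file.path(run_dir, "functional"))
    if (!is.null(pathway)) {
      ann_pw <- annotate_functional(pathway, brite)
      write_functional_outputs(ann_pw,
                               file.path(run_dir, "functional", "pathways"))
    }
    step("manifest")
    finish_run(run_dir, steps, warns)
  }, warning = note)
}

#' Align sequences and infer a phylogenetic tree via external tools
#'
#' Thin adapter over an external multiple-sequence aligner (MAFFT) and tree
#' builder (FastTree): alignment and tree inference are delegated, never
#' reimplemented. If either tool is not on the PATH the operation is
#' skipped with a warning and returns `NULL`. The returned newick string's
#' leaf labels are exactly the sequence IDs.
#'
#' @param seqs a [sequence_set()].
#' @param mafft,fasttree executable names or paths.
#' @return newick string, or `NULL` when the tools are unavailable.
#' @export
align_and_tree <- function(seqs, mafft = "mafft", fasttree = "fasttree") {
  if (Sys.which(mafft) == "" || Sys.which(fasttree) == "") {
    warning("alignment/tree tools not found on PATH; skipping tree",
            call. = FALSE)
    return(NULL)
  }
  fa <- tempfile(fileext = ".fasta")
  aln <- tempfile(fileext = ".aln")
  tre <- tempfile(fileext = ".nwk")
  errf <- tempfile()
  write_fasta(seqs, fa)
  status <- system2(mafft, c("--auto", "--quiet", fa),
                    stdout = aln, stderr = errf)
  if (status != 0)
    stop("mafft failed (exit ", status, "): ",
         paste(readLines(errf, warn = FALSE), collapse = " | "))
  status <- system2(fasttree, c("-nt", "-quiet", "-nopr", aln),
                    stdout = tre, stderr = errf)
  if (status != 0)
    stop("fasttree failed (exit ", status, "): ",
         paste(readLines(errf, warn = FALSE), collapse = " | "))
  newick <- paste(readLines(tre, warn = FALSE), collapse = "")
  phy <- ape::read.tree(text = newick)
  if (!setequal(phy$tip.label, names(seqs)))
    stop("tree leaf set does not match sequence IDs")
  newick
}
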
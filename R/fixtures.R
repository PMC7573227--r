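# Synthetic dataset generator. Emits a complete on-disk dataset in any of
# the supported dialects together with a ground-truth object of the values
# a correct parse must recover. Everything is deterministic in `seed`.

random_taxonomy <- function(n_features, gap_prob) {
  # hierarchically consistent names: each rank's label embeds its parent,
  # so identical prefixes really are identical taxa
  lin <- matrix(NA_character_, n_features, N_RANKS)
  for (i in seq_len(n_features)) {
    path <- "Bacteria"
    labels <- path
    widths <- c(4L, 2L, 2L, 2L, 3L, 3L)  # children per rank below domain
    tags <- c("P", "C", "O", "F", "G", "S")
    for (r in seq_len(6L)) {
      path <- paste0(path, "_", tags[r], sample.int(widths[r], 1L))
      labels <- c(labels, path)
    }
    lin[i, ] <- labels
  }
  if (gap_prob > 0) {
    gaps <- matrix(stats::runif(n_features * N_RANKS) < gap_prob,
                   n_features, N_RANKS)
    lin[gaps] <- NA_character_
  }
  lin
}

random_dna <- function(n, nchar_each) {
  vapply(rep_len(nchar_each, n), function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

# Fixed tiny KEGG BRITE .keg fixture; K00003 sits under two C categories.
keg_fixture_lines <- function(kos = sprintf("K%05d", 1:10)) {
  descs <- paste0("enzyme ", seq_along(kos))
  c("+D\tKO",
    "#<h2>Synthetic KO hierarchy (fixture)</h2>",
    "!",
    "A09100 Metabolism",
    "B  09101 Carbohydrate metabolism",
    "C    00010 Glycolysis / Gluconeogenesis [PATH:ko00010]",
    sprintf("D      %s  sym%d; %s [EC:1.1.1.%d]",
            kos[1:5], 1:5, descs[1:5], 1:5),
    "C    00020 Citrate cycle (TCA cycle) [PATH:ko00020]",
    sprintf("D      %s  sym%d; %s", kos[c(3L, 6L, 7L)], c(3L, 6L, 7L),
            descs[c(3L, 6L, 7L)]),
    "A09120 Genetic Information Processing",
    "B  09121 Transcription",
    "C    03020 RNA polymerase [PATH:ko03020]",
    sprintf("D      %s  sym%d; %s", kos[8:10], 8:10, descs[8:10]),
    "!",
    "#Last updated: fixture")
}

make_zip_with_python <- function(zip_path, file_path, internal_name) {
  script <- sprintf(
    "import zipfile; z=zipfile.ZipFile(%s,'w'); z.write(%s,%s); z.close()",
    shQuote(zip_path), shQuote(file_path), shQuote(internal_name))
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) stop("python zipfile construction failed")
  invisible(zip_path)
}

#' Generate a synthetic on-disk dataset with known ground truth
#'
#' Writes a complete dataset emulating one of the supported upstream
#' dialects — abundance table(s), representative-sequence FASTA, sample
#' metadata — and optionally a BRITE `.keg` hierarchy and a
#' functional-inference result `.tar`. Returns the ground-truth objects a
#' correct parse must reproduce. Generation is deterministic in `seed`
#' (archive member timestamps are pinned so even tar bytes reproduce).
#'
#' Lineages are drawn from a hierarchically consistent synthetic taxonomy;
#' each rank is independently blanked with probability `gap_prob`, so
#' `gap_prob = 0` yields all-strict lineages and `gap_prob > 0` exercises
#' strict-hierarchy repair.
#'
#' @param dir output directory (created).
#' @param dialect `"anacapa"`, `"qiime2"`, or `"mrdna"`.
#' @param n_samples,n_features dataset dimensions.
#' @param gap_prob per-rank probability of an unclassified gap.
#' @param seed integer seed.
#' @param seq_bytes sequence length(s) per record, recycled.
#' @param lambda mean per-cell count (Poisson).
#' @param bad_metadata_char if `TRUE`, one sample ID gets a period (invalid
#'   for ranacapa) in both table and metadata.
#' @param with_qza also wrap the QIIME 2 export in a `.qza` zip container
#'   (qiime2 dialect only).
#' @param with_keg also write a small `.keg` BRITE hierarchy fixture.
#' @param with_tar also write a functional-inference result archive holding
#'   a KO table and a pathway table.
#' @return list with `files` (named paths) and `truth` (list: `table` the
#'   expected [feature_table()], `seqs`, `meta`, `grand_total`, and — with
#'   `with_tar` — `ko_counts`, `pathway_counts` matrices).
#' @export
generate_fixture <- function(dir,
                             dialect = c("anacapa", "qiime2", "mrdna"),
                             n_samples = 12L, n_features = 100L,
                             gap_prob = 0.2, seed = 1L,
                             seq_bytes = 150L, lambda = 30,
                             bad_metadata_char = FALSE,
                             with_qza = FALSE, with_keg = FALSE,
                             with_tar = FALSE) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()

  truth <- with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    if (bad_metadata_char && n_samples >= 1L)
      samples[1L] <- sub("^S", "S.", samples[1L])
    fids <- sprintf("ASV_%03d", seq_len(n_features))
    lin <- random_taxonomy(n_features, gap_prob)
    counts <- matrix(stats::rpois(n_features * n_samples, lambda),
                     n_features, n_samples,
                     dimnames = list(fids, samples))
    storage.mode(counts) <- "integer"
    style <- if (dialect == "mrdna") "mrdna" else "anacapa"
    meta <- sample_metadata(data.frame(
      sample_id = samples,
      group = rep_len(c("A", "B"), n_samples),
      site = round(stats::runif(n_samples, 0, 100), 1),
      stringsAsFactors = FALSE))
    seqs <- sequence_set(stats::setNames(
      random_dna(n_features, seq_bytes), fids))
    list(table = feature_table(counts, lin, rank_style = style),
         seqs = seqs, meta = meta, grand_total = sum(counts))
  })

  meta_path <- file.path(dir, "metadata.tsv")
  write_tsv_lf(as.data.frame(truth$meta), meta_path)
  files$metadata <- meta_path

  fa_path <- file.path(dir, "seqs.fasta")
  write_fasta(truth$seqs, fa_path)
  files$seqs <- fa_path

  tb <- truth$table
  rendered <- tb$lineages
  rendered[is.na(rendered)] <- ""  # blanks on disk; parsers must recognize
  tax_strings <- apply(rendered, 1L, paste, collapse = ";")

  if (dialect == "anacapa") {
    df <- data.frame(ASV_ID = feature_ids(tb), sum.taxonomy = tax_strings,
                     tb$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, "anacapa_table.tsv")
    write_tsv_lf(df, p)
    files$table <- p
  } else if (dialect == "qiime2") {
    ft <- data.frame(feature_ids(tb), tb$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(ft)[1L] <- "#OTU ID"
    p <- file.path(dir, "feature-table.tsv")
    write_tsv_lf(ft, p)
    files$table <- p
    tax <- data.frame(feature_ids(tb), tax_strings,
                      Confidence = rep(0.97, n_features),
                      stringsAsFactors = FALSE)
    names(tax)[1:2] <- c("Feature ID", "Taxon")
    tp <- file.path(dir, "taxonomy.tsv")
    write_tsv_lf(tax, tp)
    files$taxonomy <- tp
    if (with_qza) {
      qza <- file.path(dir, "table.qza")
      make_zip_with_python(qza, p, "fixture-artifact/data/feature-table.tsv")
      files$qza <- qza
    }
  } else { # mrdna: one file per rank; deepest carries full paths
    ladder <- rank_ladder("mrdna")
    rank_files <- character(0)
    for (r in seq_len(N_RANKS)) {
      labels <- render_lineage(tb$lineages[, r])
      if (r == N_RANKS) {
        df <- data.frame(Taxonomy = tax_strings, tb$counts,
                         check.names = FALSE, stringsAsFactors = FALSE)
      } else {
        agg <- rowsum(tb$counts, labels, reorder = FALSE)
        df <- data.frame(Taxonomy = rownames(agg), agg,
                         check.names = FALSE, stringsAsFactors = FALSE)
      }
      p <- file.path(dir, paste0("mrdna_", ladder[r], ".tsv"))
      write_tsv_lf(df, p)
      rank_files[ladder[r]] <- p
    }
    files$rank_files <- rank_files
    files$table <- rank_files[[N_RANKS]]
  }

  if (with_keg) {
    kp <- file.path(dir, "hierarchy.keg")
    write_lines_lf(keg_fixture_lines(), kp)
    files$keg <- kp
  }

  if (with_tar) {
    kos <- sprintf("K%05d", 1:8)
    pathways <- sprintf("ko%05d", c(10L, 20L, 3020L))
    tar_truth <- with_seed(seed + 1L, {
      s <- sample_ids(truth$table)
      ko_counts <- matrix(stats::rpois(length(kos) * length(s), 50),
                          length(kos), length(s),
                          dimnames = list(kos, s))
      pw_counts <- matrix(stats::rpois(length(pathways) * length(s), 200),
                          length(pathways), length(s),
                          dimnames = list(pathways, s))
      list(ko = ko_counts, pw = pw_counts)
    })
    staging <- file.path(tempfile("tarfix"), "piphillin_results")
    dir.create(staging, recursive = TRUE)
    ko_df <- data.frame(KO = kos, tar_truth$ko, check.names = FALSE)
    pw_df <- data.frame(Pathway = pathways, tar_truth$pw,
                        check.names = FALSE)
    write_tsv_lf(ko_df, file.path(staging, "ko_abundance.txt"))
    write_tsv_lf(pw_df, file.path(staging, "pathway_abundance.txt"))
    # pin mtimes so archive bytes are reproducible
    epoch <- as.POSIXct("2020-01-01", tz = "UTC")
    for (f in list.files(staging, full.names = TRUE))
      Sys.setFileTime(f, epoch)
    Sys.setFileTime(staging, epoch)
    tar_path <- file.path(normalizePath(dir), "piphillin_results.tar")
    old <- setwd(dirname(staging))
    on.exit(setwd(old), add = TRUE)
    utils::tar(tar_path, basename(staging), tar = "internal")
    files$tar <- tar_path
    truth$ko_counts <- tar_truth$ko
    truth$pathway_counts <- tar_truth$pw
  }

  list(files = files, truth = truth)
}
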
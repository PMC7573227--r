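# helpers to write small dialect files by hand
write_rank_file <- function(path, taxa, counts, samples) {
  lines <- c(paste(c("Taxonomy", samples), collapse = "\t"),
             vapply(seq_along(taxa), function(i)
               paste(c(taxa[i], counts[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
}

test_that("per-rank reader recovers counts confirmed by a column-sum oracle", {
  d <- withr::local_tempdir()
  counts <- matrix(c(5L, 1L, 0L, 3L, 2L, 4L), 3, 2, byrow = TRUE)
  oracle_colsums <- c(5L + 0L + 2L, 1L + 3L + 4L)
  genus <- file.path(d, "genus.tsv")
  write_rank_file(genus, c("GenA", "GenB", "GenC"), counts, c("S1", "S2"))
  tb <- read_mrdna(c(genus = genus))
  expect_identical(as.integer(colSums(tb$counts)), oracle_colsums)
  expect_identical(unname(tb$counts[, 1]), counts[, 1])
  expect_identical(tb$lineages[1, 6], "GenA")
  expect_true(all(is.na(tb$lineages[, 7])))
})

test_that("per-rank reader handles empty tables and duplicated taxon rows", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "genus.tsv")
  writeLines("Taxonomy\tS1\tS2", empty)
  tb <- read_mrdna(c(genus = empty))
  expect_identical(nrow(tb$counts), 0L)
  expect_identical(sample_ids(tb), c("S1", "S2"))

  dup <- file.path(d, "genus2.tsv")
  write_rank_file(dup, c("GenA", "GenA"),
                  matrix(c(1L, 2L, 3L, 4L), 2, 2), c("S1", "S2"))
  tb2 <- read_mrdna(c(genus = dup))
  expect_identical(nrow(tb2$counts), 2L)
  expect_false(anyDuplicated(feature_ids(tb2)) > 0)
})

test_that("per-rank reader reconstructs ancestors by count-vector match", {
  d <- withr::local_tempdir()
  # PhyA contains only GenA (identical count vector -> unambiguous);
  # PhyB and PhyC share a count vector -> ambiguous, left unclassified
  genus <- file.path(d, "genus.tsv")
  phylum <- file.path(d, "phylum.tsv")
  write_rank_file(genus, c("GenA", "GenB"),
                  matrix(c(5L, 1L, 7L, 2L), 2, 2, byrow = TRUE),
                  c("S1", "S2"))
  write_rank_file(phylum, c("PhyA", "PhyB", "PhyC"),
                  matrix(c(5L, 1L, 7L, 2L, 7L, 2L), 3, 2, byrow = TRUE),
                  c("S1", "S2"))
  tb <- read_mrdna(c(phylum = phylum, genus = genus))
  expect_identical(tb$lineages[1, 2], "PhyA")
  expect_true(is.na(tb$lineages[2, 2]))
})

test_that("per-rank reader rejects inconsistent samples and bad cells", {
  d <- withr::local_tempdir()
  genus <- file.path(d, "genus.tsv")
  phylum <- file.path(d, "phylum.tsv")
  write_rank_file(genus, "GenA", matrix(c(1L, 2L), 1), c("S1", "S2"))
  write_rank_file(phylum, "PhyA", matrix(c(1L, 2L), 1), c("S1", "S3"))
  expect_error(read_mrdna(c(phylum = phylum, genus = genus)),
               "inconsistent sample columns.*phylum")

  bad <- file.path(d, "bad.tsv")
  writeLines(c("Taxonomy\tS1\tS2", "GenA\t1\toops"), bad)
  expect_error(read_mrdna(c(genus = bad)), "row 1, column 'S2'")
  frac <- file.path(d, "frac.tsv")
  writeLines(c("Taxonomy\tS1", "GenA\t12.5"), frac)
  expect_error(read_mrdna(c(genus = frac)), "fractional")
})

test_that("ASV reader splits semicolon lineages with blank segments", {
  d <- withr::local_tempdir()
  p <- file.path(d, "asv.tsv")
  writeLines(c("ASV_ID\tsum.taxonomy\tS1\tS2",
               "ASV_1\tBacteria;Proteobacteria;;Enterobacteriales;;Escherichia;\t4\t0",
               "ASV_2\tA;B;C;D;E;F;G\t1\t2",
               "ASV_3\t\t0\t5"), p)
  tb <- read_anacapa(p)
  expect_identical(feature_ids(tb), c("ASV_1", "ASV_2", "ASV_3"))
  expect_identical(unname(is.na(tb$lineages[1, ])),
                   c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(unname(tb$lineages[2, ]), LETTERS[1:7])
  expect_true(all(is.na(tb$lineages[3, ])))
  expect_identical(unname(tb$counts[, "S2"]), c(0L, 2L, 5L))
})

test_that("ASV reader errors on missing lineage column, warns on >7 ranks", {
  d <- withr::local_tempdir()
  p <- file.path(d, "nolin.tsv")
  writeLines(c("ASV_ID\tS1", "ASV_1\t3"), p)
  expect_error(read_anacapa(p), "sum.taxonomy")
  p2 <- file.path(d, "deep.tsv")
  writeLines(c("ASV_ID\tsum.taxonomy\tS1",
               "ASV_1\ta;b;c;d;e;f;g;h\t3"), p2)
  expect_warning(tb <- read_anacapa(p2), "truncating")
  expect_identical(tb$lineages[1, 7], "g")
})

test_that("QIIME 2 reader handles exports, .qza containers, and taxonomy", {
  fx <- generate_fixture(withr::local_tempdir(), "qiime2", n_samples = 3,
                         n_features = 8, gap_prob = 0.2, seed = 21,
                         with_qza = TRUE)
  tb <- read_qiime2(fx$files$table, taxonomy = fx$files$taxonomy)
  expect_identical(tb$counts, fx$truth$table$counts)
  expect_identical(tb$lineages, fx$truth$table$lineages)
  # the fixture's taxonomy carries a Confidence column; it must be ignored
  tb_qza <- read_qiime2(fx$files$qza, taxonomy = fx$files$taxonomy)
  expect_identical(tb_qza$counts, tb$counts)
  expect_warning(tb_warn <- read_qiime2(fx$files$table),
                 "all lineages unclassified")
  expect_true(all(is.na(tb_warn$lineages)))
})

test_that("a zip without a feature-table payload errors listing members", {
  d <- withr::local_tempdir()
  junk <- file.path(d, "junk.txt")
  writeLines("nothing here", junk)
  qza <- file.path(d, "bad.qza")
  script <- sprintf(
    "import zipfile; z=zipfile.ZipFile(%s,'w'); z.write(%s,'x/other.bin'); z.close()",
    shQuote(qza), shQuote(junk))
  expect_identical(system2("python", c("-c", shQuote(script))), 0L)
  expect_error(read_qiime2(qza), "x/other.bin")
})

test_that("FASTA reader keeps order, concatenates wrapped lines, checks IDs", {
  d <- withr::local_tempdir()
  p <- file.path(d, "a.fasta")
  writeLines(c(">r1 extra header words", "ACGT", "TTAA", ">r2", "GG"), p)
  s <- read_fasta(p)
  expect_identical(names(s), c("r1", "r2"))
  expect_identical(unclass(s)[["r1"]], "ACGTTTAA")
  # canonical serialized bytes: ">r1\nACGTTTAA\n" = 13
  expect_identical(unname(fasta_record_bytes(s)[1]), 13L)

  empty <- file.path(d, "e.fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  dup <- file.path(d, "d.fasta")
  writeLines(c(">x", "A", ">x", "C"), dup)
  expect_error(read_fasta(dup), "duplicate")
  headless <- file.path(d, "h.fasta")
  writeLines(c("ACGT", ">x", "A"), headless)
  expect_error(read_fasta(headless), "malformed FASTA")
})

test_that("result archives are recognized by content shape", {
  fx <- generate_fixture(withr::local_tempdir(), "anacapa", n_samples = 2,
                         n_features = 4, seed = 3, with_tar = TRUE)
  tables <- read_piphillin_tar(fx$files$tar)
  expect_length(tables, 2)
  tags <- vapply(tables, function(t) t$tag, character(1))
  expect_setequal(tags, c("gene", "pathway"))
  gene <- tables[[which(tags == "gene")]]
  expect_identical(gene$counts[rownames(fx$truth$ko_counts), ],
                   fx$truth$ko_counts * 1.0)

  # gzip-compressed archive of the same members parses identically
  d <- withr::local_tempdir()
  exdir <- file.path(d, "stage")
  utils::untar(fx$files$tar, exdir = exdir)
  tgz <- file.path(d, "res.tar.gz")
  withr::with_dir(exdir, utils::tar(tgz, list.files(exdir),
                                    compression = "gzip", tar = "internal"))
  tables_gz <- read_piphillin_tar(tgz)
  expect_length(tables_gz, 2)
  expect_identical(sort(sapply(tables_gz, function(t) sum(t$counts))),
                   sort(sapply(tables, function(t) sum(t$counts))))

  # archive without any abundance table errors listing members
  d2 <- withr::local_tempdir()
  writeLines("hello", file.path(d2, "readme.txt"))
  bad <- file.path(d, "bad.tar")
  withr::with_dir(d2, utils::tar(bad, "readme.txt", tar = "internal"))
  expect_error(read_piphillin_tar(bad), "readme.txt")
})

test_that("dialect round-trips reproduce randomized tables exactly", {
  for (seed in c(2L, 7L)) {
    for (dialect in c("anacapa", "qiime2", "mrdna")) {
      fx <- generate_fixture(withr::local_tempdir(), dialect,
                             n_samples = 5, n_features = 20,
                             gap_prob = 0.3, seed = seed)
      tb <- switch(dialect,
                   anacapa = read_anacapa(fx$files$table),
                   qiime2 = read_qiime2(fx$files$table, fx$files$taxonomy),
                   mrdna = read_mrdna(fx$files$rank_files))
      # equality up to feature-ID relabeling (the per-rank dialect has none)
      expect_identical(unname(tb$counts), unname(fx$truth$table$counts))
      expect_identical(unname(tb$lineages),
                       unname(fx$truth$table$lineages))
      # parsing never alters counts: line-oriented oracle over the raw file
      lines <- readLines(fx$files$table)[-1]
      raw_sum <- sum(vapply(strsplit(lines, "\t"), function(f)
        sum(suppressWarnings(as.numeric(f)), na.rm = TRUE), numeric(1)))
      expect_equal(sum(tb$counts), raw_sum)
    }
  }
})
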
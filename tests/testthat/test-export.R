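test_that("SPF writer emits strict profiles and rejects unrepaired input", {
  d <- withr::local_tempdir()
  bad <- feature_table(matrix(2L, 1, 1, dimnames = list("F1", "S1")),
                       matrix(worked_example_lineage(), 1))
  expect_error(write_spf(bad, file.path(d, "x.spf")),
               "F1.*unclassified family")

  repaired <- repair_table(bad, "fill")
  p <- file.path(d, "ok.spf")
  write_spf(repaired, p)
  df <- read.delim(p, check.names = FALSE)
  expect_identical(names(df), c(paste0("Level_", 1:7), "S1"))
  expect_identical(df$Level_5, "unclassified_Enterobacteriales")
  expect_identical(df$Level_7, "unclassified")

  # empty table -> header-only file
  empty <- feature_table(matrix(integer(0), 0, 1,
                                dimnames = list(NULL, "S1")))
  pe <- file.path(d, "empty.spf")
  write_spf(empty, pe)
  expect_length(readLines(pe), 1)

  # round trip through a generic delimited reader is cell-exact
  tb <- repair_table(random_gappy_table(25, 4, seed = 3))
  pr <- file.path(d, "rt.spf")
  write_spf(tb, pr)
  back <- read.delim(pr, check.names = FALSE)
  expect_identical(unname(as.matrix(back[, 8:11])),
                   matrix(unname(tb$counts), nrow(tb$counts)))
  rendered <- ifelse(is.na(tb$lineages), "unclassified", tb$lineages)
  expect_identical(as.matrix(back[, 1:7]),
                   matrix(rendered, nrow(tb$counts), 7,
                          dimnames = list(NULL, paste0("Level_", 1:7))))
})

test_that("edge-list writer keeps unique nonzero sample-taxon pairs", {
  d <- withr::local_tempdir()
  counts <- matrix(c(3L, 0L, 2L, 4L), 2, 2,
                   dimnames = list(c("F1", "F2"), c("S1", "S2")))
  lin <- rbind(lineage(LETTERS[1:7]), lineage(c(LETTERS[1:6], "Z")))
  tb <- feature_table(counts, lin)
  p <- file.path(d, "edges.tsv")
  write_cytoscape(tb, p)
  df <- read.delim(p)
  expect_identical(nrow(df), 3L)  # one zero cell omitted
  expect_false(anyDuplicated(df[, c("source", "target")]) > 0)
  expect_identical(sum(df$weight), sum(counts))  # conservation

  # all-zero table -> header only
  zero <- feature_table(matrix(0L, 1, 1, dimnames = list("F1", "S1")),
                        matrix(lineage(LETTERS[1:7]), 1))
  pz <- file.path(d, "zero.tsv")
  write_cytoscape(zero, pz)
  expect_length(readLines(pz), 1)

  # duplicate labels at a shallow rank aggregate into one edge
  pr <- file.path(d, "phy.tsv")
  write_cytoscape(tb, pr, rank = "phylum")
  dfp <- read.delim(pr)
  expect_identical(nrow(dfp), 2L)
  expect_identical(sum(dfp$weight), sum(counts))
})

test_that("ranacapa writer validates IDs and round-trips through the reader", {
  d <- withr::local_tempdir()
  tb <- repair_table(random_gappy_table(20, 4, seed = 9))
  meta <- sample_metadata(data.frame(sample_id = sample_ids(tb),
                                     group = rep_len(c("A", "B"), 4)))
  write_ranacapa(tb, meta, d)
  back <- read_anacapa(file.path(d, "ranacapa_taxonomy.tsv"))
  expect_identical(back$counts, tb$counts)
  expect_identical(unname(back$lineages), unname(tb$lineages))
  md <- read.delim(file.path(d, "ranacapa_metadata.tsv"))
  expect_identical(md$sample_id, sample_ids(tb))

  # a period-containing sample ID is a hard error naming the ID
  tbad <- feature_table(matrix(1L, 1, 1, dimnames = list("F1", "S.1")),
                        matrix(lineage(LETTERS[1:7]), 1))
  mbad <- sample_metadata(data.frame(sample_id = "S.1"))
  err <- tryCatch(write_ranacapa(tbad, mbad, d), error = identity)
  expect_s3_class(err, "taxbridge_validation_error")
  expect_match(conditionMessage(err), "S\\.1")
  expect_identical(err$report$bad_character_ids, "S.1")
})

test_that("QIIME 2 writer round-trips and checks tree leaves", {
  d <- withr::local_tempdir()
  tb <- repair_table(random_gappy_table(15, 3, seed = 4))
  meta <- sample_metadata(data.frame(sample_id = sample_ids(tb),
                                     depth_m = c(1.5, 2, 30)))
  write_qiime2_inputs(tb, meta, d)
  expect_false(file.exists(file.path(d, "tree.nwk")))
  back <- read_qiime2(file.path(d, "feature-table.tsv"),
                      file.path(d, "taxonomy.tsv"))
  expect_identical(back$counts, tb$counts)
  expect_identical(unname(back$lineages), unname(tb$lineages))
  md <- read.delim(file.path(d, "metadata.tsv"), check.names = FALSE)
  expect_identical(md$`sample-id`, sample_ids(tb))
  expect_identical(md$depth_m, c(1.5, 2, 30))  # numeric survives re-parse

  fid <- feature_ids(tb)
  tree <- paste0("(", fid[1], ":1,", fid[2], ":1);")
  write_qiime2_inputs(tb, meta, d, tree = tree)
  expect_identical(readLines(file.path(d, "tree.nwk")), tree)
  bad_tree <- "(notafeature:1,alsonot:1);"
  expect_error(write_qiime2_inputs(tb, meta, d, tree = bad_tree),
               "notafeature")
})

test_that("long-format writer has one row per nonzero cell, totals conserved", {
  d <- withr::local_tempdir()
  tb <- repair_table(random_gappy_table(20, 5, seed = 17))
  p <- file.path(d, "long.tsv")
  write_excel_long(tb, p)
  df <- read.delim(p, check.names = FALSE)
  expect_identical(nrow(df), sum(tb$counts != 0))
  expect_identical(sum(df$Count), sum(tb$counts))
  expect_identical(names(df), c("SampleID", rank_ladder("anacapa"), "Count"))

  zero <- feature_table(matrix(0L, 2, 2,
                               dimnames = list(c("A", "B"), c("S1", "S2"))))
  pz <- file.path(d, "zero.tsv")
  write_excel_long(repair_table(zero), pz)
  expect_length(readLines(pz), 1)
})

test_that("upload files follow the single/numbered naming convention", {
  d1 <- withr::local_tempdir()
  seqs <- uniform_sequence_set(5, 100)
  tb <- feature_table(matrix(1L, 5, 1,
                             dimnames = list(names(seqs), "S1")))
  write_piphillin_inputs(seqs, tb, d1)
  expect_setequal(list.files(d1),
                  c("piphillinseqs.fasta", "piphillinotu.csv"))
  csv <- read.csv(file.path(d1, "piphillinotu.csv"))
  expect_identical(csv$OTU_ID, names(seqs))  # CSV column 1 = FASTA IDs

  d3 <- withr::local_tempdir()
  seqs30 <- uniform_sequence_set(30, 2^20)
  tb30 <- feature_table(matrix(1L, 30, 1,
                               dimnames = list(names(seqs30), "S1")))
  write_piphillin_inputs(seqs30, tb30, d3, max_bytes = 10 * 2^20)
  expect_setequal(list.files(d3),
                  c(sprintf("piphillinseqs%d.fasta", 1:3),
                    sprintf("piphillinotu.csv%d.csv", 1:3)))
  for (f in sprintf("piphillinseqs%d.fasta", 1:3))
    expect_lte(file.size(file.path(d3, f)), 10 * 2^20)
})

test_that("run folders are timestamped, complete, and collision-safe", {
  d <- withr::local_tempdir()
  t0 <- as.POSIXct("2026-03-04 05:06:07", tz = "UTC")
  r1 <- make_run_folder(d, time = t0)
  r2 <- make_run_folder(d, time = t0)
  expect_false(identical(r1, r2))
  expect_identical(basename(r1), "20260304-050607Z")
  expect_identical(basename(r2), "20260304-050607Z-1")
  expect_setequal(list.dirs(r1, recursive = FALSE, full.names = FALSE),
                  c("excel", "stamp", "ranacapa", "cytoscape", "qiime2",
                    "piphillin", "functional"))
  stamp <- sub("Z$", "", basename(r1))
  parsed <- as.POSIXct(stamp, format = "%Y%m%d-%H%M%S", tz = "UTC")
  expect_identical(parsed, t0)
})

test_that("writers are byte-identical across repeated runs", {
  tb <- repair_table(random_gappy_table(15, 3, seed = 8))
  meta <- sample_metadata(data.frame(sample_id = sample_ids(tb), g = 1:3))
  digest_of <- function() {
    d <- withr::local_tempdir()
    write_spf(tb, file.path(d, "a.spf"))
    write_cytoscape(tb, file.path(d, "b.tsv"))
    write_excel_long(tb, file.path(d, "c.tsv"))
    write_ranacapa(tb, meta, d)
    write_qiime2_inputs(tb, meta, d)
    m <- build_manifest(d)
    m$md5
  }
  expect_identical(digest_of(), digest_of())
})
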
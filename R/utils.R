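# Small shared helpers: delimiter sniffing, local RNG scoping, manifests.

# Tab preferred, comma fallback, decided from the header line.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header)) "\t" else ","
}

read_delim_table <- function(path, sep = NULL, check.names = FALSE) {
  if (is.null(sep)) sep <- sniff_sep(path)
  utils::read.table(path, sep = sep, header = TRUE, check.names = check.names,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", colClasses = NA)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Round half away from zero (counts are non-negative here, so half-up).
round_half_up <- function(x) floor(x + 0.5)

#' Build a manifest of files under a directory
#'
#' Machine-readable inventory of a run folder: one row per file with its
#' path relative to `dir`, byte size, and MD5 content digest. Used to check
#' end-to-end reproducibility of runs.
#'
#' @param dir directory to inventory (recursively).
#' @return data.frame with columns `file`, `bytes`, `md5`, ordered by path.
#' @export
build_manifest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  files <- files[files != "manifest.tsv"]
  full <- file.path(dir, files)
  data.frame(file = files,
             bytes = as.integer(file.size(full)),
             md5 = unname(tools::md5sum(full)),
             stringsAsFactors = FALSE)
}

write_manifest <- function(manifest, dir) {
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# All file output goes through these so line endings are LF everywhere.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

write_tsv_lf <- function(df, path, sep = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
}
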
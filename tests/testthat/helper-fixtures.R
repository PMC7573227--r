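# Shared in-code fixtures. Everything is built at test time; nothing binary
# ships with the package.

# The classic problematic lineage: classified genus below an unclassified
# family (phylum..species as printed, padded with a classified kingdom).
worked_example_lineage <- function() {
  lineage(c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
            "Enterobacteriales", NA, "Escherichia", NA))
}

# independent strictness oracle: classified flags must be non-increasing
strict_oracle <- function(lin) {
  flags <- as.integer(!is.na(lin))
  all(diff(flags) <= 0)
}

# small feature table with fully classified, hierarchically nested lineages
tiny_table <- function(n_features = 3L, n_samples = 2L, seed = 42L) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_features * n_samples, 10),
                     n_features, n_samples,
                     dimnames = list(sprintf("F%02d", seq_len(n_features)),
                                     sprintf("S%02d", seq_len(n_samples))))
    lin <- t(vapply(seq_len(n_features), function(i)
      c("Bacteria", paste0("P", (i - 1L) %/% 2L + 1L), paste0("C", i),
        paste0("O", i), paste0("Fa", i), paste0("G", i), paste0("Sp", i)),
      character(7)))
    feature_table(counts, lin)
  })
}

# a random table with gappy lineages, for round-trip and conservation tests
random_gappy_table <- function(n_features = 50L, n_samples = 8L,
                               gap_prob = 0.25, seed = 1L) {
  fx <- generate_fixture(withr::local_tempdir(), "anacapa",
                         n_samples = n_samples, n_features = n_features,
                         gap_prob = gap_prob, seed = seed)
  fx$truth$table
}

# sequence set whose serialized records have exactly `bytes` bytes each
uniform_sequence_set <- function(n, bytes) {
  ids <- sprintf("R%03d", seq_len(n))
  seq_len_each <- bytes - nchar(ids) - 3L
  sequence_set(stats::setNames(strrep("A", seq_len_each), ids))
}

# enumerate all 2^7 classified/unclassified masks over random names
all_gap_masks <- function(seed = 99L) {
  withr::with_seed(seed, {
    masks <- expand.grid(rep(list(c(TRUE, FALSE)), 7))
    names <- matrix(paste0("N", sample(1000, 128 * 7, replace = TRUE)),
                    128, 7)
    lapply(seq_len(128), function(i) {
      lin <- names[i, ]
      lin[unlist(masks[i, ])] <- NA_character_
      lin
    })
  })
}
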
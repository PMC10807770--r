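# Shared fixture builders. Everything is generated in code at test time.

# Random nonnegative expression matrix with dimnames, no constant columns
# (adds a distinct jitter row to make zero variance practically impossible).
rand_expression <- function(n = 20L, p = 30L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rgamma(n * p, shape = 2, rate = 0.5), nrow = n,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(p))))
  X
}

# A small random collection over a gene universe.
rand_collection <- function(gene_ids, n_sets = 10L, sizes = 5:12,
                            seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(gene_ids, sample(sizes, 1L))
  })
  names(sets) <- paste0("set", seq_len(n_sets))
  as_gene_set_collection(sets)
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
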
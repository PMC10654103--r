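# Fixture builders shared across the suite.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(len) paste(sample(aa20, len, replace = TRUE),
                                collapse = "")

make_genome <- function(id, phams, seqs) {
  pham_genome(id, phams, seqs)
}

# Paralog-free random table: each genome draws distinct phams from a
# shared universe; translations are random.
random_paralog_free_table <- function(n_genomes = 5, n_phams = 12,
                                      genes = 6, len = c(20, 60)) {
  universe <- sprintf("ph%02d", seq_len(n_phams))
  rows <- do.call(rbind, lapply(seq_len(n_genomes), function(i) {
    ph <- sample(universe, genes)
    data.frame(genome = sprintf("G%02d", i), pham = ph,
               translation = vapply(seq_len(genes), function(k) {
                 rand_seq(sample(len[1]:len[2], 1))
               }, character(1)), stringsAsFactors = FALSE)
  }))
  pham_table(rows)
}

# Block-structured similarity matrix: `sizes` blocks with `within`
# similarity inside a block and `between` across blocks.
block_matrix <- function(sizes, within, between, prefix = "B") {
  ids <- unlist(lapply(seq_along(sizes), function(k) {
    sprintf("%s%d_%02d", prefix, k, seq_len(sizes[k]))
  }))
  labels <- rep(seq_along(sizes), sizes)
  n <- length(ids)
  m <- matrix(between, n, n, dimnames = list(ids, ids))
  for (k in seq_along(sizes)) {
    idx <- which(labels == k)
    m[idx, idx] <- within
  }
  diag(m) <- 1
  m
}

# partition from a label vector keyed by genome id
partition_from_labels <- function(labels) {
  genome_partition(split(names(labels), labels))
}

minicorpus_path <- function() {
  system.file("extdata", "minicorpus.tsv", package = "peqclust",
              mustWork = TRUE)
}
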
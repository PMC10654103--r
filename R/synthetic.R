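# Synthetic pham tables with planted cluster structure.
#
# The generator emulates the data regime of a curated phage collection at
# desk scale: genomes within a planted cluster share a cluster-private core
# pham pool at high amino-acid identity, a small fraction of genes is drawn
# from a global pool shared across clusters (emulating horizontal genetic
# exchange), the remainder is genome-private, and occasional paralogs are
# truncated mutant copies so alignments exercise gaps.

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) {
  paste(sample(.aa20, len, replace = TRUE), collapse = "")
}

# substitute each residue with probability `rate`, uniformly over the 19
# other standard residues (no indels: expected identity to the ancestor is
# analytically ~ 1 - rate)
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.aa20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Specification for a synthetic pham table
#'
#' Defaults describe a scaled-down phage-like corpus with clean planted
#' structure: three clusters of six genomes, twenty genes each, 80% of
#' genes from a cluster-private core pool, 10% from a global pool shared
#' across clusters, the rest genome-private; 5% paralog rate; 5%
#' per-residue divergence from each pham's ancestral sequence; protein
#' lengths uniform on 50-200 aa.
#'
#' @param n_clusters Number of planted clusters.
#' @param genomes_per_cluster Genomes per planted cluster.
#' @param genes_per_genome Genes per genome (before paralogs).
#' @param core_pham_fraction Fraction of genes drawn from the cluster-core
#'   pool (every member carries the full core).
#' @param inter_cluster_shared_fraction Fraction of genes drawn from the
#'   global pool shared across clusters.
#' @param paralog_rate Per-gene probability of an extra (truncated,
#'   re-mutated) paralogous copy.
#' @param substitution_rate Per-residue substitution probability applied
#'   independently per genome copy relative to the pham ancestor.
#' @param length_range Integer range of ancestral protein lengths (aa).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_clusters = 3L,
                         genomes_per_cluster = 6L,
                         genes_per_genome = 20L,
                         core_pham_fraction = 0.8,
                         inter_cluster_shared_fraction = 0.1,
                         paralog_rate = 0.05,
                         substitution_rate = 0.05,
                         length_range = c(50L, 200L),
                         seed = 1L) {
  fr <- c(core_pham_fraction, inter_cluster_shared_fraction,
          paralog_rate, substitution_rate)
  if (any(fr < 0) || any(fr > 1)) {
    stop("fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (core_pham_fraction + inter_cluster_shared_fraction > 1) {
    stop("infeasible spec: core_pham_fraction + ",
         "inter_cluster_shared_fraction > 1", call. = FALSE)
  }
  stopifnot(n_clusters >= 1, genomes_per_cluster >= 1,
            genes_per_genome >= 1, length(length_range) == 2L,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  s <- list(n_clusters = as.integer(n_clusters),
            genomes_per_cluster = as.integer(genomes_per_cluster),
            genes_per_genome = as.integer(genes_per_genome),
            core_pham_fraction = core_pham_fraction,
            inter_cluster_shared_fraction = inter_cluster_shared_fraction,
            paralog_rate = paralog_rate,
            substitution_rate = substitution_rate,
            length_range = as.integer(length_range),
            seed = as.integer(seed))
  class(s) <- "fixture_spec"
  s
}

#' Generate a synthetic pham table with planted clusters
#'
#' Fully reproducible per seed (the caller's RNG state is restored on
#' exit). Genome ids are `C<k>_G<j>`; planted cluster labels are
#' `C1, C2, ...`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `table` (a [pham_table()]) and `partition` (the
#'   planted [genome_partition()]).
#' @export
generate_table <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)

  n_core <- round(spec$core_pham_fraction * spec$genes_per_genome)
  n_shared <- round(spec$inter_cluster_shared_fraction *
                      spec$genes_per_genome)
  n_private <- spec$genes_per_genome - n_core - n_shared
  rlen <- function() sample(spec$length_range[1]:spec$length_range[2], 1)

  # global pool shared across clusters; twice the per-genome draw so that
  # cross-cluster genomes overlap in roughly half their pool genes
  pool_size <- max(1L, 2L * n_shared)
  global_pool <- if (n_shared > 0) {
    setNames(vapply(seq_len(pool_size), function(i) random_protein(rlen()),
                    character(1)),
             sprintf("shared%03d", seq_len(pool_size)))
  } else character(0)

  rows <- list()
  clusters <- list()
  private_counter <- 0L
  for (k in seq_len(spec$n_clusters)) {
    core <- if (n_core > 0) {
      setNames(vapply(seq_len(n_core), function(i) random_protein(rlen()),
                      character(1)),
               sprintf("C%d_core%03d", k, seq_len(n_core)))
    } else character(0)
    ids <- sprintf("C%d_G%02d", k, seq_len(spec$genomes_per_cluster))
    clusters[[paste0("C", k)]] <- ids
    for (id in ids) {
      phams <- character(0); seqs <- character(0)
      add_gene <- function(pham, ancestor) {
        copy <- mutate_protein(ancestor, spec$substitution_rate)
        phams <<- c(phams, pham); seqs <<- c(seqs, copy)
        if (stats::runif(1) < spec$paralog_rate && nchar(ancestor) >= 10) {
          # truncated paralog: random 50-90% prefix, independently mutated
          cut <- max(5L, floor(nchar(ancestor) *
                                 stats::runif(1, 0.5, 0.9)))
          phams <<- c(phams, pham)
          seqs <<- c(seqs, mutate_protein(substr(ancestor, 1, cut),
                                          spec$substitution_rate))
        }
      }
      for (ph in names(core)) add_gene(ph, core[[ph]])
      if (n_shared > 0) {
        draw <- sample(names(global_pool), n_shared)
        for (ph in draw) add_gene(ph, global_pool[[ph]])
      }
      if (n_private > 0) {
        for (i in seq_len(n_private)) {
          private_counter <- private_counter + 1L
          phams <- c(phams, sprintf("priv%05d", private_counter))
          seqs <- c(seqs, random_protein(rlen()))
        }
      }
      rows[[id]] <- data.frame(genome = id, pham = phams,
                               translation = seqs,
                               stringsAsFactors = FALSE)
    }
  }
  list(table = pham_table(do.call(rbind, rows)),
       partition = genome_partition(clusters))
}
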
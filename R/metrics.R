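# Pairwise genome similarity metrics.
#
# All similarities are fractions in [0, 1]; distance = 1 - similarity.
# Notation follows the field: for genomes 1 and 2, P1/P2 are pham-set
# sizes, P_S the shared-pham count, T1/T2 total protein counts, C1/C2
# conserved (shared-pham) protein copies, L_T1/L_T2 summed protein
# lengths, and L_C1/L_C2 summed lengths of conserved copies.

#' Metric names
#'
#' The six supported genome similarity metrics. `peq` (proteomic
#' equivalence quotient, AF x AAI) is the default throughout the package.
#' @export
metric_names <- function() c("jc", "gcs", "pocp", "af", "aai", "peq")

match_metric <- function(metric) {
  match.arg(metric, metric_names())
}

#' Jaccard coefficient of two genomes' pham sets
#'
#' Shared phams over the union of phams; gene lengths and paralogs are
#' ignored.
#' @param a,b [pham_genome()] objects.
#' @return Fraction in [0, 1].
#' @export
jaccard <- function(a, b) {
  pa <- names(a$pham_counts); pb <- names(b$pham_counts)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

#' Gene content similarity
#'
#' `GCS = 2 * P_S / (P1 + P2)`: the bi-directional proportion of shared
#' phams. Like the Jaccard coefficient it ignores gene length and paralogs.
#' @param a,b [pham_genome()] objects.
#' @return Fraction in [0, 1].
#' @export
gcs <- function(a, b) {
  pa <- names(a$pham_counts); pb <- names(b$pham_counts)
  2 * length(intersect(pa, pb)) / (length(pa) + length(pb))
}

#' Percentage of conserved proteins
#'
#' `POCP = (C1 + C2) / (T1 + T2)` where C1/C2 count every protein copy
#' (paralogs included) whose pham is shared and T1/T2 are total protein
#' counts. Equals GCS on paralog-free genomes.
#' @param a,b [pham_genome()] objects.
#' @return Fraction in [0, 1].
#' @export
pocp <- function(a, b) {
  shared <- intersect(names(a$pham_counts), names(b$pham_counts))
  c1 <- sum(a$pham_counts[shared])
  c2 <- sum(b$pham_counts[shared])
  (c1 + c2) / (a$gene_count + b$gene_count)
}

#' Pair orthologous gene copies within a shared pham
#'
#' Each genome's copies of the pham are sorted by translation length,
#' descending (ties keep input order), and paired positionally up to the
#' smaller copy count. Unpaired copies take no part in AAI but their
#' lengths still count as conserved in AF.
#'
#' @param a,b [pham_genome()] objects.
#' @param pham A pham identifier present in both genomes.
#' @return A list of pairs; each element is a list with `seq_a`, `seq_b`,
#'   `len_a`, `len_b`.
#' @export
pair_orthologs <- function(a, b, pham) {
  ia <- which(a$phams == pham)
  ib <- which(b$phams == pham)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("pham ", pham, " is not shared by ", a$genome_id, " and ",
         b$genome_id, call. = FALSE)
  }
  # stable sort by decreasing length keeps input order on ties
  ia <- ia[order(-nchar(a$translations[ia]))]
  ib <- ib[order(-nchar(b$translations[ib]))]
  k <- min(length(ia), length(ib))
  lapply(seq_len(k), function(i) {
    list(seq_a = a$translations[ia[i]], seq_b = b$translations[ib[i]],
         len_a = nchar(a$translations[ia[i]]),
         len_b = nchar(b$translations[ib[i]]))
  })
}

#' Alignment fraction and average amino acid identity
#'
#' `AF = (L_C1 + L_C2) / (L_T1 + L_T2)`: the summed lengths of conserved
#' proteins (every copy in a shared pham) over the summed lengths of all
#' proteins in the pair. AAI is the length-weighted average global-alignment
#' percent identity over orthologous pairs produced by [pair_orthologs()],
#' with weight `len_a + len_b` per pair. Genomes with no shared phams score
#' AF = 0 and AAI = 0.
#'
#' @param a,b [pham_genome()] objects.
#' @param params An [alignment_params()] object.
#' @return Named numeric vector `c(af = , aai = )`.
#' @export
af_aai <- function(a, b, params = alignment_params()) {
  shared <- shared_phams(a, b)
  if (length(shared) == 0L) {
    return(c(af = 0, aai = 0))
  }
  l_c <- 0
  wsum <- 0
  wpid <- 0
  for (ph in shared) {
    l_c <- l_c + sum(nchar(a$translations[a$phams == ph])) +
      sum(nchar(b$translations[b$phams == ph]))
    for (pr in pair_orthologs(a, b, ph)) {
      aln <- tryCatch(align_global(pr$seq_a, pr$seq_b, params),
                      error = function(e) {
                        stop("alignment failed for pham ", ph, " (",
                             a$genome_id, " vs ", b$genome_id, "): ",
                             conditionMessage(e), call. = FALSE)
                      })
      w <- pr$len_a + pr$len_b
      wsum <- wsum + w
      wpid <- wpid + w * aln$percent_identity
    }
  }
  c(af = l_c / (a$total_length + b$total_length), aai = wpid / wsum)
}

#' Proteomic equivalence quotient
#'
#' `PEQ = AF x AAI`. 1.0 means all genes are shared with 100% amino-acid
#' identity; 0 means no shared phams.
#' @param a,b [pham_genome()] objects.
#' @param params An [alignment_params()] object.
#' @return Fraction in [0, 1].
#' @export
peq <- function(a, b, params = alignment_params()) {
  x <- af_aai(a, b, params)
  unname(x["af"] * x["aai"])
}

#' Similarity between two genomes under a named metric
#' @param a,b [pham_genome()] objects.
#' @param metric One of [metric_names()].
#' @param params An [alignment_params()] object (used by af/aai/peq).
#' @return Fraction in [0, 1].
#' @export
genome_similarity <- function(a, b, metric = "peq",
                              params = alignment_params()) {
  metric <- match_metric(metric)
  switch(metric,
         jc = jaccard(a, b),
         gcs = gcs(a, b),
         pocp = pocp(a, b),
         af = unname(af_aai(a, b, params)["af"]),
         aai = unname(af_aai(a, b, params)["aai"]),
         peq = peq(a, b, params))
}

#' Enumerate unordered index pairs for a set of genome identifiers
#'
#' The pairwise job list: all N(N-1)/2 unordered pairs, each exactly once,
#' in row-major order.
#' @param ids Character vector of genome identifiers (or any length-N set).
#' @return Two-column integer matrix of indices `i < j`.
#' @export
genome_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  }
  first <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  second <- sequence(rev(seq_len(n - 1L))) + first
  cbind(i = first, j = second)
}

#' Build a full pairwise similarity matrix
#'
#' Computes all unordered genome pairs exactly once (optionally across
#' forked workers; results are bit-identical regardless of worker count)
#' and assembles a symmetric matrix with unit diagonal.
#'
#' @param table A [pham_table()] with at least two genomes.
#' @param metric One of [metric_names()] (default `"peq"`).
#' @param params An [alignment_params()] object.
#' @param workers Positive integer number of parallel workers.
#' @return A symmetric numeric matrix with genome ids as dimnames, entries
#'   in [0, 1], diagonal 1.
#' @export
build_matrix <- function(table, metric = "peq", params = alignment_params(),
                         workers = 1L) {
  stopifnot(inherits(table, "pham_table"))
  metric <- match_metric(metric)
  if (!is.numeric(workers) || workers < 1) {
    stop("workers must be a positive integer", call. = FALSE)
  }
  workers <- as.integer(workers)
  ids <- names(table$genomes)
  if (length(ids) < 2L) {
    stop("need at least two genomes to build a similarity matrix",
         call. = FALSE)
  }
  pairs <- genome_pairs(ids)
  vals <- compute_pair_values(table, pairs, metric, params, workers)
  assemble_similarity(ids, pairs, vals)
}

# compute similarity for each row of `pairs`; parallel over forked workers
compute_pair_values <- function(table, pairs, metric, params, workers) {
  genomes <- table$genomes
  f <- function(k) {
    genome_similarity(genomes[[pairs[k, 1]]], genomes[[pairs[k, 2]]],
                      metric, params)
  }
  n <- nrow(pairs)
  if (n == 0L) return(numeric(0))
  if (workers > 1L && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(seq_len(n), f, mc.cores = workers,
                              mc.preschedule = TRUE))
  } else {
    vapply(seq_len(n), f, numeric(1))
  }
}

assemble_similarity <- function(ids, pairs, vals) {
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (nrow(pairs) > 0L) {
    m[pairs] <- vals
    m[pairs[, c(2, 1), drop = FALSE]] <- vals
  }
  m
}

#' Validate a similarity matrix
#'
#' Checks squareness, dimnames, symmetry, unit diagonal, and range [0, 1].
#' @param m Numeric matrix.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_similarity_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("similarity matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("similarity matrix must carry identical row/column genome ids",
         call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("similarity matrix contains non-finite entries", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(m - t(m)) > 1e-12)) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m) - 1) > 1e-12)) {
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  }
  invisible(m)
}

#' Convert between similarity and distance matrices
#'
#' Entrywise `1 - s`; the transformation is an involution, so applying it
#' to a distance matrix recovers the similarity matrix.
#' @param m Square numeric matrix.
#' @return Matrix of the same shape.
#' @export
to_distance <- function(m) {
  1 - m
}

#' Write a similarity (or distance) matrix as square TSV
#'
#' Genome ids appear as the first row and first column; values are printed
#' to six decimal places.
#' @param m Square named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  out <- cbind(genome = rownames(m),
               matrix(sprintf("%.6f", m), nrow = nrow(m),
                      dimnames = dimnames(m)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Named numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
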
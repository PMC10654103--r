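# Independent oracles used by the test suite. These are written from the
# definitions, not by calling the implementation paths they check.

# Plain-R Gotoh dynamic programming for global affine-gap alignment.
# Same scoring conventions as the package contract (gap of length L costs
# open + (L-1)*ext; ties prefer aligned over gap-in-seq2 over gap-in-seq1)
# but an entirely separate implementation using dense R matrices.
oracle_align <- function(s1, s2, open = 11, ext = 1) {
  sub <- peqclust_blosum62()
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)  # source state: 1=M, 2=X, 3=Y
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) {
    X[i, 1] <- -open - (i - 2) * ext
    tX[i, 1] <- if (i == 2) 1L else 2L
  }
  for (j in seq_len(m) + 1) {
    Y[1, j] <- -open - (j - 2) * ext
    tY[1, j] <- if (j == 2) 1L else 3L
  }
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- sub[a[i - 1], b[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(prev)  # first maximum: ties prefer M > X > Y
      M[i, j] <- prev[k] + s
      tM[i, j] <- k
      xo <- M[i - 1, j] - open; xe <- X[i - 1, j] - ext
      if (xo >= xe) { X[i, j] <- xo; tX[i, j] <- 1L }
      else          { X[i, j] <- xe; tX[i, j] <- 2L }
      yo <- M[i, j - 1] - open; ye <- Y[i, j - 1] - ext
      if (yo >= ye) { Y[i, j] <- yo; tY[i, j] <- 1L }
      else          { Y[i, j] <- ye; tY[i, j] <- 3L }
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)
  i <- n; j <- m; identities <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    len <- len + 1L
    if (state == 1) {
      if (a[i] == b[j]) identities <- identities + 1L
      state <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- tX[i + 1, j + 1]; i <- i - 1
    } else {
      state <- tY[i + 1, j + 1]; j <- j - 1
    }
  }
  list(score = max(fin), identities = identities, alignment_length = len)
}

# BLOSUM62 fetched once for the oracle (shared standard data, not the
# implementation under test)
peqclust_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Brute-force pair classification: loop over every unordered genome pair.
oracle_confusion <- function(ref_labels, pred_labels) {
  ids <- names(ref_labels)
  tp <- tn <- fp <- fn <- 0
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- ref_labels[ids[i]] == ref_labels[ids[j]]
      p <- pred_labels[ids[i]] == pred_labels[ids[j]]
      if (r && p) tp <- tp + 1
      else if (r && !p) fn <- fn + 1
      else if (!r && p) fp <- fp + 1
      else tn <- tn + 1
    }
  }
  confusion_counts(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Independent AF/AAI reference: re-enumerates shared phams, conserved
# lengths, and length-sorted ortholog pairs from the raw gene table
# (alignment identities come from align_global, whose agreement with the
# DP oracle is established separately).
oracle_af_aai <- function(table, id_a, id_b, params = alignment_params()) {
  df <- as.data.frame(table)
  da <- df[df$genome == id_a, ]
  db <- df[df$genome == id_b, ]
  shared <- intersect(unique(da$pham), unique(db$pham))
  if (length(shared) == 0) return(c(af = 0, aai = 0))
  lc <- 0; wsum <- 0; wpid <- 0
  for (ph in shared) {
    sa <- da$translation[da$pham == ph]
    sb <- db$translation[db$pham == ph]
    lc <- lc + sum(nchar(sa)) + sum(nchar(sb))
    sa <- sa[order(-nchar(sa))]
    sb <- sb[order(-nchar(sb))]
    for (k in seq_len(min(length(sa), length(sb)))) {
      pid <- align_global(sa[k], sb[k], params)$percent_identity
      w <- nchar(sa[k]) + nchar(sb[k])
      wsum <- wsum + w
      wpid <- wpid + w * pid
    }
  }
  c(af = lc / (sum(nchar(da$translation)) + sum(nchar(db$translation))),
    aai = wpid / wsum)
}

# Connected components of the thresholded similarity graph via igraph.
oracle_components <- function(m, threshold) {
  adj <- (m >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(lapply(split(names(comp), comp), sort))
}
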
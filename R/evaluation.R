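# Pair-counting comparison of two genome partitions.
#
# All counts are over unordered genome pairs and are computed with exact
# integer arithmetic (stored in doubles, exact below 2^53; half-weighted
# per-cluster counts are exact half-integers). Floating point enters only
# at the final ratios.

#' Construct unordered-pair confusion counts
#'
#' @param tp,tn,fp,fn Non-negative pair counts: tp = co-clustered in both
#'   partitions; tn = co-clustered in neither; fp = co-clustered in the
#'   predicted partition only; fn = co-clustered in the reference only.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  x <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (anyNA(x) || any(x < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp ", format(x$tp, big.mark = ","),
      ", tn ", format(x$tn, big.mark = ","),
      ", fp ", format(x$fp, big.mark = ","),
      ", fn ", format(x$fn, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# label vector keyed by genome id from a partition
partition_labels <- function(p) {
  df <- as.data.frame(p)
  setNames(df$cluster, df$genome)
}

check_same_genomes <- function(reference, predicted) {
  gr <- partition_genomes(reference)
  gp <- partition_genomes(predicted)
  if (!setequal(gr, gp)) {
    stop("partitions cover different genome sets; symmetric difference: ",
         paste(union(setdiff(gr, gp), setdiff(gp, gr)), collapse = ", "),
         call. = FALSE)
  }
  gr
}

#' Pair-counting confusion matrix between two partitions
#'
#' Every unordered genome pair is classified by whether it is co-clustered
#' in the reference and/or the predicted partition.
#'
#' @param reference,predicted [genome_partition()] objects over the same
#'   genome set.
#' @return A [confusion_counts()] object; the four counts sum to
#'   N(N-1)/2.
#' @export
pair_confusion <- function(reference, predicted) {
  genomes <- check_same_genomes(reference, predicted)
  lr <- partition_labels(reference)[genomes]
  lp <- partition_labels(predicted)[genomes]
  n <- length(genomes)
  cont <- table(lr, lp)
  tp <- sum(choose(cont, 2))
  ref_pairs <- sum(choose(rowSums(cont), 2))
  pred_pairs <- sum(choose(colSums(cont), 2))
  total <- choose(n, 2)
  confusion_counts(tp = tp,
                   tn = total - ref_pairs - pred_pairs + tp,
                   fp = pred_pairs - tp,
                   fn = ref_pairs - tp)
}

#' Per-reference-cluster confusion decomposition
#'
#' One row per reference cluster. tp and fn come from the cluster's
#' internal pairs; a predicted co-clustered pair joining a member to a
#' non-member contributes half an fp to each of the two reference clusters
#' it touches; the remaining cross pairs contribute half a tn each, so
#' with zero fp a cluster of size s among N genomes has
#' tn = s(N - s)/2. Rows sum exactly to the global counts. The
#' `predicted_cluster` column reports the predicted cluster holding the
#' plurality of the reference cluster's members.
#'
#' @param reference,predicted [genome_partition()] objects over the same
#'   genome set.
#' @return Data frame with columns `reference_cluster`,
#'   `predicted_cluster`, `size`, `tp`, `tn`, `fp`, `fn` (tn/fp may be
#'   half-integers).
#' @export
per_cluster_confusion <- function(reference, predicted) {
  genomes <- check_same_genomes(reference, predicted)
  lr <- partition_labels(reference)[genomes]
  lp <- partition_labels(predicted)[genomes]
  n <- length(genomes)
  cont <- table(lr, lp)           # reference x predicted overlap counts
  pred_sizes <- colSums(cont)
  rows <- lapply(rownames(cont), function(rc) {
    o <- cont[rc, ]               # overlaps of this reference cluster
    size <- sum(o)
    tp <- sum(choose(o, 2))
    # predicted pairs joining a member to a non-member, half-weighted
    fp <- sum(o * (pred_sizes - o)) / 2
    data.frame(reference_cluster = rc,
               predicted_cluster = names(o)[which.max(o)],
               size = size,
               tp = tp,
               tn = size * (n - size) / 2 - fp,
               fp = fp,
               fn = choose(size, 2) - tp,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$reference_cluster), , drop = FALSE]
}

#' Precision and sensitivity from pair confusion counts
#'
#' precision = tp/(tp + fp); sensitivity = tp/(tp + fn). An undefined
#' ratio (zero denominator) is returned as `NA` with a warning, never as a
#' silent zero.
#'
#' @param c A [confusion_counts()] object.
#' @return Named list with `precision` and `sensitivity`.
#' @export
precision_sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  precision <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else {
    warning("precision undefined: tp + fp = 0")
    NA_real_
  }
  sensitivity <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else {
    warning("sensitivity undefined: tp + fn = 0")
    NA_real_
  }
  list(precision = precision, sensitivity = sensitivity)
}

#' Matthews correlation coefficient over pair counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in [-1, 1]:
#' 1 for identical pair relations, 0 for chance-level agreement, -1 for
#' total disagreement. A zero marginal makes the value undefined; `NA` is
#' returned with a warning naming the empty marginal.
#'
#' @param c A [confusion_counts()] object.
#' @return Numeric in [-1, 1], or `NA`.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  marg <- c("tp+fp" = c$tp + c$fp, "tp+fn" = c$tp + c$fn,
            "tn+fp" = c$tn + c$fp, "tn+fn" = c$tn + c$fn)
  if (any(marg == 0)) {
    warning("MCC undefined: zero marginal (",
            paste(names(marg)[marg == 0], collapse = ", "), ")")
    return(NA_real_)
  }
  # product of square roots avoids overflow of the 4-way product
  (c$tp * c$tn - c$fp * c$fn) / prod(sqrt(marg))
}

#' Truncate (not round) to three decimals
#'
#' Presentation rule for reported scalar statistics (e.g. a sensitivity of
#' 272335/370650 = 0.7347... is reported as 0.734).
#' @param x Numeric.
#' @return `x` truncated toward zero at the third decimal.
#' @export
truncate3 <- function(x) {
  trunc(x * 1000) / 1000
}

#' Write an evaluation report comparing two partitions
#'
#' Emits a per-reference-cluster TSV (with a cumulative row) and a
#' key-value summary of global precision, sensitivity (3 decimals,
#' truncated) and MCC.
#'
#' @param reference,predicted [genome_partition()] objects.
#' @param path_table Path for the per-cluster TSV.
#' @param path_summary Path for the key-value summary text.
#' @return The global [confusion_counts()], invisibly.
#' @export
write_evaluation_report <- function(reference, predicted,
                                    path_table, path_summary) {
  df <- per_cluster_confusion(reference, predicted)
  global <- pair_confusion(reference, predicted)
  cum <- data.frame(reference_cluster = "Cumulative",
                    predicted_cluster = "",
                    size = sum(df$size),
                    tp = global$tp, tn = global$tn,
                    fp = global$fp, fn = global$fn,
                    stringsAsFactors = FALSE)
  write.table(rbind(df, cum), path_table, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ps <- suppressWarnings(precision_sensitivity(global))
  m <- suppressWarnings(mcc(global))
  lines <- c(
    sprintf("precision\t%s", format(truncate3(ps$precision))),
    sprintf("sensitivity\t%s", format(truncate3(ps$sensitivity))),
    sprintf("mcc\t%s", format(if (is.na(m)) NA else truncate3(m))),
    sprintf("tp\t%s", format(global$tp, scientific = FALSE)),
    sprintf("tn\t%s", format(global$tn, scientific = FALSE)),
    sprintf("fp\t%s", format(global$fp, scientific = FALSE)),
    sprintf("fn\t%s", format(global$fn, scientific = FALSE))
  )
  writeLines(lines, path_summary)
  invisible(global)
}
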
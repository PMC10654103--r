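# Greedy threshold-based agglomerative clustering, the two-iteration
# cluster workflow, medoid selection, and subclustering.

#' Clustering configuration
#'
#' Defaults reproduce the two-iteration workflow: complete-linkage
#' pre-clustering at similarity >= 0.75 to form homogeneous groups,
#' average-linkage clustering of group medoids at >= 0.25, and optional
#' single-linkage subclustering at >= 0.60 for clusters of at least
#' `subcluster_min_size` genomes. Thresholds are fractions in (0, 1].
#'
#' @param metric One of [metric_names()] (default `"peq"`).
#' @param precluster_threshold Complete-linkage pre-clustering threshold.
#' @param cluster_threshold Medoid clustering threshold.
#' @param cluster_linkage Linkage for the medoid clustering step.
#' @param subcluster_threshold Subclustering threshold.
#' @param subcluster_linkage Linkage for subclustering.
#' @param subcluster_enabled Perform subclustering at all?
#' @param subcluster_min_size Only subcluster clusters of at least this
#'   many genomes (default 5).
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(metric = "peq",
                              precluster_threshold = 0.75,
                              cluster_threshold = 0.25,
                              cluster_linkage = "average",
                              subcluster_threshold = 0.60,
                              subcluster_linkage = "single",
                              subcluster_enabled = TRUE,
                              subcluster_min_size = 5L) {
  metric <- match_metric(metric)
  cluster_linkage <- match.arg(cluster_linkage,
                               c("average", "single", "complete"))
  subcluster_linkage <- match.arg(subcluster_linkage,
                                  c("single", "average", "complete"))
  if (!(cluster_threshold > 0 && cluster_threshold <= precluster_threshold &&
        precluster_threshold <= 1)) {
    stop("need 0 < cluster_threshold <= precluster_threshold <= 1",
         call. = FALSE)
  }
  if (!(subcluster_threshold > 0 && subcluster_threshold <= 1)) {
    stop("need 0 < subcluster_threshold <= 1", call. = FALSE)
  }
  if (subcluster_min_size < 2) {
    stop("subcluster_min_size must be at least 2", call. = FALSE)
  }
  cfg <- list(metric = metric,
              precluster_threshold = precluster_threshold,
              cluster_threshold = cluster_threshold,
              cluster_linkage = cluster_linkage,
              subcluster_threshold = subcluster_threshold,
              subcluster_linkage = subcluster_linkage,
              subcluster_enabled = isTRUE(subcluster_enabled),
              subcluster_min_size = as.integer(subcluster_min_size))
  class(cfg) <- "clustering_config"
  cfg
}

#' Construct a genome partition
#'
#' @param clusters Named list of character vectors; every genome appears in
#'   exactly one cluster and clusters are non-empty.
#' @param subclusters Optional named list (keyed by cluster name) of named
#'   lists of character vectors; each must partition its cluster's members
#'   exactly.
#' @return An object of class `genome_partition`.
#' @export
genome_partition <- function(clusters, subclusters = NULL) {
  stopifnot(is.list(clusters), length(clusters) >= 1L,
            !is.null(names(clusters)), !anyDuplicated(names(clusters)))
  members <- unlist(clusters, use.names = FALSE)
  if (any(lengths(clusters) < 1L)) {
    stop("clusters must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("genome(s) assigned to more than one cluster: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(subclusters)) {
    stopifnot(is.list(subclusters))
    for (cn in names(subclusters)) {
      subs <- subclusters[[cn]]
      if (!setequal(unlist(subs, use.names = FALSE), clusters[[cn]]) ||
          anyDuplicated(unlist(subs, use.names = FALSE))) {
        stop("subclusters of ", cn, " do not partition its members",
             call. = FALSE)
      }
    }
  }
  p <- list(clusters = clusters, subclusters = subclusters)
  class(p) <- "genome_partition"
  p
}

#' @export
print.genome_partition <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("<genome_partition> ", sum(sizes), " genomes in ", length(sizes),
      " clusters (", sum(sizes == 1L), " singletons)",
      if (!is.null(x$subclusters)) paste0("; ",
        sum(lengths(x$subclusters)), " subclusters"), "\n", sep = "")
  invisible(x)
}

#' All genome ids covered by a partition
#' @param p A [genome_partition()].
#' @return Character vector (sorted).
#' @export
partition_genomes <- function(p) {
  sort(unlist(p$clusters, use.names = FALSE))
}

# Name member lists by the published convention: multi-genome clusters are
# numbered 1, 2, 3, ... in descending size (ties by lexicographically
# smallest member); singleton clusters are named after their genome.
# Returns a named list ordered by descending size.
name_clusters <- function(member_lists) {
  member_lists <- lapply(member_lists, sort)
  smallest <- vapply(member_lists, `[`, character(1), 1)
  ord <- order(-lengths(member_lists), smallest)
  member_lists <- member_lists[ord]
  sizes <- lengths(member_lists)
  nm <- character(length(member_lists))
  nm[sizes == 1L] <- vapply(member_lists[sizes == 1L], `[`, character(1), 1)
  nm[sizes > 1L] <- as.character(seq_len(sum(sizes > 1L)))
  setNames(member_lists, nm)
}

# linkage test: may `cand` (genome indices) be joined with `grp` at
# threshold t, given similarity matrix m?
linkage_ok <- function(m, cand, grp, threshold, linkage) {
  cross <- m[cand, grp, drop = FALSE]
  switch(linkage,
         single = TRUE,  # the linking pair already met the threshold
         complete = min(cross) >= threshold,
         average = mean(cross) >= threshold)
}

#' Greedy threshold agglomeration
#'
#' Processes every unordered genome pair with similarity at or above the
#' threshold in descending order of similarity (ties broken
#' lexicographically on (min id, max id)). A pair of unassigned genomes
#' founds a new cluster; an unassigned genome joins an existing cluster if
#' the linkage criterion against all current members holds (complete:
#' minimum similarity >= threshold; average: mean >= threshold; single:
#' always, since the linking pair meets the threshold); two existing
#' clusters merge if the criterion holds over all cross-pairs. Genomes left
#' unassigned become singletons. Under single linkage the result equals the
#' connected components of the thresholded similarity graph.
#'
#' @param m Similarity matrix (see [validate_similarity_matrix()]).
#' @param threshold Fraction in (0, 1].
#' @param linkage One of `"single"`, `"average"`, `"complete"`.
#' @return A [genome_partition()] (no subclusters), clusters named by
#'   descending size, singletons named after their genome.
#' @export
greedy_agglomerate <- function(m, threshold, linkage = "average") {
  validate_similarity_matrix(m)
  linkage <- match.arg(linkage, c("single", "average", "complete"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  ids <- rownames(m)
  n <- length(ids)
  pairs <- genome_pairs(ids)
  if (nrow(pairs) > 0L) {
    sims <- m[pairs]
    keep <- sims >= threshold
    pairs <- pairs[keep, , drop = FALSE]
    sims <- sims[keep]
    lo <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
    hi <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
    ord <- order(-sims, lo, hi)
    pairs <- pairs[ord, , drop = FALSE]
  }
  assign <- integer(n)           # 0 = unassigned, else cluster id
  members <- list()              # cluster id -> integer indices
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ci <- assign[i]; cj <- assign[j]
    if (ci == 0L && cj == 0L) {
      members[[length(members) + 1L]] <- c(i, j)
      assign[c(i, j)] <- length(members)
    } else if (ci == cj) {
      next
    } else if (ci == 0L || cj == 0L) {
      u <- if (ci == 0L) i else j
      cl <- max(ci, cj)
      if (linkage_ok(m, u, members[[cl]], threshold, linkage)) {
        members[[cl]] <- c(members[[cl]], u)
        assign[u] <- cl
      }
    } else {
      if (linkage_ok(m, members[[ci]], members[[cj]], threshold, linkage)) {
        members[[ci]] <- c(members[[ci]], members[[cj]])
        assign[members[[cj]]] <- ci
        members[[cj]] <- integer(0)
      }
    }
  }
  out <- Filter(function(x) length(x) > 0L, members)
  out <- lapply(out, function(ix) ids[ix])
  out <- c(out, as.list(ids[assign == 0L]))
  genome_partition(name_clusters(out))
}

#' Select the medoid of a group of genomes
#'
#' The member with the highest mean similarity to the remaining members;
#' a singleton's medoid is itself; ties break lexicographically by id.
#'
#' @param members Character vector of genome ids present in `m`.
#' @param m Similarity matrix.
#' @return A genome id.
#' @export
select_medoid <- function(members, m) {
  stopifnot(length(members) >= 1L)
  if (!all(members %in% rownames(m))) {
    stop("member(s) absent from the similarity matrix: ",
         paste(setdiff(members, rownames(m)), collapse = ", "),
         call. = FALSE)
  }
  if (length(members) == 1L) return(members)
  sub <- m[members, members, drop = FALSE]
  means <- (rowSums(sub) - diag(sub)) / (length(members) - 1)
  members[order(-means, members)][1]
}

#' Two-iteration greedy clustering
#'
#' (1) Complete-linkage greedy agglomeration at the pre-clustering
#' threshold yields homogeneous pre-groups; (2) the medoid of each
#' pre-group is selected as its representative; (3) the medoids are
#' agglomerated on their submatrix at the cluster threshold (average
#' linkage by default); (4) every pre-group joins the cluster of its
#' medoid wholesale. Clusters are named by descending size (1, 2, 3, ...),
#' singletons after their genome.
#'
#' @param m Similarity matrix.
#' @param config A [clustering_config()].
#' @return A [genome_partition()] (no subclusters yet).
#' @export
two_step_cluster <- function(m, config = clustering_config()) {
  validate_similarity_matrix(m)
  stopifnot(inherits(config, "clustering_config"))
  if (nrow(m) == 1L) {
    return(genome_partition(name_clusters(list(rownames(m)))))
  }
  pre <- greedy_agglomerate(m, config$precluster_threshold, "complete")
  groups <- pre$clusters
  medoids <- vapply(groups, select_medoid, character(1), m = m)
  if (length(medoids) == 1L) {
    return(genome_partition(name_clusters(list(unlist(groups,
                                                      use.names = FALSE)))))
  }
  sub <- m[medoids, medoids, drop = FALSE]
  med_part <- greedy_agglomerate(sub, config$cluster_threshold,
                                 config$cluster_linkage)
  final <- lapply(med_part$clusters, function(ms) {
    unlist(groups[match(ms, medoids)], use.names = FALSE)
  })
  genome_partition(name_clusters(final))
}

#' Subcluster the non-singleton clusters of a partition
#'
#' Each cluster with at least `subcluster_min_size` members is subdivided
#' by greedy agglomeration at the subcluster threshold (single linkage by
#' default) over its own submatrix. Subclusters are named
#' `<cluster>_<ordinal>` by descending size. Smaller clusters, or all
#' clusters when subclustering is disabled, carry no subclusters.
#'
#' @param p A [genome_partition()] over the genomes of `m`.
#' @param m Similarity matrix.
#' @param config A [clustering_config()].
#' @return The partition with a `subclusters` component.
#' @export
subcluster_partition <- function(p, m, config = clustering_config()) {
  stopifnot(inherits(p, "genome_partition"))
  validate_similarity_matrix(m)
  if (!config$subcluster_enabled) {
    return(p)
  }
  subs <- list()
  for (cn in names(p$clusters)) {
    mem <- p$clusters[[cn]]
    if (length(mem) < config$subcluster_min_size) next
    part <- greedy_agglomerate(m[mem, mem, drop = FALSE],
                               config$subcluster_threshold,
                               config$subcluster_linkage)
    groups <- unname(part$clusters)   # already size-desc, tie by member
    subs[[cn]] <- setNames(groups,
                           paste0(cn, "_", seq_along(groups)))
  }
  genome_partition(p$clusters, if (length(subs)) subs else NULL)
}

#' Group counts across a threshold sweep
#'
#' Agglomerates a set of genomes at each threshold and reports the number
#' of groups formed; under single linkage the count is non-decreasing in
#' the threshold.
#'
#' @param m Similarity matrix.
#' @param members Genome ids to sweep (subset of `rownames(m)`).
#' @param thresholds Ascending fractions in (0, 1].
#' @param linkage Linkage rule.
#' @return Data frame with columns `threshold` and `n_groups`.
#' @export
subcluster_count_sweep <- function(m, members, thresholds,
                                   linkage = "single") {
  stopifnot(length(members) >= 1L, all(members %in% rownames(m)))
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  sub <- m[members, members, drop = FALSE]
  counts <- vapply(thresholds, function(t) {
    length(greedy_agglomerate(sub, t, linkage)$clusters)
  }, integer(1))
  data.frame(threshold = thresholds, n_groups = counts)
}

#' Convert a partition to a data frame
#' @param x A [genome_partition()].
#' @param ... Unused.
#' @return Data frame with columns `genome`, `cluster`, and (when
#'   subclusters exist) `subcluster` (`NA` for unsubclustered clusters).
#' @export
as.data.frame.genome_partition <- function(x, ...) {
  df <- do.call(rbind, lapply(names(x$clusters), function(cn) {
    data.frame(genome = x$clusters[[cn]], cluster = cn,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(x$subclusters)) {
    df$subcluster <- NA_character_
    for (cn in names(x$subclusters)) {
      for (sn in names(x$subclusters[[cn]])) {
        df$subcluster[df$genome %in% x$subclusters[[cn]][[sn]]] <- sn
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a partition as TSV
#'
#' Two columns (genome, cluster), or three when subclusters are present.
#' @param p A [genome_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a partition from TSV
#'
#' Accepts the dialect of [write_partition_tsv()]: columns genome and
#' cluster, optionally subcluster.
#' @param path Input path.
#' @return A [genome_partition()].
#' @export
read_partition_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  if (ncol(df) < 2L) {
    stop("partition file must have at least genome and cluster columns",
         call. = FALSE)
  }
  names(df)[1:2] <- c("genome", "cluster")
  clusters <- split(df$genome, df$cluster)
  subclusters <- NULL
  if (ncol(df) >= 3L) {
    names(df)[3] <- "subcluster"
    has <- !is.na(df$subcluster)
    if (any(has)) {
      subclusters <- lapply(split(df[has, ], df$cluster[has]), function(d) {
        split(d$genome, d$subcluster)
      })
      # only keep clusters fully covered by subclusters
      subclusters <- subclusters[vapply(names(subclusters), function(cn) {
        setequal(unlist(subclusters[[cn]]), clusters[[cn]])
      }, logical(1))]
      if (length(subclusters) == 0L) subclusters <- NULL
    }
  }
  genome_partition(clusters, subclusters)
}
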
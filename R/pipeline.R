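# Run orchestration: matrix construction with an on-disk pair cache,
# clustering, per-cluster outputs, heatmaps, evaluation, and a run log.

cache_file_name <- function(metric, params) {
  sprintf("pairwise_%s_%s_%d_%d.tsv", metric, params$substitution_matrix,
          params$gap_open, params$gap_extend)
}

# Build the full matrix, reusing cached pair scores when a cache file
# exists. Returns list(matrix, computed, reused); writes the cache back
# when `write_cache` is TRUE.
build_matrix_cached <- function(table, metric, params, workers,
                                cache_path = NULL, write_cache = FALSE) {
  ids <- names(table$genomes)
  pairs <- genome_pairs(ids)
  vals <- rep(NA_real_, nrow(pairs))
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cache <- read.delim(cache_path, stringsAsFactors = FALSE)
    key <- paste(cache$genome_a, cache$genome_b, sep = "\r")
    want <- paste(pmin(ids[pairs[, 1]], ids[pairs[, 2]]),
                  pmax(ids[pairs[, 1]], ids[pairs[, 2]]), sep = "\r")
    hit <- match(want, key)
    vals[!is.na(hit)] <- cache$similarity[hit[!is.na(hit)]]
  }
  todo <- which(is.na(vals))
  if (length(todo) > 0L) {
    vals[todo] <- compute_pair_values(table,
                                      pairs[todo, , drop = FALSE],
                                      metric, params, workers)
  }
  if (write_cache && !is.null(cache_path)) {
    out <- data.frame(genome_a = pmin(ids[pairs[, 1]], ids[pairs[, 2]]),
                      genome_b = pmax(ids[pairs[, 1]], ids[pairs[, 2]]),
                      similarity = vals, stringsAsFactors = FALSE)
    write.table(out, cache_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(matrix = assemble_similarity(ids, pairs, vals),
       computed = length(todo),
       reused = nrow(pairs) - length(todo))
}

heat_color <- function(v) {
  # white (0) to a deep blue (1)
  r <- round(255 + (33 - 255) * v)
  g <- round(255 + (102 - 255) * v)
  b <- round(255 + (172 - 255) * v)
  sprintf("#%02X%02X%02X", r, g, b)
}

#' Write a standalone HTML heatmap for a group of genomes
#'
#' Genomes are ordered medoid-first, then by descending similarity to the
#' medoid (ties by id); cells show similarity rendered as a percentage on
#' a white-to-blue scale.
#'
#' @param members At least two genome ids present in `m`.
#' @param m Similarity matrix.
#' @param path Output HTML path.
#' @param title Document title (defaults to the file name).
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(members, m, path,
                          title = basename(path)) {
  validate_similarity_matrix(m[members, members, drop = FALSE])
  if (length(members) < 2L) {
    stop("a heatmap needs at least two genomes", call. = FALSE)
  }
  med <- select_medoid(members, m)
  rest <- setdiff(members, med)
  rest <- rest[order(-m[med, rest], rest)]
  ord <- c(med, rest)
  sub <- m[ord, ord, drop = FALSE]
  cells <- function(i) {
    paste0(vapply(seq_along(ord), function(j) {
      v <- sub[i, j]
      sprintf('<td style="background:%s;color:%s">%.1f</td>',
              heat_color(v), if (v > 0.6) "#FFFFFF" else "#000000",
              100 * v)
    }, character(1)), collapse = "")
  }
  rows <- vapply(seq_along(ord), function(i) {
    paste0("<tr><th>", ord[i], "</th>", cells(i), "</tr>")
  }, character(1))
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", title, "</title>"),
    "<style>",
    "table{border-collapse:collapse;font-family:sans-serif;font-size:11px}",
    "td,th{border:1px solid #ccc;padding:3px 6px;text-align:right}",
    "th{background:#f4f4f4;text-align:left}",
    "</style></head><body>",
    paste0("<h1>", title, "</h1>"),
    "<p>Pairwise similarity (%), medoid-first ordering.</p>",
    "<table>",
    paste0("<tr><th></th>",
           paste0("<th>", ord, "</th>", collapse = ""), "</tr>"),
    rows,
    "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Run the full clustering pipeline
#'
#' Parses the input table, builds the pairwise similarity matrix (with an
#' on-disk cache under `<outdir>/temp` reused across runs when
#' `keep_temp`), clusters and optionally subclusters, and writes all
#' artifacts: the full matrix, per-cluster and per-subcluster matrices,
#' the partition TSV, one HTML heatmap per non-singleton cluster, an
#' evaluation report when a reference partition is supplied, and a run
#' log with parameters and timings. On error, partial outputs are removed
#' unless `keep_temp` is set.
#'
#' @param input Path to a pham-table TSV, or a [pham_table()] object.
#' @param outdir Output directory (created if absent).
#' @param config A [clustering_config()].
#' @param params An [alignment_params()].
#' @param workers Positive integer of parallel workers.
#' @param keep_temp Keep (and reuse) cached pairwise scores and partial
#'   outputs.
#' @param reference Optional path to (or [genome_partition()] of) a
#'   reference partition; triggers the evaluation report.
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (named paths), `matrix`, and `partition`.
#' @export
run_pipeline <- function(input, outdir,
                         config = clustering_config(),
                         params = alignment_params(),
                         workers = 1L,
                         keep_temp = FALSE,
                         reference = NULL) {
  stopifnot(inherits(config, "clustering_config"),
            inherits(params, "alignment_params"))
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  artifacts <- character(0)
  created <- character(0)
  note <- function(name, path, track = TRUE) {
    artifacts[name] <<- path
    if (track) created <<- c(created, path)
    path
  }
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  run <- function() {
    table <- if (inherits(input, "pham_table")) input else
      parse_pham_tsv(input)
    say("loaded ", length(table$genomes), " genomes, ",
        length(table$pham_universe), " phams")
    say("metric=", config$metric,
        " matrix=", params$substitution_matrix,
        " gap_open=", params$gap_open, " gap_extend=", params$gap_extend,
        " workers=", workers)
    say("precluster: complete linkage, threshold ",
        config$precluster_threshold)
    say("cluster: ", config$cluster_linkage, " linkage, threshold ",
        config$cluster_threshold)
    say(if (config$subcluster_enabled)
      paste0("subcluster: ", config$subcluster_linkage,
             " linkage, threshold ", config$subcluster_threshold,
             ", min size ", config$subcluster_min_size)
      else "subcluster: disabled")

    temp_dir <- file.path(outdir, "temp")
    cache_path <- NULL
    if (keep_temp) {
      dir.create(temp_dir, showWarnings = FALSE)
      cache_path <- file.path(temp_dir,
                              cache_file_name(config$metric, params))
    }
    bm <- build_matrix_cached(table, config$metric, params, workers,
                              cache_path, write_cache = keep_temp)
    m <- bm$matrix
    say("pairwise scores: ", bm$computed, " computed, ", bm$reused,
        " reused from cache")
    write_matrix_tsv(m, note("matrix", file.path(
      outdir, paste0("matrix_", config$metric, ".tsv"))))

    p <- two_step_cluster(m, config)
    p <- subcluster_partition(p, m, config)
    say("clusters: ", length(p$clusters), " (",
        sum(lengths(p$clusters) == 1L), " singletons)")
    write_partition_tsv(p, note("partition",
                                file.path(outdir, "partition.tsv")))

    cdir <- file.path(outdir, "clusters")
    hdir <- file.path(outdir, "heatmaps")
    dir.create(cdir, showWarnings = FALSE)
    dir.create(hdir, showWarnings = FALSE)
    for (cn in names(p$clusters)) {
      mem <- p$clusters[[cn]]
      if (length(mem) < 2L) next
      write_matrix_tsv(m[mem, mem],
                       note(paste0("cluster_matrix_", cn),
                            file.path(cdir, paste0(cn, "_similarity.tsv"))))
      write_heatmap(mem, m,
                    note(paste0("heatmap_", cn),
                         file.path(hdir, paste0(cn, ".html"))),
                    title = paste("Cluster", cn))
      for (sn in names(p$subclusters[[cn]])) {
        smem <- p$subclusters[[cn]][[sn]]
        if (length(smem) < 2L) next
        write_matrix_tsv(m[smem, smem],
                         note(paste0("subcluster_matrix_", sn),
                              file.path(cdir,
                                        paste0(sn, "_similarity.tsv"))))
      }
    }

    if (!is.null(reference)) {
      ref <- if (inherits(reference, "genome_partition")) reference else
        read_partition_tsv(reference)
      global <- write_evaluation_report(
        ref, p,
        note("evaluation", file.path(outdir, "evaluation.tsv")),
        note("summary", file.path(outdir, "evaluation_summary.txt")))
      ps <- suppressWarnings(precision_sensitivity(global))
      say("evaluation: precision ", format(truncate3(ps$precision)),
          ", sensitivity ", format(truncate3(ps$sensitivity)))
    }
    say("done in ",
        sprintf("%.1f s", as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))))
    writeLines(c(paste0("peqclust ",
                        as.character(utils::packageVersion("peqclust")),
                        " / ", R.version.string),
                 log_lines),
               note("log", file.path(outdir, "run.log")))
    list(status = 0L, artifacts = artifacts, matrix = m, partition = p)
  }
  tryCatch(invisible(run()), error = function(e) {
    if (!keep_temp) unlink(created)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}
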
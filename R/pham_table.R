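# Genome -> pham -> translation tables.
#
# The input dialect is the three-column TSV emitted by pham-assembly
# pipelines: genome identifier, pham identifier, amino-acid translation.
# Duplicate (genome, pham) rows are paralogs and are retained.

#' Standard amino-acid alphabet accepted in translations
#'
#' The 20 standard residues plus the ambiguity character X. Translations are
#' uppercased on ingest and terminal stop/gap characters (`*`, `-`) are
#' stripped; internal stops or gaps are rejected as corrupt input.
#' @keywords internal
.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Uppercase, strip terminal * / -, and validate residues.
# Returns the cleaned string or stops with `where` in the message.
clean_translation <- function(x, where = "translation") {
  x <- toupper(trimws(x))
  x <- sub("^[*-]+", "", x)
  x <- sub("[*-]+$", "", x)
  if (!nzchar(x)) {
    stop("empty translation (", where, ")", call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad) > 0) {
    stop("invalid residue character(s) ", paste0("'", bad, "'", collapse = ", "),
         " (", where, ")", call. = FALSE)
  }
  x
}

is_valid_translation <- function(x) {
  x <- sub("[*-]+$", "", sub("^[*-]+", "", toupper(trimws(x))))
  nzchar(x) &&
    all(strsplit(x, "", fixed = TRUE)[[1]] %in% .aa_alphabet)
}

#' Construct a genome from its gene records
#'
#' @param genome_id Genome identifier (unique within a table).
#' @param phams Character vector of pham identifiers, one per gene, in
#'   input order.
#' @param translations Character vector of amino-acid translations parallel
#'   to `phams`.
#' @return An object of class `pham_genome` with fields `genome_id`,
#'   `phams`, `translations`, `pham_counts` (pham multiset as a named
#'   integer vector), `gene_count`, and `total_length` (summed amino-acid
#'   lengths, the AF denominator contribution).
#' @export
pham_genome <- function(genome_id, phams, translations) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id),
            length(phams) == length(translations), length(phams) >= 1L)
  phams <- as.character(phams)
  translations <- vapply(seq_along(translations), function(i) {
    clean_translation(translations[[i]],
                      where = paste0(genome_id, " gene ", i))
  }, character(1))
  counts <- table(phams)
  g <- list(
    genome_id = genome_id,
    phams = phams,
    translations = translations,
    pham_counts = setNames(as.integer(counts), names(counts)),
    gene_count = length(phams),
    total_length = sum(nchar(translations))
  )
  class(g) <- "pham_genome"
  g
}

#' @export
print.pham_genome <- function(x, ...) {
  cat("<pham_genome> ", x$genome_id, ": ", x$gene_count, " genes, ",
      length(x$pham_counts), " phams, ", x$total_length, " aa\n", sep = "")
  invisible(x)
}

#' Construct a pham table from a long-format data frame
#'
#' @param genes A data frame with columns `genome`, `pham`, `translation`
#'   (one row per gene; duplicate (genome, pham) rows are paralogs).
#' @return An object of class `pham_table`: a named list of
#'   [pham_genome()] objects (`genomes`, keyed and ordered by first
#'   appearance) plus the `pham_universe` (union of all pham identifiers).
#' @export
pham_table <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("genome", "pham", "translation") %in% names(genes)))
  if (nrow(genes) == 0L) {
    stop("empty pham table: no gene rows", call. = FALSE)
  }
  ids <- unique(as.character(genes$genome))
  genomes <- lapply(ids, function(id) {
    rows <- genes[genes$genome == id, , drop = FALSE]
    pham_genome(id, as.character(rows$pham), as.character(rows$translation))
  })
  names(genomes) <- ids
  tab <- list(
    genomes = genomes,
    pham_universe = sort(unique(unlist(lapply(genomes,
                                              function(g) names(g$pham_counts)))))
  )
  class(tab) <- "pham_table"
  tab
}

#' @export
print.pham_table <- function(x, ...) {
  cat("<pham_table> ", length(x$genomes), " genomes, ",
      length(x$pham_universe), " phams, ",
      sum(vapply(x$genomes, `[[`, integer(1), "gene_count")), " genes\n",
      sep = "")
  invisible(x)
}

#' Parse a genome-to-pham-to-translation TSV file
#'
#' Reads the three-column tab-separated dialect (genome, pham, translation;
#' no quoting, UTF-8). A single leading header line is tolerated and
#' auto-detected: if the third field of the first line is not a valid
#' residue string it is treated as a header.
#'
#' @param path Path to the TSV file.
#' @return A [pham_table()].
#' @export
parse_pham_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty pham table: ", path, " has no gene rows", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1]
    stop("malformed line ", line_no[bad], " in ", path,
         ": expected 3 tab-separated fields, found ", nf[bad], call. = FALSE)
  }
  # header auto-detection on the first line only
  if (!is_valid_translation(fields[[1]][3])) {
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0L) {
      stop("empty pham table: ", path, " has no gene rows", call. = FALSE)
    }
  }
  mat <- do.call(rbind, fields)
  genes <- data.frame(genome = mat[, 1], pham = mat[, 2],
                      translation = mat[, 3], stringsAsFactors = FALSE)
  # validate translations with 1-based line numbers before construction
  for (i in seq_len(nrow(genes))) {
    ok <- tryCatch({ clean_translation(genes$translation[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop("malformed line ", line_no[i], " in ", path, ": ", ok,
           call. = FALSE)
    }
  }
  pham_table(genes)
}

#' Write a pham table in the input TSV dialect
#'
#' @param table A [pham_table()].
#' @param path Output file path.
#' @param header Write a `genome  pham  translation` header line
#'   (default `FALSE`, matching the minimal upstream dialect).
#' @return `path`, invisibly.
#' @export
write_pham_tsv <- function(table, path, header = FALSE) {
  stopifnot(inherits(table, "pham_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines("genome\tpham\ttranslation", con)
  for (g in table$genomes) {
    writeLines(paste(g$genome_id, g$phams, g$translations, sep = "\t"), con)
  }
  invisible(path)
}

#' Convert a pham table to a long-format data frame
#' @param x A [pham_table()].
#' @param ... Unused.
#' @return Data frame with columns `genome`, `pham`, `translation`.
#' @export
as.data.frame.pham_table <- function(x, ...) {
  do.call(rbind, lapply(x$genomes, function(g) {
    data.frame(genome = g$genome_id, pham = g$phams,
               translation = g$translations, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Phams shared by a pair of genomes
#'
#' Set intersection of the two genomes' pham repertoires (paralog copy
#' counts ignored); symmetric in its arguments.
#'
#' @param a,b [pham_genome()] objects.
#' @return Character vector of shared pham identifiers (sorted).
#' @export
shared_phams <- function(a, b) {
  stopifnot(inherits(a, "pham_genome"), inherits(b, "pham_genome"))
  sort(intersect(names(a$pham_counts), names(b$pham_counts)))
}
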
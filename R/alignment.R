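# Needleman-Wunsch global protein alignment (affine gaps).

# cache for substitution matrices pulled from Biostrings' data sets
.matrix_cache <- new.env(parent = emptyenv())

get_substitution_matrix <- function(name) {
  if (!exists(name, envir = .matrix_cache, inherits = FALSE)) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = e)) {
      stop("unknown substitution matrix: ", name, call. = FALSE)
    }
    m <- get(name, envir = e)
    storage.mode(m) <- "integer"
    assign(name, m, envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache, inherits = FALSE)
}

#' Alignment parameters
#'
#' @param substitution_matrix Name of a standard scoring matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open Positive gap-opening penalty (default 11). A gap of
#'   length L costs `gap_open + (L - 1) * gap_extend`: the opening column
#'   carries the opening penalty.
#' @param gap_extend Positive gap-extension penalty (default 1).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || is.na(gap_extend) ||
      gap_open < gap_extend || gap_extend < 0) {
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0",
         call. = FALSE)
  }
  get_substitution_matrix(substitution_matrix)  # fail early on unknown name
  p <- list(substitution_matrix = substitution_matrix,
            gap_open = gap_open, gap_extend = gap_extend)
  class(p) <- "alignment_params"
  p
}

# translate a residue string into 0-based indices into the matrix rows
encode_residues <- function(seq, residues, arg) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, residues)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("residue(s) ", paste0("'", bad, "'", collapse = ", "),
         " in ", arg, " absent from the substitution matrix", call. = FALSE)
  }
  idx - 1L
}

#' Global alignment of two protein sequences
#'
#' Optimal Needleman-Wunsch global alignment under an affine gap model
#' (Gotoh dynamic programming). Percent identity is the number of identical
#' aligned residue pairs divided by the total number of alignment columns,
#' gap columns included; equal-scoring tracebacks are resolved
#' deterministically (diagonal over up over left).
#'
#' @param seq1,seq2 Non-empty amino-acid strings (uppercase; residues must
#'   be present in the substitution matrix).
#' @param params An [alignment_params()] object.
#' @return An object of class `alignment_result`: a list with `score`
#'   (matrix units), `alignment_length` (columns), `identities`, and
#'   `percent_identity` (fraction in [0, 1]).
#' @examples
#' align_global("AAA", "AAA")$score  # 3 * BLOSUM62[A, A] = 12
#' @export
align_global <- function(seq1, seq2, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"),
            is.character(seq1), length(seq1) == 1L,
            is.character(seq2), length(seq2) == 1L)
  if (!nzchar(seq1) || !nzchar(seq2)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  sub <- get_substitution_matrix(params$substitution_matrix)
  residues <- rownames(sub)
  r <- nw_align_cpp(encode_residues(seq1, residues, "seq1"),
                    encode_residues(seq2, residues, "seq2"),
                    sub, params$gap_open, params$gap_extend)
  res <- list(score = r$score,
              alignment_length = r$alignment_length,
              identities = r$identities,
              percent_identity = r$identities / r$alignment_length)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", x$score, ", length ", x$alignment_length,
      ", identities ", x$identities, " (",
      sprintf("%.1f%%", 100 * x$percent_identity), ")\n", sep = "")
  invisible(x)
}
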
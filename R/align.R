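#' Global protein alignment with affine gaps
#'
#' Needleman–Wunsch global alignment under a named substitution matrix and
#' affine gap penalties (a length-`k` gap costs
#' `gap_open + k * gap_extend`). Alignment is delegated to
#' \pkg{Biostrings}; this wrapper adds the position map used by the residue
#' signature check.
#'
#' @param a,b Nonempty amino-acid strings. `b` is treated as the reference
#'   for `position_map`.
#' @param matrix Substitution matrix name shipped with \pkg{Biostrings}
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM120"`).
#' @param gap_open,gap_extend Nonnegative gap penalties.
#' @return A `protein_alignment`: list with gapped strings `aligned_a`,
#'   `aligned_b`, the alignment `score`, and `position_map` — for each
#'   position of `b` (1-based), the aligned position of `a`, or `NA` where
#'   `b` is aligned to a gap.
#' @export
align_proteins <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- tryCatch(
    suppressWarnings(get(utils::data(list = matrix, package = "Biostrings",
                                     envir = environment()))),
    error = function(e) stop("unknown substitution matrix '", matrix, "'",
                             call. = FALSE)
  )
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a),
    subject = Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = gap_open,
    gapExtension = gap_extend,
    type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b,
         score = Biostrings::score(pa),
         position_map = alignment_position_map(aligned_a, aligned_b)),
    class = "protein_alignment"
  )
}

# For each non-gap position of the reference (second gapped string), the
# 1-based position of the partner residue in the first string, or NA at gaps.
alignment_position_map <- function(aligned_a, aligned_b) {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  stopifnot(length(ca) == length(cb))
  pa <- cumsum(ca != "-")
  map <- ifelse(ca == "-", NA_integer_, pa)[cb != "-"]
  as.integer(map)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> score:", x$score, "\n")
  cat(" a:", substr(x$aligned_a, 1, 60),
      if (nchar(x$aligned_a) > 60) "..." else "", "\n")
  cat(" b:", substr(x$aligned_b, 1, 60),
      if (nchar(x$aligned_b) > 60) "..." else "", "\n")
  invisible(x)
}
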
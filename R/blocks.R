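#' Extract conserved ungapped blocks from a protein alignment
#'
#' A block is a maximal run of alignment columns that are gap-free in every
#' row and whose most frequent residue reaches `min_column_conservation`,
#' with run length at least `min_block_len`. Such blocks mark the highly
#' conserved regions of a transposase alignment from which residue-level
#' diagnostics are read.
#'
#' @param msa Character vector of equal-length gapped amino-acid strings
#'   (at least two rows); gaps are `"-"`.
#' @param min_block_len Minimum block width in columns.
#' @param min_column_conservation Minimum fraction for the modal residue of
#'   each column.
#' @return Tibble with `block_id`, `start_col`, `end_col` (0-based,
#'   half-open alignment columns) and `width`.
#' @export
extract_blocks <- function(msa, min_block_len = 3L,
                           min_column_conservation = 0.5) {
  stopifnot(length(msa) >= 2)
  if (length(unique(nchar(msa))) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  ncol_aln <- ncol(m)
  eligible <- vapply(seq_len(ncol_aln), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(FALSE)
    max(table(col)) / length(col) >= min_column_conservation
  }, logical(1))
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_block_len
  if (!any(keep)) {
    return(tibble::tibble(block_id = integer(0), start_col = integer(0),
                          end_col = integer(0), width = integer(0)))
  }
  tibble::tibble(
    block_id = seq_len(sum(keep)),
    start_col = starts[keep] - 1L,
    end_col = ends[keep],
    width = r$lengths[keep]
  )
}

#' Per-column residue counts for a conserved block
#'
#' The text-mode stand-in for a sequence logo: a positions-by-20 count
#' matrix over the standard amino-acid alphabet.
#'
#' @param msa Character vector of equal-length gapped strings.
#' @param start_col,end_col Block bounds, 0-based half-open (as returned by
#'   [extract_blocks()]).
#' @return Integer matrix of dimension `end_col - start_col` by 20; each
#'   row sums to the number of alignment rows.
#' @export
block_frequencies <- function(msa, start_col, end_col) {
  width <- nchar(msa[1])
  stopifnot(start_col >= 0, end_col <= width, end_col > start_col)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  cols <- seq.int(start_col + 1L, end_col)
  out <- t(vapply(cols, function(j) {
    as.integer(table(factor(m[, j], levels = AA20)))
  }, integer(20)))
  dimnames(out) <- list(NULL, AA20)
  out
}
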
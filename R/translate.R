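#' Translate a DNA sequence in all six reading frames
#'
#' Standard genetic code; frames `-1..-3` translate the reverse complement.
#' Trailing partial codons are dropped. Codons containing `N` translate to
#' `X`; stop codons are kept as `*` so downstream ORF splitting can see
#' them.
#'
#' @param sequence DNA string of length at least 3.
#' @return Named character vector of six protein strings, names
#'   `"+1", "+2", "+3", "-1", "-2", "-3"`.
#' @export
#' @examples
#' six_frame_translate("ATGGCC")
six_frame_translate <- function(sequence) {
  if (nchar(sequence) < 3) {
    stop("sequence shorter than one codon", call. = FALSE)
  }
  fwd <- sequence
  rev <- revcomp(sequence)
  frames <- c(`+1` = 1L, `+2` = 2L, `+3` = 3L, `-1` = 1L, `-2` = 2L,
              `-3` = 3L)
  out <- vapply(seq_along(frames), function(i) {
    s <- if (i <= 3) fwd else rev
    translate_frame(s, frames[i])
  }, character(1))
  names(out) <- names(frames)
  out
}

# translate one frame (offset 1..3) of a forward string
translate_frame <- function(s, offset) {
  n <- nchar(s)
  if (n - offset + 1L < 3L) return("")
  starts <- seq.int(offset, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames across all six frames
#'
#' Reports every maximal stop-free run of at least `min_aa` residues in any
#' frame. A start codon is deliberately not required: consensus
#' transposable-element sequences frequently carry transposase fragments
#' without an intact initiator. Coordinates are mapped back to the forward
#' strand, 0-based, half-open.
#'
#' @param sequence DNA string.
#' @param min_aa Minimum ORF length in residues.
#' @return Tibble with columns `frame` (one of `+1,+2,+3,-1,-2,-3`),
#'   `nt_start`, `nt_end` (forward-strand bp), `aa_length`, `protein`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2)
find_orfs <- function(sequence, min_aa = 100L) {
  n <- nchar(sequence)
  if (n < 3L) {
    return(tibble::tibble(frame = character(0), nt_start = integer(0),
                          nt_end = integer(0), aa_length = integer(0),
                          protein = character(0)))
  }
  empty <- tibble::tibble(frame = character(0), nt_start = integer(0),
                          nt_end = integer(0), aa_length = integer(0),
                          protein = character(0))
  prots <- six_frame_translate(sequence)
  res <- purrr::map_dfr(names(prots), function(fr) {
    prot <- prots[[fr]]
    if (!nzchar(prot)) return(NULL)
    runs <- gregexpr("[^*]+", prot)[[1]]
    if (runs[1] == -1) return(NULL)
    lens <- attr(runs, "match.length")
    keep <- lens >= min_aa
    if (!any(keep)) return(NULL)
    aa_start <- as.integer(runs[keep])     # 1-based within frame protein
    aa_len <- lens[keep]
    offset <- as.integer(substr(fr, 2, 2)) # 1..3
    # frame-local nt coords (0-based, half-open) on the translated strand
    loc_start <- (offset - 1L) + 3L * (aa_start - 1L)
    loc_end <- loc_start + 3L * aa_len
    if (startsWith(fr, "+")) {
      nt_start <- loc_start
      nt_end <- loc_end
    } else {
      nt_start <- n - loc_end
      nt_end <- n - loc_start
    }
    tibble::tibble(frame = fr, nt_start = nt_start, nt_end = nt_end,
                   aa_length = aa_len,
                   protein = substring(prot, aa_start,
                                       aa_start + aa_len - 1L))
  })
  if (nrow(res) == 0) return(empty)
  dplyr::arrange(res, dplyr::desc(.data$aa_length), .data$frame,
                 .data$nt_start)
}
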
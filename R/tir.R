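#' Detect terminal inverted repeats in one element
#'
#' Enumerates every arm pair satisfying all of the following predicates, the
#' detection rule used throughout the package:
#' \itemize{
#'   \item the 5' arm starts within `terminal_window` bp of the element
#'     start, and the 3' arm ends within `terminal_window` bp of the element
#'     end;
#'   \item arm length is in `[min_len, max_len]` (both arms of a pair have
#'     equal length);
#'   \item the Hamming distance between the 5' arm and the reverse
#'     complement of the 3' arm is at most `max_arm_mismatches` (`N` never
#'     matches);
#'   \item the 5' arm's leading bases mismatch the degenerate `anchor` motif
#'     at no more than `max_anchor_mismatches` positions;
#'   \item the arms do not overlap.
#' }
#' All coordinates are 0-based, half-open, on the forward strand. Results
#' are sorted by arm length (longest first), then arm mismatches (fewest
#' first), then 5' start, then 3' start.
#'
#' @param sequence DNA string (uppercase `{A,C,G,T,N}`).
#' @param anchor Degenerate anchor motif (string or [parse_motif()] object).
#'   Default is the classical hAT TIR consensus `"(T/C)A(A/G)NG"`.
#' @param min_len,max_len Arm length bounds in bp. hAT TIRs are at least
#'   8 bp; 30 bp caps degenerate whole-sequence "repeats".
#' @param max_arm_mismatches Arm-vs-arm Hamming budget (default 4, the
#'   permissive setting used for sensitive scans of diverged consensus
#'   elements).
#' @param max_anchor_mismatches Budget for the anchor motif on the 5' arm.
#' @param terminal_window How far from each end an arm may sit, in bp.
#' @param element_id Optional id copied into the result.
#' @return Tibble with columns `element_id`, `five_prime_start`,
#'   `five_prime_end`, `three_prime_start`, `three_prime_end`, `arm_length`,
#'   `arm_mismatches`, `motif_mismatches`, `five_prime_arm`,
#'   `three_prime_arm`.
#' @export
#' @examples
#' el <- paste0("TAGGGTTG", strrep("A", 10), strrep("C", 10), "CAACCCTA")
#' find_tirs(el, min_len = 8, max_len = 8, max_arm_mismatches = 0,
#'           terminal_window = 1)
find_tirs <- function(sequence,
                      anchor = "(T/C)A(A/G)NG",
                      min_len = 8L,
                      max_len = 30L,
                      max_arm_mismatches = 4L,
                      max_anchor_mismatches = 1L,
                      terminal_window = 200L,
                      element_id = NA_character_) {
  anchor <- as_motif(anchor)
  if (min_len < length(anchor)) {
    stop("min_len (", min_len, ") must be at least the anchor motif length (",
         length(anchor), ")", call. = FALSE)
  }
  n <- nchar(sequence)
  if (n < 2L * min_len) {
    stop("sequence too short to host two ", min_len, " bp arms", call. = FALSE)
  }
  ch <- seq_chars(sequence)
  compch <- comp_chars(ch)
  win <- min(as.integer(terminal_window), n)

  # candidate 5' starts (1-based) and their anchor mismatch counts
  s_all <- seq_len(win)
  anchor_mm <- anchor_mismatch_profile(ch, anchor, s_all)
  s_ok <- s_all[!is.na(anchor_mm) & anchor_mm <= max_anchor_mismatches]
  if (length(s_ok) == 0) return(empty_tir_tbl())
  anchor_mm_ok <- anchor_mm[s_ok]

  # candidate 3' ends (1-based, inclusive)
  e_all <- seq.int(n - win + 1L, n)

  lens <- seq.int(min_len, max_len)
  rows <- vector("list", 256L)
  nrows <- 0L

  # For a fixed diagonal k = s + e, base i of the 5' arm starting at s pairs
  # with base k - (s + i - 1) of the 3' arm ending at e = k - s, so one
  # match vector + cumulative sum serves every (s, length) on the diagonal.
  for (k in seq.int(min(s_ok) + min(e_all), max(s_ok) + max(e_all))) {
    p_lo <- max(1L, k - n)
    p_hi <- min(n, k - 1L)
    if (p_hi - p_lo + 1L < min_len) next
    s_here <- s_ok[s_ok >= p_lo & (k - s_ok) >= e_all[1] & (k - s_ok) <= n]
    if (length(s_here) == 0) next
    p <- seq.int(p_lo, p_hi)
    mv <- (ch[p] == compch[k - p]) & (ch[p] != "N") & (ch[k - p] != "N")
    cs <- c(0L, cumsum(mv))
    for (si in seq_along(s_here)) {
      s <- s_here[si]
      e <- k - s
      # max length: stay in bounds and keep the arms non-overlapping
      lmax <- min(max_len, n - s + 1L, e, (e + 1L - s) %/% 2L)
      if (lmax < min_len) next
      ls <- seq.int(min_len, lmax)
      off <- s - p_lo
      matches <- cs[off + ls + 1L] - cs[off + 1L]
      mism <- ls - matches
      keep <- mism <= max_arm_mismatches
      if (!any(keep)) next
      for (L in ls[keep]) {
        nrows <- nrows + 1L
        if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nrows]] <- c(s, L, e, mism[match(L, ls)],
                           anchor_mm_ok[match(s, s_ok)])
      }
    }
  }
  if (nrows == 0L) return(empty_tir_tbl())
  m <- do.call(rbind, rows[seq_len(nrows)])
  s <- m[, 1]; L <- m[, 2]; e <- m[, 3]
  out <- tibble::tibble(
    element_id = element_id,
    five_prime_start = s - 1L,
    five_prime_end = s - 1L + L,
    three_prime_start = e - L,
    three_prime_end = e,
    arm_length = as.integer(L),
    arm_mismatches = as.integer(m[, 4]),
    motif_mismatches = as.integer(m[, 5]),
    five_prime_arm = substring(sequence, s, s + L - 1L),
    three_prime_arm = substring(sequence, e - L + 1L, e)
  )
  dplyr::arrange(out, dplyr::desc(.data$arm_length), .data$arm_mismatches,
                 .data$five_prime_start, .data$three_prime_start)
}

empty_tir_tbl <- function() {
  tibble::tibble(
    element_id = character(0),
    five_prime_start = integer(0), five_prime_end = integer(0),
    three_prime_start = integer(0), three_prime_end = integer(0),
    arm_length = integer(0), arm_mismatches = integer(0),
    motif_mismatches = integer(0),
    five_prime_arm = character(0), three_prime_arm = character(0)
  )
}

#' Scan a table of elements for terminal inverted repeats
#'
#' Tidy wrapper around [find_tirs()]: one call per row of `elements`, rows
#' bound into a single tibble. Elements too short to host two arms yield no
#' rows rather than an error.
#'
#' @param elements Tibble with `element_id` and `sequence` columns (as from
#'   [read_hat_fasta()] or [generate_dataset()]).
#' @inheritParams find_tirs
#' @param ... Passed on to [find_tirs()].
#' @return Tibble of detected arm pairs across all elements.
#' @export
scan_tirs <- function(elements, anchor = "(T/C)A(A/G)NG", min_len = 8L, ...) {
  anchor <- as_motif(anchor)
  purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    if (nchar(elements$sequence[i]) < 2L * min_len) return(empty_tir_tbl())
    find_tirs(elements$sequence[i], anchor = anchor, min_len = min_len, ...,
              element_id = elements$element_id[i])
  })
}

#' Best-supported TIR pair per element
#'
#' Picks the top row of the canonical [find_tirs()] ordering (longest arm,
#' then fewest mismatches, then leftmost) for each element present in
#' `tirs`. Elements with no detected pair are simply absent from the result.
#'
#' @param tirs Tibble of arm pairs from [scan_tirs()] / [find_tirs()].
#' @return Tibble with one row per element.
#' @export
best_tir <- function(tirs) {
  if (nrow(tirs) == 0) return(tirs)
  tirs |>
    dplyr::arrange(dplyr::desc(.data$arm_length), .data$arm_mismatches,
                   .data$five_prime_start, .data$three_prime_start) |>
    dplyr::distinct(.data$element_id, .keep_all = TRUE)
}

#' Drop duplicate TIR arm sequences
#'
#' Keeps the first occurrence of each exact 5' arm string, preserving order —
#' the redundancy-minimisation step applied before consensus building.
#'
#' @param arms Character vector of arm sequences.
#' @return Character vector of unique arms in first-seen order.
#' @export
dedupe_tirs <- function(arms) {
  arms[!duplicated(arms)]
}

#' Derive a degenerate consensus from TIR arms
#'
#' Builds a position frequency matrix over the first `n_columns` bases of
#' each arm and renders a degenerate consensus: a column becomes a single
#' letter when the most frequent base reaches `single_threshold`, a
#' two-letter alternative `[X/Y]` when the top two bases jointly reach
#' `pair_threshold` and each individually reaches `1 - pair_threshold`, and
#' `N` otherwise. `N` characters in arms are excluded from the counts.
#'
#' Within a bracket pair the two bases are written in the fixed order
#' T, C, A, G — the order conventional in the hAT TIR literature — so the
#' rendered consensus does not flap with sampling noise in evenly split
#' columns.
#'
#' @param arms Character vector of arm sequences (deduplicate first with
#'   [dedupe_tirs()]); every arm must be at least `n_columns` long.
#' @param n_columns Number of terminal positions the consensus covers.
#' @param single_threshold Minimum fraction for a single-letter call.
#' @param pair_threshold Minimum joint fraction for a two-letter call.
#' @return A `tir_consensus` object: list with `consensus` (string),
#'   `frequency_matrix` (`n_columns` x 4 counts), `n_input`, `n_unique`.
#' @export
#' @examples
#' derive_consensus(c(rep("TAGGGAAG", 5), rep("CAGGGAAG", 5)))
derive_consensus <- function(arms, n_columns = 8L, single_threshold = 0.6,
                             pair_threshold = 0.8) {
  if (length(arms) == 0) stop("empty arm list", call. = FALSE)
  if (any(nchar(arms) < n_columns)) {
    stop("all arms must be at least n_columns (", n_columns, ") long",
         call. = FALSE)
  }
  mat <- matrix(0L, nrow = n_columns, ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  chm <- do.call(rbind, strsplit(substr(arms, 1L, n_columns), "",
                                 fixed = TRUE))
  for (j in seq_len(n_columns)) {
    tab <- table(factor(chm[, j], levels = DNA_BASES))
    mat[j, ] <- as.integer(tab)
  }
  display_order <- c("T", "C", "A", "G")
  cols <- vapply(seq_len(n_columns), function(j) {
    counts <- mat[j, ]
    tot <- sum(counts)
    if (tot == 0) return("N")
    frac <- counts / tot
    ord <- order(-frac, match(DNA_BASES, display_order))
    top <- frac[ord[1]]
    if (top >= single_threshold) return(names(frac)[ord[1]])
    two <- names(frac)[ord[1:2]]
    if (sum(frac[ord[1:2]]) >= pair_threshold &&
        all(frac[ord[1:2]] >= 1 - pair_threshold)) {
      two <- two[order(match(two, display_order))]
      return(paste0("[", two[1], "/", two[2], "]"))
    }
    "N"
  }, character(1))
  structure(
    list(consensus = paste(cols, collapse = ""),
         frequency_matrix = mat,
         n_input = length(arms),
         n_unique = length(unique(arms)),
         single_threshold = single_threshold,
         pair_threshold = pair_threshold),
    class = "tir_consensus"
  )
}

#' @export
print.tir_consensus <- function(x, ...) {
  cat("TIR consensus over", nrow(x$frequency_matrix), "positions:",
      x$consensus, "\n")
  cat("arms:", x$n_input, "input,", x$n_unique, "unique\n")
  invisible(x)
}

#' @method tidy tir_consensus
#' @export
tidy.tir_consensus <- function(x, ...) {
  mat <- x$frequency_matrix
  tibble::tibble(
    position = rep(seq_len(nrow(mat)) - 1L, each = ncol(mat)),
    base = rep(colnames(mat), nrow(mat)),
    count = as.integer(t(mat)),
  ) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' @method glance tir_consensus
#' @export
glance.tir_consensus <- function(x, ...) {
  tibble::tibble(consensus = x$consensus,
                 n_columns = nrow(x$frequency_matrix),
                 n_input = x$n_input, n_unique = x$n_unique)
}

#' Plot a TIR consensus frequency matrix
#'
#' Stacked per-position base fractions, a text-graphics stand-in for a
#' sequence logo.
#'
#' @param object A `tir_consensus` from [derive_consensus()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tir_consensus
#' @export
autoplot.tir_consensus <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$fraction,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "TIR position (0-based)", y = "base fraction",
                  title = paste("Consensus:", object$consensus)) +
    ggplot2::theme_minimal()
}
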
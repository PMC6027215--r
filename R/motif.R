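#' Parse a degenerate nucleotide motif
#'
#' Motifs describe one allowed-nucleotide set per position, written in either
#' of two dialects seen in the TIR literature: parenthesised alternatives
#' `"(T/C)A(A/G)NG"` or bracketed alternatives `"[T/C]AGNGNNG"`. `N` denotes
#' the full set `{A,C,G,T}`. Both dialects parse to the same object and
#' render back via [format()].
#'
#' @param pattern Motif string.
#' @return A `degenerate_motif`: a list of character vectors (allowed bases
#'   per position, in written order) with the source dialect as an attribute.
#' @export
#' @examples
#' parse_motif("(T/C)A(A/G)NG")
#' parse_motif("[T/C]AGNGNNG")
parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (!nzchar(pattern)) stop("empty motif pattern", call. = FALSE)
  ch <- seq_chars(pattern)
  positions <- list()
  dialect <- "bracket"
  i <- 1L
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 %in% c("(", "[")) {
      close <- if (c0 == "(") ")" else "]"
      if (c0 == "(") dialect <- "paren"
      j <- i + 1L
      group <- character(0)
      while (j <= length(ch) && ch[j] != close) {
        if (ch[j] != "/") {
          if (!ch[j] %in% c(DNA_BASES, "N")) {
            stop("illegal letter '", ch[j], "' at offset ", j - 1L,
                 " in motif '", pattern, "'", call. = FALSE)
          }
          group <- c(group, ch[j])
        }
        j <- j + 1L
      }
      if (j > length(ch)) {
        stop("unclosed group at offset ", i - 1L, " in motif '", pattern,
             "'", call. = FALSE)
      }
      if (length(group) == 0) {
        stop("empty group at offset ", i - 1L, " in motif '", pattern, "'",
             call. = FALSE)
      }
      if ("N" %in% group) group <- DNA_BASES
      positions[[length(positions) + 1L]] <- unique(group)
      i <- j + 1L
    } else if (c0 == "N") {
      positions[[length(positions) + 1L]] <- DNA_BASES
      i <- i + 1L
    } else if (c0 %in% DNA_BASES) {
      positions[[length(positions) + 1L]] <- c0
      i <- i + 1L
    } else {
      stop("illegal letter '", c0, "' at offset ", i - 1L, " in motif '",
           pattern, "'", call. = FALSE)
    }
  }
  structure(positions, class = "degenerate_motif", dialect = dialect)
}

#' @export
format.degenerate_motif <- function(x, dialect = attr(x, "dialect"), ...) {
  if (is.null(dialect)) dialect <- "bracket"
  open <- if (dialect == "paren") "(" else "["
  close <- if (dialect == "paren") ")" else "]"
  paste(vapply(unclass(x), function(p) {
    if (length(p) == 4) {
      "N"
    } else if (length(p) == 1) {
      p
    } else {
      paste0(open, paste(p, collapse = "/"), close)
    }
  }, character(1)), collapse = "")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif> ", format(x), "  (", length(x), " positions)\n",
      sep = "")
  invisible(x)
}

#' @export
length.degenerate_motif <- function(x) length(unclass(x))

# coerce a string or motif to degenerate_motif
as_motif <- function(x) {
  if (inherits(x, "degenerate_motif")) x else parse_motif(x)
}

#' Count mismatches between a sequence prefix and a degenerate motif
#'
#' Compares the first `length(motif)` characters of `seq` position by
#' position: a position mismatches when the observed base is not in the
#' motif's allowed set. `N` in the sequence matches only an `N` (all-base)
#' motif position — ambiguity is scored conservatively as a mismatch
#' everywhere else.
#'
#' @param seq DNA string at least as long as the motif.
#' @param motif A `degenerate_motif` or motif string.
#' @return Integer mismatch count.
#' @export
#' @examples
#' motif_mismatches("TAGGG", "(T/C)A(A/G)NG")  # 0
#' motif_mismatches("GGGGG", "(T/C)A(A/G)NG")  # 2
motif_mismatches <- function(seq, motif) {
  motif <- as_motif(motif)
  m <- length(motif)
  if (nchar(seq) < m) {
    stop("sequence shorter than motif (", nchar(seq), " < ", m, ")",
         call. = FALSE)
  }
  ch <- seq_chars(substr(seq, 1L, m))
  mm <- 0L
  for (i in seq_len(m)) {
    allowed <- motif[[i]]
    ok <- ch[i] %in% allowed || (ch[i] == "N" && length(allowed) == 4)
    if (!ok) mm <- mm + 1L
  }
  mm
}

# vectorised anchor mismatch counts for all start positions `starts`
# (1-based) of the character vector `ch`; positions running past the end
# get NA_integer_
anchor_mismatch_profile <- function(ch, motif, starts) {
  m <- length(motif)
  n <- length(ch)
  out <- rep(NA_integer_, length(starts))
  valid <- starts + m - 1L <= n
  if (!any(valid)) return(out)
  sv <- starts[valid]
  mm <- integer(length(sv))
  for (j in seq_len(m)) {
    allowed <- motif[[j]]
    cj <- ch[sv + j - 1L]
    ok <- cj %in% allowed | (cj == "N" & length(allowed) == 4)
    mm <- mm + as.integer(!ok)
  }
  out[valid] <- mm
  out
}
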
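# Independent oracles the unit and acceptance tests check the package
# against. These deliberately re-derive results by the most direct route
# available (exhaustive scans, Biostrings translation, tree path lengths)
# rather than calling the code paths under test.

# Brute-force TIR scan: try every (5' start, 3' end, length) triple and
# apply the predicates literally.
oracle_find_tirs <- function(sequence, anchor = "(T/C)A(A/G)NG",
                             min_len = 8L, max_len = 30L,
                             max_arm_mismatches = 4L,
                             max_anchor_mismatches = 1L,
                             terminal_window = 200L) {
  motif <- unclass(parse_motif(anchor))
  m <- length(motif)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  n <- length(ch)
  win <- min(terminal_window, n)
  e_lo <- max(n - win + 1L, 1L)
  rows <- list()
  for (s in seq_len(win)) {
    for (L in seq.int(min_len, max_len)) {
      if (s + L - 1L > n) next
      a <- ch[s:(s + L - 1L)]
      amm <- sum(!mapply(function(c0, set) {
        c0 %in% set || (c0 == "N" && length(set) == 4)
      }, a[seq_len(m)], motif))
      if (amm > max_anchor_mismatches) next
      for (e in seq.int(e_lo, n)) {
        if (e - L + 1L < 1L) next
        if (s + 2L * L - 1L > e) next          # arms must not overlap
        b <- rev(comp[(e - L + 1L):e])
        mm <- sum(a != b | a == "N" | b == "N")
        if (mm > max_arm_mismatches) next
        rows[[length(rows) + 1L]] <-
          data.frame(five_prime_start = s - 1L, five_prime_end = s - 1L + L,
                     three_prime_start = e - L, three_prime_end = e,
                     arm_length = L, arm_mismatches = mm,
                     motif_mismatches = amm)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(five_prime_start = integer(0),
                      five_prime_end = integer(0),
                      three_prime_start = integer(0),
                      three_prime_end = integer(0),
                      arm_length = integer(0), arm_mismatches = integer(0),
                      motif_mismatches = integer(0)))
  }
  do.call(rbind, rows)
}

# canonical form shared for set comparison of TIR tables
tir_key <- function(df) {
  sort(paste(df$five_prime_start, df$five_prime_end, df$three_prime_start,
             df$three_prime_end, df$arm_length, df$arm_mismatches,
             df$motif_mismatches, sep = ":"))
}

# Six-frame ORF scan via Biostrings translation (fuzzy codons -> X),
# splitting on stops and mapping coordinates independently.
oracle_orfs <- function(sequence, min_aa) {
  n <- nchar(sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rc
    for (off in 1:3) {
      len <- (nchar(s) - off + 1L) %/% 3L
      if (len < 1) next
      sub <- substr(s, off, off + 3L * len - 1L)
      prot <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X",
        no.init.codon = TRUE)))
      runs <- gregexpr("[^*]+", prot)[[1]]
      if (runs[1] == -1) next
      lens <- attr(runs, "match.length")
      for (i in seq_along(runs)) {
        if (lens[i] < min_aa) next
        loc_start <- (off - 1L) + 3L * (runs[i] - 1L)
        loc_end <- loc_start + 3L * lens[i]
        out[[length(out) + 1L]] <- data.frame(
          frame = paste0(strand, off),
          nt_start = if (strand == "+") loc_start else n - loc_end,
          nt_end = if (strand == "+") loc_end else n - loc_start,
          aa_length = lens[i],
          protein = substr(prot, runs[i], runs[i] + lens[i] - 1L)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = character(0), nt_start = integer(0),
                      nt_end = integer(0), aa_length = integer(0),
                      protein = character(0)))
  }
  do.call(rbind, out)
}

orf_key <- function(df) {
  sort(paste(df$frame, df$nt_start, df$nt_end, df$protein, sep = ":"))
}

# Exhaustive global-alignment score for tiny sequences under affine gaps
# (gap of length k costs open + k * extend), enumerating all alignments.
oracle_align_score <- function(a, b, mat, open, extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + mat[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      pen <- extend + if (state == "ga") 0 else open
      rec(i + 1, j, score - pen, "ga")
    }
    if (j <= length(cb)) {
      pen <- extend + if (state == "gb") 0 else open
      rec(i, j + 1, score - pen, "gb")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# canonical bipartition key matching the package's convention
canon_key <- function(side, all_labels) {
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(setdiff(all_labels, side)), collapse = ",")
  if (a <= b) a else b
}

# random element table for round-trip tests
random_elements <- function(n, min_len = 1L, max_len = 200L) {
  tibble::tibble(
    element_id = paste0("el", seq_len(n)),
    sequence = vapply(sample(seq.int(min_len, max_len), n, replace = TRUE),
                      hatannot::random_dna, character(1)),
  ) |>
    dplyr::mutate(length = nchar(sequence))
}
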
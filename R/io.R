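#' Read consensus elements from a FASTA file
#'
#' Reads a Repbase-style FASTA of consensus transposable-element nucleotide
#' sequences into a tibble, one row per record in file order. Sequences are
#' uppercased and `U` is mapped to `T`; any character outside
#' `{A,C,G,T,N,U}` is an error naming the record and the 0-based offset of
#' the offending character.
#'
#' Repbase headers conventionally start with the genus and species initial
#' letters of the host ("Os", "Zm", ...). The species code is taken from the
#' first capture group of `species_pattern` applied to the record name; a
#' non-matching name yields `NA` so nonconforming headers survive parsing.
#'
#' @param path Path to a FASTA file.
#' @param species_pattern Regex with one capture group extracting the species
#'   code from the record name. Default: the leading letter pair.
#' @return A tibble with columns `element_id`, `species_code`, `sequence`,
#'   `length`.
#' @export
read_hat_fasta <- function(path, species_pattern = "^([A-Za-z][a-z])") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    stop("no records in '", path, "'", call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' at offset %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i] - 1L,
                 sub("\\s.*$", "", names(ss)[i])),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence in record '",
         sub("\\s.*$", "", names(ss)[which(nchar(seqs) == 0)[1]]), "'",
         call. = FALSE)
  }
  element_id <- sub("\\s.*$", "", names(ss))
  m <- regexec(species_pattern, element_id)
  species_code <- vapply(regmatches(element_id, m), function(g) {
    if (length(g) >= 2) g[2] else NA_character_
  }, character(1))
  tibble::tibble(
    element_id = element_id,
    species_code = species_code,
    sequence = unname(seqs),
    length = unname(nchar(seqs))
  )
}

#' Write consensus elements to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns. `read_hat_fasta()` after
#' `write_hat_fasta()` is the identity on (`element_id`, `sequence`).
#'
#' @param elements Tibble with columns `element_id` and `sequence` (as from
#'   [read_hat_fasta()]). An empty tibble writes an empty file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hat_fasta <- function(elements, path) {
  stopifnot(all(c("element_id", "sequence") %in% names(elements)))
  ss <- Biostrings::BStringSet(stats::setNames(elements$sequence,
                                               elements$element_id))
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Parse element names for nonautonomous N-suffixes
#'
#' Nonautonomous hAT derivatives are conventionally named by inserting the
#' letter "N" into the name of their autonomous parent. Two dialects occur:
#' an explicit `-N<k>` suffix ("Os_TEMPINDAS-N1") and an embedded `N<k>`
#' following a numeric stem ("hAT-14N1", parent "hAT-14"). Any other name is
#' returned whole as the stem. Re-rendering `paste0(stem, suffix)` always
#' reproduces the input byte-for-byte.
#'
#' @param name Character vector of element names.
#' @return Tibble with columns `name`, `stem`, `n_suffix_index` (integer,
#'   `NA` when the name encodes no derivative) and `suffix` (the literal
#'   suffix text, `""` when absent).
#' @export
#' @examples
#' parse_element_name(c("Os_TEMPINDAS-N1", "hAT-14N1", "Gulliver"))
parse_element_name <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  stem <- name
  idx <- rep(NA_integer_, length(name))
  suffix <- rep("", length(name))

  dash <- regexec("^(.*)-N([0-9]+)$", name)
  emb <- regexec("^(.*[0-9])N([0-9]+)$", name)
  for (i in seq_along(name)) {
    gd <- regmatches(name[i], dash[i])[[1]]
    ge <- regmatches(name[i], emb[i])[[1]]
    if (length(gd) == 3 && nzchar(gd[2])) {
      stem[i] <- gd[2]
      idx[i] <- as.integer(gd[3])
      suffix[i] <- paste0("-N", gd[3])
    } else if (length(ge) == 3) {
      stem[i] <- ge[2]
      idx[i] <- as.integer(ge[3])
      suffix[i] <- paste0("N", ge[3])
    }
  }
  tibble::tibble(name = name, stem = stem, n_suffix_index = idx,
                 suffix = suffix)
}
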
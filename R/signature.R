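AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic pseudo-random amino-acid background (Lehmer generator, no
# dependence on R's RNG stream) with fixed residues planted at `sites`.
synthetic_protein <- function(length, sites, state) {
  out <- character(length)
  for (i in seq_len(length)) {
    state <- (16807 * state) %% 2147483647
    out[i] <- AA20[(state %% 20) + 1]
  }
  for (i in seq_len(nrow(sites))) {
    out[sites$position[i]] <- sites$allowed[[i]][1]
  }
  paste(out, collapse = "")
}

#' Transposase activity signature specifications
#'
#' A signature is an ordered set of reference positions with allowed
#' residues — the five catalytic/diagnostic amino acids whose joint presence
#' defines an "active" hAT transposase. Two numbering presets ship:
#' \describe{
#'   \item{`"AC"`}{maize Activator numbering: D301, D367, R463, aromatic
#'     W/F at 464, E719.}
#'   \item{`"Hermes"`}{housefly Hermes numbering: D180, D248, R318, W319,
#'     E572.}
#' }
#' Each preset carries a synthetic reference transposase — an invented
#' protein with the signature residues planted at the preset's coordinates —
#' so the full check runs without distributing any curated sequence. Supply
#' your own reference (e.g. the real Activator transposase) via
#' `reference_protein` to check real data; it must itself pass the
#' signature.
#'
#' @param numbering `"AC"` or `"Hermes"`.
#' @param reference_protein Optional replacement reference protein string in
#'   the chosen numbering.
#' @param reference_id Optional id for the reference.
#' @return A `signature_spec`: list with `reference_id`,
#'   `reference_protein` and a `sites` tibble (`position`, `allowed`
#'   list-column).
#' @export
#' @examples
#' spec <- hat_signature("AC")
#' spec$sites
hat_signature <- function(numbering = c("AC", "Hermes"),
                          reference_protein = NULL,
                          reference_id = NULL) {
  numbering <- match.arg(numbering)
  if (numbering == "AC") {
    sites <- tibble::tibble(
      position = c(301L, 367L, 463L, 464L, 719L),
      allowed = list("D", "D", "R", c("W", "F"), "E")
    )
    len <- 750L
    state <- 4301L
    id <- "synthetic-AC-transposase"
  } else {
    sites <- tibble::tibble(
      position = c(180L, 248L, 318L, 319L, 572L),
      allowed = list("D", "D", "R", "W", "E")
    )
    len <- 612L
    state <- 4172L
    id <- "synthetic-Hermes-transposase"
  }
  ref <- reference_protein %||% synthetic_protein(len, sites, state)
  signature_spec(reference_protein = ref,
                 positions = sites$position,
                 allowed = sites$allowed,
                 reference_id = reference_id %||% id)
}

#' Build a custom signature specification
#'
#' @param reference_protein Reference amino-acid string.
#' @param positions Strictly increasing 1-based positions in the reference.
#' @param allowed List of allowed-residue character vectors, one per
#'   position.
#' @param reference_id Identifier recorded in outputs.
#' @return A `signature_spec` object.
#' @export
signature_spec <- function(reference_protein, positions, allowed,
                           reference_id = "reference") {
  stopifnot(length(positions) == length(allowed),
            all(diff(positions) > 0),
            all(positions >= 1),
            all(positions <= nchar(reference_protein)),
            all(lengths(allowed) >= 1))
  sites <- tibble::tibble(position = as.integer(positions),
                          allowed = allowed)
  obs <- substring(reference_protein, sites$position, sites$position)
  ok <- mapply(function(o, a) o %in% a, obs, sites$allowed)
  if (!all(ok)) {
    stop("reference protein fails its own signature at position(s) ",
         paste(sites$position[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(reference_id = reference_id,
                 reference_protein = reference_protein,
                 sites = sites),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat("<signature_spec>", x$reference_id, "-", nchar(x$reference_protein),
      "aa reference,", nrow(x$sites), "signature sites\n")
  cat(paste0(" ", vapply(seq_len(nrow(x$sites)), function(i) {
    paste0("[", paste(x$sites$allowed[[i]], collapse = "/"), "]",
           x$sites$position[i])
  }, character(1)), collapse = ""), "\n")
  invisible(x)
}

#' Check a protein against a transposase activity signature
#'
#' Globally aligns `protein` to the signature's reference and reads the
#' residue aligned opposite each signature position. A site passes when the
#' observed residue is in the allowed set; a gap at a site fails it (a
#' deleted residue is a lacking residue, not missing data). Status is
#' `"active"` when every site passes, otherwise `"truncated"`.
#'
#' @param protein Nonempty amino-acid string.
#' @param spec A `signature_spec`, e.g. from [hat_signature()].
#' @param alignment Optional precomputed [align_proteins()] result of
#'   `protein` vs the reference, to avoid re-aligning.
#' @param ... Alignment parameters passed to [align_proteins()].
#' @return A `residue_check`: list with `status` and a `sites` tibble
#'   (`reference_position`, `allowed`, `observed`, `pass`).
#' @export
check_signature <- function(protein, spec, alignment = NULL, ...) {
  stopifnot(inherits(spec, "signature_spec"), nzchar(protein))
  aln <- alignment %||%
    align_proteins(protein, spec$reference_protein, ...)
  partner <- aln$position_map[spec$sites$position]
  observed <- ifelse(is.na(partner), "-",
                     substring(protein, partner, partner))
  pass <- mapply(function(o, a) o %in% a, observed, spec$sites$allowed)
  residue_check(
    status = if (all(pass)) "active" else "truncated",
    sites = tibble::tibble(
      reference_position = spec$sites$position,
      allowed = vapply(spec$sites$allowed, paste, character(1),
                       collapse = "/"),
      observed = unname(observed),
      pass = unname(pass)
    )
  )
}

residue_check <- function(status, sites) {
  structure(list(status = status, sites = sites), class = "residue_check")
}

# the check returned when no ORF qualifies
absent_check <- function(spec) {
  residue_check(
    status = "absent",
    sites = tibble::tibble(
      reference_position = spec$sites$position,
      allowed = vapply(spec$sites$allowed, paste, character(1),
                       collapse = "/"),
      observed = NA_character_,
      pass = FALSE
    )
  )
}

#' @export
print.residue_check <- function(x, ...) {
  cat("<residue_check> status:", x$status, "\n")
  print(x$sites)
  invisible(x)
}

#' @method tidy residue_check
#' @export
tidy.residue_check <- function(x, ...) {
  dplyr::mutate(x$sites, status = x$status)
}

#' Locate and grade an element's transposase
#'
#' Finds all ORFs of at least `min_aa` residues in six frames, aligns each
#' to the signature reference, keeps the best-scoring one and checks the
#' activity signature on it. Status is `"absent"` when no ORF reaches
#' `min_aa`.
#'
#' @param sequence Element DNA string.
#' @param spec A `signature_spec`.
#' @param min_aa Minimum candidate ORF length (residues). The default 100
#'   keeps deletion derivatives visible as truncated while excluding noise
#'   ORFs from random sequence.
#' @param ... Alignment parameters passed to [align_proteins()].
#' @return List with `orf` (one-row tibble from [find_orfs()] plus an
#'   `alignment_score` column, or `NULL`) and `check` (a `residue_check`).
#' @export
call_transposase <- function(sequence, spec, min_aa = 100L, ...) {
  orfs <- find_orfs(sequence, min_aa = min_aa)
  if (nrow(orfs) == 0) {
    return(list(orf = NULL, check = absent_check(spec)))
  }
  alns <- lapply(orfs$protein, align_proteins,
                 b = spec$reference_protein, ...)
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- which.max(scores)
  orf <- orfs[best, ]
  orf$alignment_score <- scores[best]
  list(orf = orf,
       check = check_signature(orf$protein, spec, alignment = alns[[best]]))
}

#' Grade transposases across a table of elements
#'
#' Tidy wrapper over [call_transposase()].
#'
#' @param elements Tibble with `element_id` and `sequence`.
#' @inheritParams call_transposase
#' @return Tibble with one row per element: `element_id`, `status`,
#'   `frame`, `orf_start`, `orf_end`, `aa_length`, `alignment_score`, and
#'   one `site_<pos>` column per signature site holding the observed
#'   residue.
#' @export
scan_transposases <- function(elements, spec, min_aa = 100L, ...) {
  purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    res <- call_transposase(elements$sequence[i], spec, min_aa = min_aa, ...)
    obs <- stats::setNames(res$check$sites$observed,
                           paste0("site_", res$check$sites$reference_position))
    base <- tibble::tibble(
      element_id = elements$element_id[i],
      status = res$check$status,
      frame = if (is.null(res$orf)) NA_character_ else res$orf$frame,
      orf_start = if (is.null(res$orf)) NA_integer_ else res$orf$nt_start,
      orf_end = if (is.null(res$orf)) NA_integer_ else res$orf$nt_end,
      aa_length = if (is.null(res$orf)) NA_integer_ else res$orf$aa_length,
      alignment_score = if (is.null(res$orf)) NA_real_ else
        res$orf$alignment_score
    )
    dplyr::bind_cols(base, tibble::as_tibble_row(as.list(obs)))
  })
}
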
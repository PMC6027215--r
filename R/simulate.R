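#' Simulation configuration for synthetic hAT elements
#'
#' Collects the generator's parameters, which mirror the defining features
#' of hAT elements: terminal inverted repeats drawn from a degenerate motif
#' (>= 8 bp), a 4–8 bp target-site duplication flanking both ends, an
#' internal transposase ORF that may carry or lack the five-residue
#' activity signature, nonautonomous derivatives made by internal deletion,
#' and point-mutation divergence.
#'
#' @param n_species Number of species codes used (round-robin).
#' @param elements_per_species Base elements per species (derivatives come
#'   on top).
#' @param tir_motif Degenerate motif the TIR starts with (string or
#'   [parse_motif()] object).
#' @param tir_length TIR arm length in bp (>= 8, >= motif length).
#' @param tsd_length Target-site duplication length in `[4, 8]`, or `NULL`
#'   to draw it per element.
#' @param element_length Total element length in bp; must accommodate TSDs,
#'   TIRs and (when present) the transposase ORF.
#' @param transposase_fraction Fraction of base elements carrying the
#'   transposase ORF.
#' @param knockout_fraction Fraction of transposase-bearing elements with
#'   one signature residue mutated to alanine.
#' @param deletion_fraction Fraction of intact transposase-bearing elements
#'   spawning an internally deleted nonautonomous `-N1` derivative.
#' @param per_site_mutation_rate Per-site substitution probability applied
#'   to every finished element.
#' @param seed Integer seed making [generate_dataset()] deterministic.
#' @param signature Signature preset the planted ORF encodes
#'   (see [hat_signature()]).
#' @return A `hat_sim_config` list.
#' @export
simulation_config <- function(n_species = 3L,
                              elements_per_species = 10L,
                              tir_motif = "[T/C]AGNGNNG",
                              tir_length = 12L,
                              tsd_length = NULL,
                              element_length = 2700L,
                              transposase_fraction = 0.5,
                              knockout_fraction = 0.2,
                              deletion_fraction = 0.3,
                              per_site_mutation_rate = 0,
                              seed = 1L,
                              signature = hat_signature("AC")) {
  motif <- as_motif(tir_motif)
  stopifnot(tir_length >= 8L, tir_length >= length(motif),
            is.null(tsd_length) ||
              (tsd_length >= 4L && tsd_length <= 8L),
            transposase_fraction >= 0, transposase_fraction <= 1,
            knockout_fraction >= 0, knockout_fraction <= 1,
            deletion_fraction >= 0, deletion_fraction <= 1,
            per_site_mutation_rate >= 0, per_site_mutation_rate < 0.75,
            inherits(signature, "signature_spec"))
  orf_nt <- 3L * (nchar(signature$reference_protein) + 0L)
  min_len <- 2L * 8L + 2L * tir_length + orf_nt + 6L + 40L
  if (element_length < min_len) {
    stop("element_length ", element_length, " too short; need at least ",
         min_len, " bp to host TSDs, TIRs and the transposase ORF",
         call. = FALSE)
  }
  structure(
    list(n_species = as.integer(n_species),
         elements_per_species = as.integer(elements_per_species),
         tir_motif = motif,
         tir_length = as.integer(tir_length),
         tsd_length = tsd_length,
         element_length = as.integer(element_length),
         transposase_fraction = transposase_fraction,
         knockout_fraction = knockout_fraction,
         deletion_fraction = deletion_fraction,
         per_site_mutation_rate = per_site_mutation_rate,
         seed = as.integer(seed),
         signature = signature),
    class = "hat_sim_config"
  )
}

#' Sample a TIR arm from a degenerate motif
#'
#' The first `length(motif)` positions are drawn uniformly from each
#' position's allowed set; remaining positions are uniform over the four
#' bases. Every draw has zero mismatches against its own motif.
#'
#' @param motif Degenerate motif (string or object).
#' @param tir_length Total arm length (>= motif length).
#' @return A DNA string.
#' @export
sample_tir <- function(motif, tir_length) {
  motif <- as_motif(motif)
  m <- length(motif)
  stopifnot(tir_length >= m)
  head_part <- vapply(unclass(motif), function(p) {
    p[sample.int(length(p), 1L)]
  }, character(1))
  tail_part <- if (tir_length > m) {
    sample(DNA_BASES, tir_length - m, replace = TRUE)
  } else {
    character(0)
  }
  paste(c(head_part, tail_part), collapse = "")
}

# deterministic reverse translation: first codon listed for each residue
codon_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(names(gc)[match(aa, gc)], aa)
}

# DNA encoding the reference protein, flanked by in-frame stop codons
encode_orf <- function(protein) {
  aa <- seq_chars(protein)
  paste0("TAA", paste(codon_for(aa), collapse = ""), "TAA")
}

#' Build one synthetic consensus element
#'
#' Layout: `[TSD][5' TIR][filler][stop][transposase ORF][stop][filler]
#' [revcomp(5' TIR)][TSD]`, with the ORF block omitted for
#' `with_transposase = FALSE`. Draws come from the current RNG stream;
#' seed control lives in [generate_dataset()].
#'
#' @param config A `hat_sim_config`.
#' @param with_transposase Plant the transposase ORF?
#' @param knockout Mutate one randomly chosen signature residue to alanine
#'   (only meaningful with a transposase).
#' @param element_id,species_code Identifiers recorded in the outputs.
#' @return List with `element` (one-row tibble: `element_id`,
#'   `species_code`, `sequence`, `length`) and `truth` (one-row tibble of
#'   planted coordinates and states).
#' @export
build_element <- function(config, with_transposase = TRUE, knockout = FALSE,
                          element_id = "el1", species_code = "Xx") {
  tsd_len <- config$tsd_length %||% sample(4:8, 1L)
  tsd <- random_dna(tsd_len)
  tir <- sample_tir(config$tir_motif, config$tir_length)
  tirL <- config$tir_length
  L <- config$element_length

  orf_block <- if (with_transposase) {
    encode_orf(config$signature$reference_protein)
  } else {
    ""
  }
  fixed <- 2L * tsd_len + 2L * tirL + nchar(orf_block)
  filler_total <- L - fixed
  if (filler_total < 2L) {
    stop("element_length infeasible for the drawn TSD length", call. = FALSE)
  }
  f1 <- sample.int(filler_total - 1L, 1L)
  filler1 <- random_dna(f1)
  filler2 <- random_dna(filler_total - f1)

  sequence <- paste0(tsd, tir, filler1, orf_block, filler2, revcomp(tir),
                     tsd)
  # 0-based coords of the coding region (between the planted stops)
  orf_start <- if (with_transposase) tsd_len + tirL + f1 + 3L else
    NA_integer_
  orf_end <- if (with_transposase) {
    orf_start + 3L * nchar(config$signature$reference_protein)
  } else {
    NA_integer_
  }

  knocked_site <- NA_integer_
  if (with_transposase && knockout) {
    site <- sample.int(nrow(config$signature$sites), 1L)
    pos <- config$signature$sites$position[site]
    cs <- orf_start + 3L * (pos - 1L)         # 0-based codon start
    sequence <- paste0(substr(sequence, 1L, cs), "GCT",
                       substr(sequence, cs + 4L, nchar(sequence)))
    knocked_site <- pos
  }

  element <- tibble::tibble(element_id = element_id,
                            species_code = species_code,
                            sequence = sequence, length = nchar(sequence))
  truth <- tibble::tibble(
    element_id = element_id,
    species_code = species_code,
    tsd_length = tsd_len,
    tir5_start = tsd_len, tir5_end = tsd_len + tirL,
    tir3_start = L - tsd_len - tirL, tir3_end = L - tsd_len,
    orf_start = orf_start, orf_end = orf_end,
    knocked_site = knocked_site,
    signature_state = if (!with_transposase) "none" else
      if (knockout) "knocked_out" else "intact",
    autonomy = if (with_transposase && !knockout) "autonomous" else
      "nonautonomous",
    parent_id = NA_character_
  )
  list(element = element, truth = truth)
}

#' Derive a nonautonomous element by internal deletion
#'
#' Removes a random internal span from a transposase-bearing parent. The
#' span always lies strictly between the TIRs (both arms and TSDs are
#' kept) and always covers at least one signature-site codon, so the
#' derivative genuinely lacks the activity signature. The child is named
#' `<parent>-N<k>`.
#'
#' @param parent Result of [build_element()] (list with `element` and
#'   `truth`).
#' @param config The `hat_sim_config` used for the parent.
#' @param k Derivative index for the name suffix.
#' @return List with `element` and `truth` one-row tibbles.
#' @export
derive_nonautonomous <- function(parent, config, k = 1L) {
  tr <- parent$truth
  if (is.na(tr$orf_start)) {
    stop("parent carries no transposase ORF to delete", call. = FALSE)
  }
  seq <- parent$element$sequence
  lo <- tr$tir5_end + 4L              # first deletable position (0-based)
  hi <- tr$tir3_start - 4L            # one past last deletable position
  orf_len <- tr$orf_end - tr$orf_start
  dl <- sample(seq.int(round(0.25 * orf_len), round(0.6 * orf_len)), 1L)

  site <- sample.int(nrow(config$signature$sites), 1L)
  pos <- config$signature$sites$position[site]
  codon_start <- tr$orf_start + 3L * (pos - 1L)
  codon_end <- codon_start + 3L
  start_min <- max(lo, codon_end - dl)
  start_max <- min(codon_start, hi - dl)
  if (start_max < start_min) {
    dl <- codon_end - lo
    start_min <- lo
    start_max <- lo
  }
  del_start <- if (start_max > start_min) {
    sample(seq.int(start_min, start_max), 1L)
  } else {
    start_min
  }

  child_seq <- paste0(substr(seq, 1L, del_start),
                      substr(seq, del_start + dl + 1L, nchar(seq)))
  child_id <- paste0(tr$element_id, "-N", k)
  L2 <- nchar(child_seq)
  tirL <- tr$tir5_end - tr$tir5_start

  element <- tibble::tibble(element_id = child_id,
                            species_code = tr$species_code,
                            sequence = child_seq, length = L2)
  truth <- tibble::tibble(
    element_id = child_id,
    species_code = tr$species_code,
    tsd_length = tr$tsd_length,
    tir5_start = tr$tir5_start, tir5_end = tr$tir5_end,
    tir3_start = L2 - tr$tsd_length - tirL,
    tir3_end = L2 - tr$tsd_length,
    orf_start = NA_integer_, orf_end = NA_integer_,
    knocked_site = NA_integer_,
    signature_state = "deleted",
    autonomy = "nonautonomous",
    parent_id = tr$element_id
  )
  list(element = element, truth = truth)
}

#' Apply per-site point substitutions
#'
#' Each `A/C/G/T` site is independently replaced, with probability `rate`,
#' by one of the three other bases (uniformly). `N` sites are left alone.
#'
#' @param sequence DNA string.
#' @param rate Per-site substitution probability.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  ch <- seq_chars(sequence)
  eligible <- which(ch %in% DNA_BASES)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit) > 0) {
    old <- match(ch[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

# Ground-truth signature evaluation on the emitted sequence: translate the
# planted coding region in its planted frame and require (i) every
# signature residue in its allowed set and (ii) no stop codon between the
# first and last signature sites. A stop outside that span leaves a single
# stop-free fragment that still carries all five residues, which the
# residue-based activity criterion counts as active; a stop inside it
# splits the sites across fragments. Mutation-disrupted signatures are
# thereby downgraded honestly.
signature_intact_in_truth <- function(sequence, orf_start, orf_end, spec) {
  if (is.na(orf_start)) return(FALSE)
  starts <- seq.int(orf_start + 1L, orf_end - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  span <- seq.int(min(spec$sites$position), max(spec$sites$position))
  if (any(aa[span] == "*")) return(FALSE)
  obs <- aa[spec$sites$position]
  all(mapply(function(o, a) o %in% a, obs, spec$sites$allowed))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds `n_species * elements_per_species` base elements (transposase,
#' knockout and derivative status drawn per the config fractions), spawns
#' nonautonomous derivatives, applies per-site mutation, and re-evaluates
#' every truth label on the emitted sequences. Deterministic for a fixed
#' config seed, including byte-identical files when paths are given.
#'
#' @param config A `hat_sim_config` from [simulation_config()].
#' @param out_fasta,out_truth Optional paths; when given, the elements are
#'   written as FASTA and the truth table as TSV.
#' @return List with tibbles `elements` and `truth`.
#' @export
generate_dataset <- function(config, out_fasta = NULL, out_truth = NULL) {
  stopifnot(inherits(config, "hat_sim_config"))
  species_pool <- c("Os", "Zm", "At", "Ta", "Hv", "Nt", "Mt", "Pt", "Cr",
                    "Vc")
  if (config$n_species > length(species_pool)) {
    species_pool <- c(species_pool,
                      sprintf("S%02d",
                              seq_len(config$n_species -
                                        length(species_pool))))
  }
  species <- species_pool[seq_len(config$n_species)]

  res <- with_rng_seed(config$seed, {
    elements <- list()
    truths <- list()
    counter <- stats::setNames(integer(length(species)), species)
    n_base <- config$n_species * config$elements_per_species
    for (i in seq_len(n_base)) {
      sp <- species[((i - 1L) %% length(species)) + 1L]
      counter[sp] <- counter[sp] + 1L
      id <- paste0(sp, "_hAT-", counter[sp])
      with_tp <- stats::runif(1) < config$transposase_fraction
      ko <- with_tp && stats::runif(1) < config$knockout_fraction
      built <- build_element(config, with_transposase = with_tp,
                             knockout = ko, element_id = id,
                             species_code = sp)
      elements[[length(elements) + 1L]] <- built$element
      truths[[length(truths) + 1L]] <- built$truth
      if (with_tp && !ko &&
          stats::runif(1) < config$deletion_fraction) {
        child <- derive_nonautonomous(built, config, k = 1L)
        elements[[length(elements) + 1L]] <- child$element
        truths[[length(truths) + 1L]] <- child$truth
      }
    }
    elements <- dplyr::bind_rows(elements)
    truth <- dplyr::bind_rows(truths)

    if (config$per_site_mutation_rate > 0) {
      elements$sequence <- vapply(elements$sequence, mutate_sequence,
                                  character(1),
                                  rate = config$per_site_mutation_rate,
                                  USE.NAMES = FALSE)
      elements$length <- nchar(elements$sequence)
    }

    # honest truth on the emitted sequences
    intact <- vapply(seq_len(nrow(truth)), function(i) {
      signature_intact_in_truth(elements$sequence[i], truth$orf_start[i],
                                truth$orf_end[i], config$signature)
    }, logical(1))
    truth$signature_state <- dplyr::case_when(
      truth$signature_state == "none" ~ "none",
      truth$signature_state == "deleted" ~ "deleted",
      intact ~ "intact",
      .default = "knocked_out"
    )
    truth$autonomy <- ifelse(truth$signature_state == "intact",
                             "autonomous", "nonautonomous")
    list(elements = elements, truth = truth)
  })

  if (!is.null(out_fasta)) write_hat_fasta(res$elements, out_fasta)
  if (!is.null(out_truth)) readr::write_tsv(res$truth, out_truth)
  res
}

#' Radiate a sequence along a tree with per-branch substitutions
#'
#' Simulates divergence of a root sequence down a binary tree: every branch
#' independently substitutes each site with its branch-specific
#' probability (a Jukes–Cantor-type event: the new base is uniform over the
#' other three). When no tree is supplied, a random topology on
#' `tree_leaves` tips is drawn and every branch gets
#' `per_site_mutation_rate`. The returned `tree` carries branch lengths on
#' the expected-distance scale `-(3/4) log(1 - 4r/3)`, which makes path
#' lengths additive and directly comparable to Jukes–Cantor corrected
#' distances.
#'
#' @param root_seq Root DNA string.
#' @param tree_leaves Number of leaves for the random topology (ignored
#'   when `tree` is given).
#' @param per_site_mutation_rate Per-branch substitution probability for
#'   the random topology.
#' @param tree Optional `phylo` whose `edge.length` are per-branch
#'   substitution probabilities (each `< 0.75`).
#' @return List with `leaves` (named character vector of tip sequences),
#'   `tree` (`phylo`, branch lengths in expected substitutions per site)
#'   and `rates` (`phylo` with the raw per-branch probabilities).
#' @export
mutate_and_radiate <- function(root_seq, tree_leaves = 8L,
                               per_site_mutation_rate = 0.05,
                               tree = NULL) {
  stopifnot(per_site_mutation_rate < 0.75)
  if (is.null(tree)) {
    tree <- ape::rtree(tree_leaves)
    tree$edge.length <- rep(per_site_mutation_rate, nrow(tree$edge))
  }
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), all(tree$edge.length < 0.75))
  n <- length(tree$tip.label)
  root <- n + 1L
  tree_po <- ape::reorder.phylo(tree, "postorder")
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- root_seq
  # preorder: parents before children
  for (k in rev(seq_len(nrow(tree_po$edge)))) {
    p <- tree_po$edge[k, 1]
    ch <- tree_po$edge[k, 2]
    seqs[[ch]] <- mutate_sequence(seqs[[p]], tree_po$edge.length[k])
  }
  leaves <- stats::setNames(
    vapply(seq_len(n), function(i) seqs[[i]], character(1)),
    tree$tip.label)
  dist_tree <- tree
  dist_tree$edge.length <- -0.75 * log(1 - 4 * tree$edge.length / 3)
  list(leaves = leaves, tree = dist_tree, rates = tree)
}
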
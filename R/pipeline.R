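#' Run the full hAT annotation pipeline
#'
#' Chains every stage over a table of elements: TIR scan, best-TIR
#' selection, TIR deduplication and consensus, six-frame transposase
#' discovery with signature checks, autonomy classification with
#' derivative linking, and the dataset summary. Optionally aligns nothing —
#' a precomputed alignment may be supplied for the phylogeny stage, which
#' is otherwise skipped.
#'
#' When `out_dir` is given, each stage's table is written as TSV, the
#' effective parameters are dumped alongside, and a `MANIFEST.tsv` records
#' every output with its MD5 content hash and a completeness flag. The run
#' is deterministic for fixed inputs and seed.
#'
#' @param elements Element tibble (from [read_hat_fasta()] or
#'   [generate_dataset()]), or a path to a FASTA file.
#' @param signature A `signature_spec` for the transposase check.
#' @param anchor Degenerate anchor motif for the TIR scan.
#' @param min_len,max_len,max_arm_mismatches,max_anchor_mismatches,terminal_window
#'   TIR scan parameters (see [find_tirs()]).
#' @param consensus_columns,single_threshold,pair_threshold TIR consensus
#'   parameters (see [derive_consensus()]).
#' @param min_aa Minimum transposase ORF length (see [call_transposase()]).
#' @param msa Optional named character vector of aligned element sequences;
#'   when given, an NJ tree with bootstrap supports is built.
#' @param n_bootstrap,seed Bootstrap replicate count and seed for the tree
#'   stage.
#' @param out_dir Optional output directory.
#' @return A `hat_pipeline` object: list with `elements`, `tirs`,
#'   `best_tirs`, `consensus`, `transposases`, `calls`, `summary`, `tree`
#'   (or `NULL`) and `params`.
#' @export
run_hat_pipeline <- function(elements,
                             signature = hat_signature("AC"),
                             anchor = "(T/C)A(A/G)NG",
                             min_len = 8L, max_len = 30L,
                             max_arm_mismatches = 4L,
                             max_anchor_mismatches = 1L,
                             terminal_window = 200L,
                             consensus_columns = 8L,
                             single_threshold = 0.6,
                             pair_threshold = 0.8,
                             min_aa = 100L,
                             msa = NULL,
                             n_bootstrap = 100L,
                             seed = NULL,
                             out_dir = NULL) {
  if (is.character(elements) && length(elements) == 1) {
    elements <- read_hat_fasta(elements)
  }
  stopifnot(is.data.frame(elements),
            all(c("element_id", "sequence") %in% names(elements)),
            inherits(signature, "signature_spec"))
  params <- list(
    anchor = format(as_motif(anchor)), min_len = min_len, max_len = max_len,
    max_arm_mismatches = max_arm_mismatches,
    max_anchor_mismatches = max_anchor_mismatches,
    terminal_window = terminal_window,
    consensus_columns = consensus_columns,
    single_threshold = single_threshold, pair_threshold = pair_threshold,
    min_aa = min_aa, n_bootstrap = n_bootstrap,
    seed = seed %||% NA_integer_,
    reference_id = signature$reference_id
  )

  tirs <- scan_tirs(elements, anchor = anchor, min_len = min_len,
                    max_len = max_len,
                    max_arm_mismatches = max_arm_mismatches,
                    max_anchor_mismatches = max_anchor_mismatches,
                    terminal_window = terminal_window)
  best <- best_tir(tirs)
  arms <- dedupe_tirs(best$five_prime_arm)
  consensus <- if (length(arms) > 0 &&
                   all(nchar(arms) >= consensus_columns)) {
    derive_consensus(arms, n_columns = consensus_columns,
                     single_threshold = single_threshold,
                     pair_threshold = pair_threshold)
  } else {
    NULL
  }

  transposases <- scan_transposases(elements, signature, min_aa = min_aa)
  evidence <- autonomy_evidence(elements, tirs, transposases)
  calls <- link_derivatives(classify_autonomy(evidence))
  summary <- summarize_dataset(elements, calls, consensus)

  tree <- if (!is.null(msa)) {
    bootstrap_support(msa, n_reps = n_bootstrap, seed = seed)
  } else {
    NULL
  }

  result <- structure(
    list(elements = elements, tirs = tirs, best_tirs = best,
         consensus = consensus, transposases = transposases,
         calls = calls, summary = summary, tree = tree, params = params),
    class = "hat_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    elements = "elements.tsv", tirs = "tirs.tsv",
    best_tirs = "best_tirs.tsv", transposases = "transposases.tsv",
    calls = "autonomy_calls.tsv"
  )
  written <- character(0)
  for (nm in names(paths)) {
    p <- file.path(out_dir, paths[[nm]])
    readr::write_tsv(result[[nm]], p)
    written <- c(written, p)
  }
  if (!is.null(result$consensus)) {
    p <- file.path(out_dir, "tir_consensus.tsv")
    readr::write_tsv(tidy(result$consensus), p)
    writeLines(result$consensus$consensus,
               file.path(out_dir, "tir_consensus.txt"))
    written <- c(written, p, file.path(out_dir, "tir_consensus.txt"))
  }
  p <- file.path(out_dir, "summary.tsv")
  readr::write_tsv(glance(result$summary), p)
  written <- c(written, p)
  p <- file.path(out_dir, "per_species.tsv")
  readr::write_tsv(result$summary$per_species, p)
  written <- c(written, p)
  if (!is.null(result$tree)) {
    p <- file.path(out_dir, "tree.nwk")
    write_newick(result$tree, p)
    written <- c(written, p)
  }
  p <- file.path(out_dir, "params.tsv")
  readr::write_tsv(tibble::tibble(key = names(result$params),
                                  value = vapply(result$params, as.character,
                                                 character(1))), p)
  written <- c(written, p)
  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    complete = TRUE
  )
  readr::write_tsv(manifest, file.path(out_dir, "MANIFEST.tsv"))
  invisible(out_dir)
}

#' @export
print.hat_pipeline <- function(x, ...) {
  cat("hAT annotation pipeline\n")
  cat("  elements:", nrow(x$elements), "\n")
  cat("  TIR arm pairs:", nrow(x$tirs), "; elements with a TIR:",
      nrow(x$best_tirs), "\n")
  if (!is.null(x$consensus)) {
    cat("  TIR consensus (", x$consensus$n_unique, " unique arms): ",
        x$consensus$consensus, "\n", sep = "")
  }
  cat("  active transposases:",
      sum(x$transposases$status == "active"), "of",
      nrow(x$transposases), "\n")
  cat("  autonomous:", x$summary$n_autonomous,
      sprintf("(%.1f%%)", x$summary$autonomous_percent), "\n")
  invisible(x)
}

#' @method glance hat_pipeline
#' @export
glance.hat_pipeline <- function(x, ...) {
  tibble::tibble(
    n_elements = nrow(x$elements),
    n_tir_pairs = nrow(x$tirs),
    n_with_tir = nrow(x$best_tirs),
    n_active = sum(x$transposases$status == "active"),
    n_autonomous = x$summary$n_autonomous,
    autonomous_percent = x$summary$autonomous_percent,
    tir_consensus = if (is.null(x$consensus)) NA_character_ else
      x$consensus$consensus
  )
}

#' @method tidy hat_pipeline
#' @export
tidy.hat_pipeline <- function(x, ...) {
  x$calls
}
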
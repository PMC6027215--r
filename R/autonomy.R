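#' Classify elements as autonomous or nonautonomous
#'
#' An element is autonomous when it both possesses a detected TIR pair and
#' encodes an active transposase (all five signature residues present);
#' every failed criterion is recorded as a reason: `no_tir`,
#' `truncated_transposase` or `no_transposase`. The call is a pure function
#' of the two evidence inputs.
#'
#' @param evidence Tibble with one row per element and columns
#'   `element_id`, `has_tir` (logical) and `transposase_status`
#'   (`"active"`, `"truncated"` or `"absent"`). Build it with
#'   [autonomy_evidence()] from stage outputs.
#' @return Tibble with `element_id`, `status` (`"autonomous"` /
#'   `"nonautonomous"`), `reasons` (comma-joined, `""` when autonomous) and
#'   `parent_id` (`NA`; fill with [link_derivatives()]).
#' @export
classify_autonomy <- function(evidence) {
  stopifnot(all(c("element_id", "has_tir", "transposase_status") %in%
                  names(evidence)),
            !anyDuplicated(evidence$element_id))
  reasons <- purrr::map2_chr(
    evidence$has_tir, evidence$transposase_status,
    function(tir, status) {
      r <- character(0)
      if (!isTRUE(tir)) r <- c(r, "no_tir")
      if (status == "truncated") r <- c(r, "truncated_transposase")
      if (status == "absent") r <- c(r, "no_transposase")
      paste(r, collapse = ",")
    }
  )
  tibble::tibble(
    element_id = evidence$element_id,
    status = ifelse(reasons == "", "autonomous", "nonautonomous"),
    reasons = reasons,
    parent_id = NA_character_
  )
}

#' Assemble classification evidence from stage outputs
#'
#' Joins the TIR scan and the transposase scan into the per-element
#' evidence table [classify_autonomy()] consumes. An element has a TIR when
#' at least one arm pair was detected for it.
#'
#' @param elements Element tibble (`element_id`, ...).
#' @param tirs TIR tibble from [scan_tirs()].
#' @param transposases Transposase tibble from [scan_transposases()].
#' @return Evidence tibble (`element_id`, `has_tir`, `transposase_status`).
#' @export
autonomy_evidence <- function(elements, tirs, transposases) {
  tibble::tibble(element_id = elements$element_id) |>
    dplyr::mutate(has_tir = .data$element_id %in% tirs$element_id) |>
    dplyr::left_join(
      dplyr::select(transposases, "element_id",
                    transposase_status = "status"),
      by = "element_id"
    ) |>
    dplyr::mutate(transposase_status =
                    dplyr::coalesce(.data$transposase_status, "absent"))
}

#' Link nonautonomous N-suffix derivatives to their parents
#'
#' A nonautonomous element whose name carries an N-suffix (see
#' [parse_element_name()]) gets `parent_id` set to its stem when an element
#' of that name exists in the dataset; orphans keep `NA`. Autonomous
#' elements are never assigned a parent from naming.
#'
#' @param calls Classification tibble from [classify_autonomy()].
#' @return `calls` with `parent_id` filled in.
#' @export
link_derivatives <- function(calls) {
  stopifnot(!anyDuplicated(calls$element_id))
  names_tbl <- parse_element_name(calls$element_id)
  parent <- ifelse(
    calls$status == "nonautonomous" &
      !is.na(names_tbl$n_suffix_index) &
      names_tbl$stem %in% calls$element_id,
    names_tbl$stem,
    NA_character_
  )
  dplyr::mutate(calls, parent_id = parent)
}

#' Summarize an annotated dataset
#'
#' Per-species element counts, the autonomous count, and the autonomous
#' percentage — truncated (not rounded) to one decimal, the convention used
#' when such fractions are reported — plus the derived TIR consensus.
#'
#' @param elements Element tibble with `element_id` and `species_code`.
#' @param calls Classification tibble from [classify_autonomy()].
#' @param tir_consensus Optional consensus string or `tir_consensus`
#'   object.
#' @return A `hat_summary` object.
#' @export
summarize_dataset <- function(elements, calls, tir_consensus = NULL) {
  if (nrow(elements) == 0) stop("empty dataset", call. = FALSE)
  stopifnot(nrow(calls) == nrow(elements),
            setequal(calls$element_id, elements$element_id))
  per_species <- elements |>
    dplyr::count(.data$species_code, name = "n_elements") |>
    dplyr::arrange(dplyr::desc(.data$n_elements), .data$species_code)
  n_total <- nrow(elements)
  n_autonomous <- sum(calls$status == "autonomous")
  cons <- if (inherits(tir_consensus, "tir_consensus")) {
    tir_consensus$consensus
  } else {
    tir_consensus
  }
  structure(
    list(per_species = per_species,
         n_total = n_total,
         n_autonomous = n_autonomous,
         autonomous_percent = autonomous_percent(n_autonomous, n_total),
         tir_consensus = cons),
    class = "hat_summary"
  )
}

#' Autonomous percentage with one-decimal truncation
#'
#' `floor(1000 * n_autonomous / n_total) / 10`: 35 of 276 gives 12.6.
#'
#' @param n_autonomous,n_total Counts.
#' @return Percentage truncated to one decimal.
#' @export
autonomous_percent <- function(n_autonomous, n_total) {
  stopifnot(n_total >= 1, n_autonomous >= 0, n_autonomous <= n_total)
  floor(1000 * n_autonomous / n_total) / 10
}

#' @export
print.hat_summary <- function(x, ...) {
  cat("hAT dataset summary\n")
  cat("  elements:", x$n_total, "across", nrow(x$per_species), "species\n")
  cat("  autonomous:", x$n_autonomous,
      sprintf("(%.1f%%)", x$autonomous_percent), "\n")
  if (!is.null(x$tir_consensus)) {
    cat("  TIR consensus:", x$tir_consensus, "\n")
  }
  print(x$per_species)
  invisible(x)
}

#' @method tidy hat_summary
#' @export
tidy.hat_summary <- function(x, ...) {
  x$per_species
}

#' @method glance hat_summary
#' @export
glance.hat_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total,
                 n_autonomous = x$n_autonomous,
                 autonomous_percent = x$autonomous_percent,
                 tir_consensus = x$tir_consensus %||% NA_character_)
}
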
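#' Uncorrected p-distance with pairwise deletion
#'
#' Fraction of mismatching sites among comparable sites. A site is
#' comparable when both sequences carry an unambiguous base (`A/C/G/T`);
#' columns with a gap (`-`) or `N` in either sequence are excluded, so
#' gappy transposon alignments do not force whole-column deletion.
#'
#' @param a,b Equal-length (gapped) DNA strings.
#' @return The proportion of differing comparable sites.
#' @export
#' @examples
#' p_distance("AA-A", "AATA")  # gap column excluded -> 0
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) stop("zero comparable sites", call. = FALSE)
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Jukes–Cantor corrected distance
#'
#' `d = -(3/4) * log(1 - 4p/3)`, the one-parameter correction for multiple
#' substitutions at a site. Defined for `0 <= p < 0.75`.
#'
#' @param p Observed proportion of differing sites.
#' @return Corrected substitutions per site.
#' @export
#' @examples
#' jc69(0.3)
jc69 <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop("p-distance saturated: JC69 undefined for p >= 0.75", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' Computes all pairwise distances under pairwise deletion. Under
#' `model = "jc69"` a saturated pair (`p >= 0.75`) falls back to its raw
#' p-distance and the event is counted in the `n_fallback` attribute, so a
#' single diverged pair cannot abort a bootstrap replicate.
#'
#' @param msa Named character vector of equal-length gapped DNA strings.
#' @param model `"jc69"` (default) or `"p"`.
#' @return Symmetric numeric matrix with sequence names as dimnames and an
#'   `n_fallback` attribute.
#' @export
msa_distances <- function(msa, model = c("jc69", "p")) {
  model <- match.arg(model)
  stopifnot(length(msa) >= 2, !is.null(names(msa)),
            !anyDuplicated(names(msa)))
  if (length(unique(nchar(msa))) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  valid <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  n_fallback <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) stop("zero comparable sites between '", names(msa)[i],
                         "' and '", names(msa)[j], "'", call. = FALSE)
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      dij <- if (model == "p") {
        p
      } else if (p < 0.75) {
        jc69(p)
      } else {
        n_fallback <- n_fallback + 1L
        p
      }
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  attr(d, "n_fallback") <- n_fallback
  d
}

#' Neighbor-joining tree
#'
#' Saitou–Nei agglomeration: repeatedly joins the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (`R` the row sums), with branch
#' lengths `b_i = d(i,j)/2 + (R_i - R_j) / (2(n-2))` and distance update
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in `Q` are broken by the
#' smallest `(i, j)` index pair in the current matrix order. A negative
#' branch length is clamped to zero with the deficit moved onto its sibling
#' branch, preserving the joined pair's distance. The result is unrooted
#' (root trifurcation) and exact on additive matrices.
#'
#' @param d Symmetric distance matrix with labels as dimnames (or a
#'   `dist`). At least 3 taxa.
#' @return An \pkg{ape} `phylo` object.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  stopifnot(!anyDuplicated(labels))

  # node bookkeeping: tips 1..n, internals appended as created
  kids <- vector("list", 2L * n)
  blen <- rep(NA_real_, 2L * n)
  next_node <- n + 1L
  active <- seq_len(n)      # node ids
  D <- unname(d)

  while (length(active) > 3L) {
    na <- length(active)
    R <- rowSums(D)
    Q <- (na - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]

    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (na - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bi <- 0; bj <- D[i, j] }
    if (bj < 0) { bj <- 0; bi <- D[i, j] }

    u <- next_node
    next_node <- next_node + 1L
    kids[[u]] <- c(active[i], active[j])
    blen[active[i]] <- bi
    blen[active[j]] <- bj

    others <- setdiff(seq_len(na), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    active <- c(active[others], u)
  }

  # root trifurcation over the last three nodes
  x <- active[1]; y <- active[2]; z <- active[3]
  bx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  by <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root <- next_node
  kids[[root]] <- c(x, y, z)
  blen[x] <- max(bx, 0)
  blen[y] <- max(by, 0)
  blen[z] <- max(bz, 0)

  as_phylo_from_kids(kids, blen, n, labels, root)
}

# convert the internal kids/branch-length bookkeeping to an ape phylo,
# renumbering internal nodes in preorder so the root is n+1
as_phylo_from_kids <- function(kids, blen, n_tips, labels, root) {
  n_internal <- root - n_tips
  edge <- matrix(0L, nrow = 0, ncol = 2)
  elen <- numeric(0)
  new_id <- integer(root)
  next_int <- n_tips + 1L

  visit <- function(old) {
    if (old <= n_tips) {
      new_id[old] <<- old
    } else {
      new_id[old] <<- next_int
      next_int <<- next_int + 1L
      for (ch in kids[[old]]) {
        visit(ch)
        edge <<- rbind(edge, c(new_id[old], new_id[ch]))
        elen <<- c(elen, blen[ch])
      }
    }
  }
  visit(root)

  tr <- list(edge = edge, edge.length = elen, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalised
#' to the side whose sorted, comma-joined label string is lexicographically
#' smaller, so the key is stable under side swap.
#'
#' @param tree A `phylo` object.
#' @return Tibble with `node` (the ape node id whose subtree defines the
#'   split) and `key` (canonical bipartition string).
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "postorder") {
    tree_po <- ape::reorder.phylo(tree, "postorder")
  } else {
    tree_po <- tree
  }
  clades <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) clades[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree_po$edge))) {
    p <- tree_po$edge[k, 1]
    ch <- tree_po$edge[k, 2]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  root <- n + 1L
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  keep <- internal[vapply(internal, function(nd) {
    sz <- length(clades[[nd]])
    sz >= 2 && sz <= n - 2
  }, logical(1))]
  tibble::tibble(
    node = keep,
    key = vapply(keep, function(nd) {
      canonical_split(clades[[nd]], tree$tip.label)
    }, character(1))
  )
}

canonical_split <- function(side, all_labels) {
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(setdiff(all_labels, side)), collapse = ",")
  if (a <= b) a else b
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilds the tree each time, and attaches to
#' each internal edge of the full tree the percentage of replicates whose
#' tree contains the same bipartition. Replicate `r` draws its columns
#' under seed `seed + r`, making the whole analysis reproducible from one
#' integer. Saturated distances inside a replicate fall back to p-distance
#' (see [msa_distances()]).
#'
#' @param msa Named character vector of at least 4 equal-length gapped DNA
#'   strings.
#' @param n_reps Number of pseudo-replicates (default 100).
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param model Distance model passed to [msa_distances()].
#' @return The full-data `phylo` with `node.label` holding supports in
#'   `[0, 100]` (empty at the root).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = NULL,
                              model = "jc69") {
  stopifnot(length(msa) >= 4)
  full <- nj_tree(msa_distances(msa, model = model))
  bip <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, nrow(bip)), bip$key)

  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  ncols <- ncol(m)
  for (r in seq_len(n_reps)) {
    cols <- with_rng_seed(if (is.null(seed)) NULL else seed + r,
                          sample.int(ncols, ncols, replace = TRUE))
    rep_msa <- stats::setNames(
      apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
      names(msa))
    rep_tree <- nj_tree(msa_distances(rep_msa, model = model))
    rep_keys <- tree_bipartitions(rep_tree)$key
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }

  support <- 100 * counts / n_reps
  n <- length(full$tip.label)
  labels <- rep("", full$Nnode)
  labels[bip$node - n] <- format(support, trim = TRUE)
  full$node.label <- labels
  full
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser and serialiser. Supports
#' ride as internal node labels; branch lengths survive a round trip to at
#' least 6 decimals.
#'
#' @param tree A `phylo` object.
#' @param path File path; for `write_newick`, `NULL` returns the Newick
#'   string instead of writing.
#' @return `read_newick`: a `phylo`. `write_newick`: the Newick string,
#'   invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
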
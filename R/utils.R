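DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input. `N` stays `N`; all sequences are assumed
#' uppercase over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TAGGGTTG")
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# split one sequence into a character vector of bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# complement of a character vector of bases
comp_chars <- function(ch) chartr("ACGTN", "TGCAN", ch)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so seeded package operations never perturb a user's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' Uniform over `{A,C,G,T}`, drawn from the current RNG stream.
#'
#' @param n Length in bp.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
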
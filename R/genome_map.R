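#' Genetic map for a single simulated chromosome
#'
#' A `genome_map` describes the marker grid on which haplotypes are observed:
#' the number of SNPs `L`, the genetic length `D` of the chromosome in
#' Morgans, and the genetic-map position of every SNP in `(0, D]`. One Morgan
#' corresponds to one expected crossover per meiosis, so `D` controls how
#' finely ancestry tracts are broken up each generation.
#'
#' By default markers are evenly spaced, with SNP `l` at position `l * D / L`.
#' A custom (strictly increasing) position vector may be supplied to model a
#' non-uniform marker density; the recombination process itself is always
#' uniform per Morgan.
#'
#' @param L Positive integer, number of SNPs.
#' @param D Positive number, genetic length in Morgans (default 5).
#' @param positions Optional numeric vector of length `L`, strictly increasing
#'   genetic positions in `(0, D]`. Defaults to even spacing.
#'
#' @return An object of class `genome_map`: a list with elements `L`, `D`
#'   and `positions`.
#' @examples
#' gm <- genome_map(L = 500, D = 5)
#' gm$positions[1:3]
#' @export
genome_map <- function(L, D = 5, positions = NULL) {
  stopifnot(is.numeric(L), length(L) == 1, L >= 0, L == floor(L))
  stopifnot(is.numeric(D), length(D) == 1, D > 0)
  L <- as.integer(L)
  if (is.null(positions)) {
    positions <- if (L > 0) seq_len(L) * D / L else numeric(0)
  } else {
    positions <- as.numeric(positions)
    if (length(positions) != L) {
      stop("`positions` must have length L = ", L, call. = FALSE)
    }
    if (L > 0) {
      if (any(diff(positions) <= 0)) {
        stop("`positions` must be strictly increasing", call. = FALSE)
      }
      if (positions[1] <= 0 || positions[L] > D) {
        stop("`positions` must lie in (0, D]", call. = FALSE)
      }
    }
  }
  structure(list(L = L, D = D, positions = positions), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$L, " SNPs over ", format(x$D), " Morgans\n", sep = "")
  invisible(x)
}

is_genome_map <- function(x) inherits(x, "genome_map")
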
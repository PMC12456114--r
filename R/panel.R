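#' Haplotype panel: one generation of diploid individuals
#'
#' A `hap_panel` holds three aligned `N x 2 x L` arrays for one generation of
#' `N` diploid individuals observed at `L` SNPs:
#'
#' * `G` — genotype track, 0 for the reference allele, 1 for the alternate;
#' * `A` — local-ancestry track, 1 where the haplotype segment descends from
#'   the conservation *target* population, 0 where it is *introgressed*;
#' * `F` — founder-label track, an integer identifying which founder
#'   haplotype each segment was inherited from.
#'
#' The second dimension indexes the two haplotype copies of each individual.
#' All three tracks are propagated jointly through meiosis, so `F` records an
#' exact "local pedigree" from which identity-by-descent (and hence empirical
#' kinship) can be read off directly, and `A` records the true local ancestry
#' that, on real data, would come from a local-ancestry inference pipeline.
#'
#' @param G,A Binary `N x 2 x L` arrays (genotype, ancestry).
#' @param F_ Integer `N x 2 x L` array of founder-haplotype labels. If `NULL`,
#'   founder labels are initialised as for a founder generation (see
#'   [init_founder_labels()]).
#' @param t Generation index, non-negative integer (default 0).
#'
#' @return An object of class `hap_panel`: a list with elements `t`, `G`,
#'   `A`, `F`.
#' @seealso [realized_scores()], [expected_pair_matrix()], [make_offspring()]
#' @examples
#' G <- array(0L, c(2, 2, 3)); A <- array(1L, c(2, 2, 3))
#' p <- hap_panel(G, A)
#' p$F[1, , 1]  # founder labels 1 and 2 on individual 1
#' @export
hap_panel <- function(G, A, F_ = NULL, t = 0L) {
  dG <- dim(G)
  if (length(dG) != 3 || dG[2] != 2) {
    stop("`G` must be an N x 2 x L array", call. = FALSE)
  }
  if (!identical(dim(A), dG)) stop("`A` must match dim(G)", call. = FALSE)
  if (any(G != 0L & G != 1L)) stop("`G` must be binary 0/1", call. = FALSE)
  if (any(A != 0L & A != 1L)) stop("`A` must be binary 0/1", call. = FALSE)
  if (is.null(F_)) {
    F_ <- init_founder_labels(dG[1], dG[3])
  } else if (!identical(dim(F_), dG)) {
    stop("`F_` must match dim(G)", call. = FALSE)
  }
  storage.mode(G) <- "integer"
  storage.mode(A) <- "integer"
  storage.mode(F_) <- "integer"
  structure(list(t = as.integer(t), G = G, A = A, F = F_),
            class = "hap_panel")
}

#' Founder-generation labels for the local pedigree
#'
#' Assigns every haplotype in a founder generation a unique integer label:
#' individual `i` carries labels `2i - 1` (haplotype 1) and `2i` (haplotype
#' 2), constant along the chromosome. Self-comparisons between the two
#' copies of a founder therefore never match, so the founder kinship score
#' is exactly zero.
#'
#' @param N Number of diploid founders.
#' @param L Number of SNPs.
#' @return Integer `N x 2 x L` array of labels in `1..2N`.
#' @export
init_founder_labels <- function(N, L) {
  lab <- array(0L, c(N, 2L, L))
  lab[, 1L, ] <- 2L * seq_len(N) - 1L
  lab[, 2L, ] <- 2L * seq_len(N)
  lab
}

#' @export
print.hap_panel <- function(x, ...) {
  d <- dim(x$G)
  cat("<hap_panel> generation ", x$t, ": ", d[1], " diploids x ", d[3],
      " SNPs\n", sep = "")
  cat("  mean target ancestry: ", format(mean(x$A), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel A [hap_panel()].
#' @return Integer.
#' @export
n_individuals <- function(panel) dim(panel$G)[1]

#' @rdname n_individuals
#' @export
n_loci <- function(panel) dim(panel$G)[3]

is_hap_panel <- function(x) inherits(x, "hap_panel")

# 2N x L matrix view of one track: rows 1..N are haplotype copy 1,
# rows N+1..2N copy 2. Block-averaging over the four N x N quadrants of a
# haplotype-level similarity matrix then yields the pairwise expected
# measures in one or two crossproducts.
hap_matrix <- function(track) {
  N <- dim(track)[1]
  L <- dim(track)[3]
  rbind(matrix(track[, 1L, ], N, L), matrix(track[, 2L, ], N, L))
}

# Subset a panel to the given individuals (in the given order).
panel_subset <- function(panel, idx, t = panel$t) {
  hap_panel(panel$G[idx, , , drop = FALSE],
            panel$A[idx, , , drop = FALSE],
            panel$F[idx, , , drop = FALSE],
            t = t)
}
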
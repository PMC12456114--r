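#' Simulate a gamete inheritance vector by independent crossover
#'
#' Generates the inheritance vector `a` of a single gamete: for each SNP,
#' which of the parent's two haplotype copies (1 or 2) the gamete carries.
#' The crossover process is the standard no-interference model: starting at
#' genetic position 0 on a randomly chosen haplotype, segment lengths are
#' drawn i.i.d. Exponential(1) in Morgans and the active haplotype flips at
#' every breakpoint, until the chromosome end is passed. The number of
#' crossovers per gamete is therefore Poisson with mean `D`.
#'
#' `start_hap` and `seg_lengths` allow a fully scripted draw (used for
#' deterministic replay); when `NULL` they are drawn from R's RNG.
#'
#' @param genome_map A [genome_map()].
#' @param start_hap Optional 1 or 2: haplotype active at position 0.
#' @param seg_lengths Optional numeric vector of segment lengths in Morgans;
#'   must reach past the last SNP position.
#' @return Integer vector of length `L` over `{1, 2}`.
#' @examples
#' gm <- genome_map(4, D = 1)
#' simulate_gamete(gm, start_hap = 1, seg_lengths = c(0.6, 2))  # 1 1 2 2
#' @export
simulate_gamete <- function(genome_map, start_hap = NULL, seg_lengths = NULL) {
  stopifnot(is_genome_map(genome_map))
  L <- genome_map$L
  if (L == 0L) return(integer(0))
  h <- if (is.null(start_hap)) sample.int(2L, 1L) else as.integer(start_hap)
  stopifnot(h %in% c(1L, 2L))
  end_pos <- genome_map$positions[L]
  if (is.null(seg_lengths)) {
    # draw breakpoints in batches until the chromosome is covered
    ends <- cumsum(stats::rexp(max(8L, ceiling(end_pos + 4 * sqrt(end_pos) + 8))))
    while (ends[length(ends)] <= end_pos) {
      ends <- c(ends, ends[length(ends)] + cumsum(stats::rexp(16L)))
    }
  } else {
    ends <- cumsum(as.numeric(seg_lengths))
    if (ends[length(ends)] <= end_pos) {
      stop("`seg_lengths` do not cover the chromosome", call. = FALSE)
    }
  }
  # segment b covers positions [ends[b-1], ends[b}); SNP l belongs to the
  # first segment whose end exceeds its position
  seg <- findInterval(genome_map$positions, c(0, ends),
                      left.open = FALSE, rightmost.closed = FALSE)
  a <- as.integer(ifelse(seg %% 2L == 1L, h, 3L - h))
  # underlying breakpoint count on (0, R_L): Poisson(R_L) by construction.
  # Marker-level switches undercount it whenever two crossovers fall in one
  # inter-SNP gap, so the true count is carried as an attribute.
  attr(a, "n_crossovers") <- sum(ends < end_pos)
  a
}

#' Number of crossovers of a gamete
#'
#' Uses the exact breakpoint count recorded by [simulate_gamete()] when
#' present; otherwise falls back to counting switches between adjacent SNPs
#' (a slight undercount when two crossovers land in one inter-SNP gap).
#' @param a Inheritance vector from [simulate_gamete()].
#' @return Integer crossover count.
#' @export
count_crossovers <- function(a) {
  n <- attr(a, "n_crossovers")
  if (!is.null(n)) return(as.integer(n))
  if (length(a) < 2L) return(0L)
  sum(a[-1L] != a[-length(a)])
}

#' Create one offspring from two parents by simulated meiosis
#'
#' Draws one gamete from each parent with [simulate_gamete()] and propagates
#' the genotype, ancestry and founder-label tracks with the *same*
#' inheritance vector per gamete, so all three stay aligned. Haplotype 1 of
#' the child comes from `parent_i`, haplotype 2 from `parent_j`.
#'
#' @param panel A [hap_panel()].
#' @param parent_i,parent_j Distinct individual indices in `panel`.
#' @param genome_map A [genome_map()] matching the panel's locus count.
#' @param gamete_i,gamete_j Optional scripted inheritance vectors (for
#'   deterministic replay); drawn if `NULL`.
#' @return A list with `G`, `A`, `F`: each a `2 x L` integer matrix
#'   (haplotype copies in rows).
#' @export
make_offspring <- function(panel, parent_i, parent_j, genome_map,
                           gamete_i = NULL, gamete_j = NULL) {
  stopifnot(is_hap_panel(panel))
  N <- n_individuals(panel)
  if (parent_i == parent_j) stop("self-mating is not permitted", call. = FALSE)
  stopifnot(parent_i >= 1, parent_i <= N, parent_j >= 1, parent_j <= N)
  if (genome_map$L != n_loci(panel)) {
    stop("genome_map L does not match panel", call. = FALSE)
  }
  ai <- if (is.null(gamete_i)) simulate_gamete(genome_map) else gamete_i
  aj <- if (is.null(gamete_j)) simulate_gamete(genome_map) else gamete_j
  L <- genome_map$L
  li <- cbind(parent_i, ai, seq_len(L))  # index matrix into N x 2 x L
  lj <- cbind(parent_j, aj, seq_len(L))
  list(
    G = rbind(panel$G[li], panel$G[lj]),
    A = rbind(panel$A[li], panel$A[lj]),
    F = rbind(panel$F[li], panel$F[lj])
  )
}

# Breed a full next generation by Wright-Fisher random mating: each of
# `n_out` offspring draws two distinct uniform parents. Returns a hap_panel
# at generation t+1.
wf_generation <- function(panel, genome_map, n_out = n_individuals(panel)) {
  N <- n_individuals(panel)
  stopifnot(N >= 2)
  L <- n_loci(panel)
  G <- array(0L, c(n_out, 2L, L))
  A <- array(0L, c(n_out, 2L, L))
  F_ <- array(0L, c(n_out, 2L, L))
  for (k in seq_len(n_out)) {
    pr <- sample.int(N, 2L, replace = FALSE)
    off <- make_offspring(panel, pr[1L], pr[2L], genome_map)
    G[k, , ] <- off$G
    A[k, , ] <- off$A
    F_[k, , ] <- off$F
  }
  hap_panel(G, A, F_, t = panel$t + 1L)
}
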
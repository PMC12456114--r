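#' Selection-measure specification
#'
#' The breeding algorithms select on one of seven pairwise expected measures,
#' each the expectation over the four equiprobable haplotype pairs a
#' potential offspring of two individuals could inherit, averaged over loci:
#'
#' * `K`  — empirical kinship: probability two allele copies share a founder
#'   haplotype (identity by descent from the program founders). Minimized.
#' * `H`  — expected heterozygosity: probability the two copies differ in
#'   allelic state. Maximized.
#' * `Q`  — target-population admixture: expected dose of target ancestry.
#'   Maximized (equivalently `1 - Q`, the introgressed fraction, minimized).
#' * `PH` — population heterozygosity: heterozygosity with any haplotype
#'   pair not fully of target ancestry masked to 0. Maximized.
#' * `PK` — population kinship: kinship with non-target pairs masked to 1,
#'   so only target-ancestry, founder-distinct pairs are rewarded. Minimized.
#' * `WPH` — weighted population heterozygosity: convex combination putting
#'   weight `delta` on `PH` and `1 - delta` on the admixture dose. Maximized.
#' * `WPK` — weighted population kinship: weight `delta` on `PK` and
#'   `1 - delta` on the introgressed dose `1 - Q`. Minimized.
#'
#' `RANDOM` is accepted as a strategy name by the breeding driver (no measure
#' is computed; mating is random).
#'
#' @param id One of `"K"`, `"H"`, `"Q"`, `"PH"`, `"PK"`, `"WPH"`, `"WPK"`.
#' @param delta Weight in `[0, 1]` used by `WPH`/`WPK` (default 0.5, which
#'   for `WPH` weights heterozygosity and ancestry dose equally: per-locus
#'   offspring values 0 / 0.25 / 0.5 / 1 for no target allele / one target
#'   allele / two identical target alleles / heterozygous target alleles).
#' @return An object of class `measure_spec` with fields `id`, `delta` and
#'   `direction` (`"minimize"` or `"maximize"`).
#' @export
measure_spec <- function(id, delta = 0.5) {
  id <- toupper(id)
  ids <- c("K", "H", "Q", "PH", "PK", "WPH", "WPK")
  if (!id %in% ids) {
    stop("unknown measure id: ", id, " (expected one of ",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  }
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1)
  direction <- if (id %in% c("K", "PK", "WPK")) "minimize" else "maximize"
  structure(list(id = id, delta = delta, direction = direction),
            class = "measure_spec")
}

#' @export
print.measure_spec <- function(x, ...) {
  cat("<measure_spec> ", x$id, " (", x$direction, ")",
      if (x$id %in% c("WPH", "WPK")) paste0(", delta = ", x$delta), "\n",
      sep = "")
  invisible(x)
}

#' Per-locus expected measure for one pair of individuals
#'
#' Evaluates the selected measure kernel at a single locus by explicit
#' enumeration of the four haplotype pairs `(a, b)` an offspring could
#' inherit, one copy from each parent. This is the reference (scalar)
#' evaluation; [expected_pair_matrix()] computes the same quantities
#' vectorized over all pairs and loci.
#'
#' @param measure A [measure_spec()].
#' @param G_i,A_i,F_i Length-2 vectors: individual `i`'s two haplotype values
#'   at the locus (genotype 0/1, ancestry 0/1, integer founder label).
#' @param G_j,A_j,F_j Same for individual `j` (which may equal `i`).
#' @return A number in `[0, 1]`.
#' @examples
#' m <- measure_spec("Q")
#' per_locus_pair_measure(m, A_i = c(1, 0), A_j = c(1, 1))  # 0.75
#' @export
per_locus_pair_measure <- function(measure, G_i = NULL, A_i = NULL, F_i = NULL,
                                   G_j = NULL, A_j = NULL, F_j = NULL) {
  stopifnot(inherits(measure, "measure_spec"))
  d <- measure$delta
  acc <- 0
  for (a in 1:2) {
    for (b in 1:2) {
      acc <- acc + switch(
        measure$id,
        K   = (F_i[a] == F_j[b]),
        H   = (G_i[a] != G_j[b]),
        Q   = (A_i[a] + A_j[b]) / 2,
        PH  = (A_i[a] + A_j[b] == 2) * (G_i[a] != G_j[b]),
        PK  = (A_i[a] + A_j[b] == 2) * (F_i[a] != F_j[b]),
        WPH = ((1 - d) * (A_i[a] + A_j[b]) +
                 2 * d * (A_i[a] + A_j[b] == 2) * (G_i[a] != G_j[b])) / 2,
        WPK = ((1 - d) * (2 - A_i[a] - A_j[b]) +
                 2 * d * (1 - (A_i[a] + A_j[b] == 2) * (F_i[a] != F_j[b]))) / 2
      )
    }
  }
  val <- acc / 4
  if (measure$id == "PK") val <- 1 - val
  as.numeric(val)
}

# Average the four N x N haplotype-pair blocks of a 2N x 2N haplotype
# similarity matrix (rows/cols 1..N = copy 1, N+1..2N = copy 2).
block_average <- function(S, N) {
  i1 <- seq_len(N)
  i2 <- N + i1
  (S[i1, i1, drop = FALSE] + S[i1, i2, drop = FALSE] +
     S[i2, i1, drop = FALSE] + S[i2, i2, drop = FALSE]) / 4
}

# Sparse one-hot encoding of founder labels per (haplotype, locus), with an
# optional binary mask (same shape) zeroing entries out. tcrossprod of the
# result counts per-pair loci with matching labels (within the mask).
founder_onehot <- function(Fhap, mask = NULL) {
  nh <- nrow(Fhap)
  L <- ncol(Fhap)
  # compact the label space: only labels still segregating matter
  labs <- sort(unique(as.vector(Fhap)))
  Fhap <- matrix(match(Fhap, labs), nh, L)
  maxlab <- length(labs)
  keep <- if (is.null(mask)) rep(TRUE, nh * L) else as.vector(mask) == 1L
  i <- rep(seq_len(nh), times = L)[keep]
  l <- rep(seq_len(L), each = nh)[keep]
  j <- (l - 1L) * maxlab + as.vector(Fhap)[keep]
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nh, L * maxlab))
}

#' Pairwise expected-measure matrix over a panel
#'
#' Computes the `N x N` symmetric matrix whose `(i, j)` entry is the mean
#' over loci of the per-locus expected measure for the potential offspring
#' of individuals `i` and `j`. The diagonal is computed with the same
#' kernels at `i = j` (it feeds the ranking averages; self-pairs are never
#' bred). The computation is exact — matrix cross-products over haplotype
#' tracks, not Monte Carlo.
#'
#' @param measure A [measure_spec()].
#' @param panel A [hap_panel()].
#' @return A `pairwise_matrix`: the numeric matrix with the `measure_spec`
#'   attached as attribute `measure`.
#' @export
expected_pair_matrix <- function(measure, panel) {
  stopifnot(inherits(measure, "measure_spec"), is_hap_panel(panel))
  N <- n_individuals(panel)
  L <- n_loci(panel)
  Ah <- hap_matrix(panel$A)
  M <- switch(
    measure$id,
    K = {
      S <- as.matrix(Matrix::tcrossprod(founder_onehot(hap_matrix(panel$F))))
      block_average(S, N) / L
    },
    H = {
      Gh <- hap_matrix(panel$G)
      s <- rowSums(Gh)
      mism <- outer(s, rep(1, 2 * N)) + outer(rep(1, 2 * N), s) -
        2 * tcrossprod(Gh)
      block_average(mism, N) / L
    },
    Q = {
      q <- (rowMeans(matrix(panel$A[, 1L, ], N, L)) +
              rowMeans(matrix(panel$A[, 2L, ], N, L))) / 2
      (outer(q, rep(1, N)) + outer(rep(1, N), q)) / 2
    },
    PH = ph_counts(panel) / L,
    PK = {
      AA <- tcrossprod(Ah)
      eqm <- as.matrix(Matrix::tcrossprod(
        founder_onehot(hap_matrix(panel$F), mask = Ah)))
      1 - block_average(AA - eqm, N) / L
    },
    WPH = {
      q <- (rowMeans(matrix(panel$A[, 1L, ], N, L)) +
              rowMeans(matrix(panel$A[, 2L, ], N, L))) / 2
      Qm <- (outer(q, rep(1, N)) + outer(rep(1, N), q)) / 2
      (1 - measure$delta) * Qm + measure$delta * ph_counts(panel) / L
    },
    WPK = {
      q <- (rowMeans(matrix(panel$A[, 1L, ], N, L)) +
              rowMeans(matrix(panel$A[, 2L, ], N, L))) / 2
      Qm <- (outer(q, rep(1, N)) + outer(rep(1, N), q)) / 2
      AA <- tcrossprod(Ah)
      eqm <- as.matrix(Matrix::tcrossprod(
        founder_onehot(hap_matrix(panel$F), mask = Ah)))
      PKm <- 1 - block_average(AA - eqm, N) / L
      (1 - measure$delta) * (1 - Qm) + measure$delta * PKm
    }
  )
  M <- (M + t(M)) / 2  # enforce exact symmetry against rounding
  structure(M, measure = measure, class = c("pairwise_matrix", "matrix", "array"))
}

# Sum over loci of the masked-heterozygosity counts for all haplotype pairs,
# block-averaged: entry (i,j) = sum_l (1/4) sum_ab A_ial A_jbl I(G != G).
ph_counts <- function(panel) {
  N <- n_individuals(panel)
  Ah <- hap_matrix(panel$A)
  Gh <- hap_matrix(panel$G)
  X <- Ah * Gh
  counts <- tcrossprod(X, Ah) + tcrossprod(Ah, X) - 2 * tcrossprod(X)
  block_average(counts, N)
}

#' Realized population scores for one generation
#'
#' Scores summarise the current generation itself (no expectation over
#' offspring): each is a mean over individuals and loci.
#'
#' * `S_Q`  — mean target-ancestry dose `(A_1 + A_2) / 2`; `1 - S_Q` is the
#'   introgressed fraction.
#' * `S_H`  — proportion of heterozygous (individual, locus) pairs.
#' * `S_K`  — proportion of loci where an individual's two copies share a
#'   founder label (zero in the founder generation by construction).
#' * `S_PH` — heterozygosity restricted to loci where both copies are target
#'   ancestry (others contribute 0).
#' * `S_PK` — kinship with non-target loci masked to 1: only target-diploid,
#'   founder-distinct loci score 0.
#'
#' @param panel A [hap_panel()].
#' @param replicate Optional replicate id carried into the output.
#' @return One-row tibble: `replicate` (if given), `generation`, `S_Q`,
#'   `S_H`, `S_K`, `S_PH`, `S_PK`.
#' @export
realized_scores <- function(panel, replicate = NULL) {
  s <- realized_individual_scores(panel)
  out <- tibble::tibble(
    generation = panel$t,
    S_Q = mean(s$S_Q), S_H = mean(s$S_H), S_K = mean(s$S_K),
    S_PH = mean(s$S_PH), S_PK = mean(s$S_PK)
  )
  if (!is.null(replicate)) out <- tibble::add_column(out, replicate = replicate, .before = 1)
  out
}

#' Per-individual realized scores
#'
#' The individual-level decomposition of [realized_scores()], plus the
#' weighted combinations `S_WPH = (1-delta) S_Q + delta S_PH` and
#' `S_WPK = (1-delta)(1-S_Q) + delta S_PK` used by the threshold breeding
#' rule.
#'
#' @param panel A [hap_panel()].
#' @param delta Weight for the weighted scores (default 0.5).
#' @return Tibble with one row per individual: `individual`, `S_Q`, `S_H`,
#'   `S_K`, `S_PH`, `S_PK`, `S_WPH`, `S_WPK`.
#' @export
realized_individual_scores <- function(panel, delta = 0.5) {
  N <- n_individuals(panel)
  L <- n_loci(panel)
  G1 <- matrix(panel$G[, 1L, ], N, L); G2 <- matrix(panel$G[, 2L, ], N, L)
  A1 <- matrix(panel$A[, 1L, ], N, L); A2 <- matrix(panel$A[, 2L, ], N, L)
  F1 <- matrix(panel$F[, 1L, ], N, L); F2 <- matrix(panel$F[, 2L, ], N, L)
  het <- G1 != G2
  dip <- A1 * A2           # both copies target ancestry
  S_Q <- rowMeans((A1 + A2) / 2)
  S_H <- rowMeans(het)
  S_K <- rowMeans(F1 == F2)
  S_PH <- rowMeans(dip * het)
  S_PK <- rowMeans(1 - dip * (F1 != F2))
  tibble::tibble(
    individual = seq_len(N),
    S_Q = S_Q, S_H = S_H, S_K = S_K, S_PH = S_PH, S_PK = S_PK,
    S_WPH = (1 - delta) * S_Q + delta * S_PH,
    S_WPK = (1 - delta) * (1 - S_Q) + delta * S_PK
  )
}

#' Realized per-locus weighted values
#'
#' The weighted population heterozygosity of a single realized (individual,
#' locus) pair: `(1-delta)` times the target-ancestry dose plus `delta`
#' times the masked heterozygosity indicator. At `delta = 0.5` this gives 0
#' for no target alleles, 0.25 for a single target allele, 0.5 for two
#' identical target alleles and 1 for heterozygous target alleles.
#' `wpk_locus_value()` is the kinship analogue (to be minimized).
#'
#' @param a Length-2 ancestry indicators of the two copies (0/1).
#' @param g Length-2 allelic states (0/1).
#' @param f Length-2 founder labels (integers).
#' @param delta Weight in `[0, 1]` (default 0.5).
#' @return A number in `[0, 1]`.
#' @export
wph_locus_value <- function(a, g, delta = 0.5) {
  (1 - delta) * (a[1] + a[2]) / 2 + delta * (a[1] * a[2]) * (g[1] != g[2])
}

#' @rdname wph_locus_value
#' @export
wpk_locus_value <- function(a, f, delta = 0.5) {
  (1 - delta) * (1 - (a[1] + a[2]) / 2) +
    delta * (1 - (a[1] * a[2]) * (f[1] != f[2]))
}
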
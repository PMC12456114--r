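test_that("per-locus kernels match hand enumeration on the worked cases", {
  # kinship: disjoint founders vs full-sib clone sharing
  K <- measure_spec("K")
  expect_equal(per_locus_pair_measure(K, F_i = c(1, 2), F_j = c(3, 4)), 0)
  expect_equal(per_locus_pair_measure(K, F_i = c(1, 2), F_j = c(1, 2)), 0.5)
  # admixture dose
  Q <- measure_spec("Q")
  expect_equal(per_locus_pair_measure(Q, A_i = c(1, 0), A_j = c(1, 1)), 0.75)
  # masked heterozygosity: only the two a = 1 pairs pass the diploidy mask
  PH <- measure_spec("PH")
  expect_equal(per_locus_pair_measure(PH, G_i = c(0, 1), A_i = c(1, 0),
                                      G_j = c(1, 1), A_j = c(1, 1)), 0.5)
  # masked kinship: one masked-in, founder-distinct pair
  PK <- measure_spec("PK")
  expect_equal(per_locus_pair_measure(PK, A_i = c(1, 1), F_i = c(1, 2),
                                      A_j = c(1, 0), F_j = c(1, 4)), 0.75)
  expect_error(measure_spec("XYZ"), "unknown measure")
})

test_that("realized weighted per-locus values give 0 / 0.25 / 0.5 / 1", {
  # no target alleles; a single target allele; two identical target
  # alleles; heterozygous target alleles
  expect_equal(wph_locus_value(c(0, 0), c(0, 1)), 0)
  expect_equal(wph_locus_value(c(1, 0), c(0, 1)), 0.25)
  expect_equal(wph_locus_value(c(1, 1), c(1, 1)), 0.5)
  expect_equal(wph_locus_value(c(1, 1), c(0, 1)), 1)
  # relative weights 0 : 1 : 2 : 4
  v <- c(wph_locus_value(c(0, 0), c(0, 1)), wph_locus_value(c(1, 0), c(0, 1)),
         wph_locus_value(c(1, 1), c(1, 1)), wph_locus_value(c(1, 1), c(0, 1)))
  expect_equal(v / v[2], c(0, 1, 2, 4))
  # kinship analogue is its mirror: best (0) for het target founders
  expect_equal(wpk_locus_value(c(0, 0), c(1, 2)), 1)
  expect_equal(wpk_locus_value(c(1, 1), c(1, 2)), 0)
  expect_equal(wpk_locus_value(c(1, 1), c(1, 1)), 0.5)
})

test_that("expected_pair_matrix agrees with the offspring-enumeration oracle", {
  set.seed(501)
  # hand-built 3-individual, 4-locus panel plus random panels
  panels <- c(list(random_panel(3, 4, n_labels = 4)),
              lapply(1:3, function(i) random_panel(4, 6, n_labels = 5)))
  for (p in panels) {
    for (id in c("K", "H", "Q", "PH", "PK", "WPH", "WPK")) {
      M <- expected_pair_matrix(measure_spec(id), p)
      O <- oracle_matrix(id, p)
      expect_equal(unclass(M), O, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("matrix path agrees with scalar kernel evaluation", {
  set.seed(502)
  p <- random_panel(3, 5, n_labels = 6)
  for (id in c("K", "H", "Q", "PH", "PK", "WPH", "WPK")) {
    m <- measure_spec(id, delta = 0.3)
    M <- expected_pair_matrix(m, p)
    for (i in 1:3) for (j in 1:3) {
      v <- mean(vapply(1:5, function(l) per_locus_pair_measure(
        m, G_i = p$G[i, , l], A_i = p$A[i, , l], F_i = p$F[i, , l],
        G_j = p$G[j, , l], A_j = p$A[j, , l], F_j = p$F[j, , l]),
        numeric(1)))
      expect_equal(M[i, j], v, tolerance = 1e-12)
    }
  }
})

test_that("weighting identities and masking bounds hold on random panels", {
  set.seed(503)
  for (rep in 1:3) {
    p <- random_panel(5, 8, n_labels = 6, p_anc = runif(1, 0.2, 0.9))
    Q <- unclass(expected_pair_matrix(measure_spec("Q"), p))
    H <- unclass(expected_pair_matrix(measure_spec("H"), p))
    K <- unclass(expected_pair_matrix(measure_spec("K"), p))
    PH <- unclass(expected_pair_matrix(measure_spec("PH"), p))
    PK <- unclass(expected_pair_matrix(measure_spec("PK"), p))
    # delta endpoints collapse the weighted measures
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPH", 0), p)), Q,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPH", 1), p)), PH,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPK", 0), p)),
                 1 - Q, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPK", 1), p)), PK,
                 tolerance = 1e-12, ignore_attr = TRUE)
    # interior delta is the exact convex combination
    d <- 0.37
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPH", d), p)),
                 (1 - d) * Q + d * PH, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(expected_pair_matrix(measure_spec("WPK", d), p)),
                 (1 - d) * (1 - Q) + d * PK, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # masking bounds and self-kinship
    expect_true(all(PH <= H + 1e-12))
    expect_true(all(PK >= K - 1e-12))
    expect_true(all(diag(K) >= 0.5))
    for (M in list(Q, H, K, PH, PK)) {
      expect_true(all(M >= -1e-12 & M <= 1 + 1e-12))
      expect_equal(M, t(M))
    }
  }
})

test_that("clone panels give constant kinship 0.5 off-diagonal", {
  L <- 6
  tr <- function(v) array(rep(v, each = 3), c(3, 2, L))
  F_ <- array(0L, c(3, 2, L)); F_[, 1, ] <- 1L; F_[, 2, ] <- 2L
  p <- hap_panel(tr(0L) * 0L, array(1L, c(3, 2, L)), F_)
  K <- expected_pair_matrix(measure_spec("K"), p)
  expect_equal(K[upper.tri(K)], rep(0.5, 3))
  expect_equal(diag(unclass(K)), rep(0.5, 3), ignore_attr = TRUE)
})

test_that("realized scores behave at the masked and unmasked extremes", {
  set.seed(504)
  N <- 6; L <- 10
  G <- array(rbinom(N * 2 * L, 1, 0.5), c(N, 2, L))
  # founder panel: kinship score is exactly zero
  p0 <- hap_panel(G, array(1L, c(N, 2, L)))
  s0 <- realized_scores(p0)
  expect_equal(s0$S_K, 0)
  # mask inactive when all ancestry is target
  expect_equal(s0$S_PH, s0$S_H)
  expect_equal(s0$S_PK, s0$S_K)
  expect_equal(s0$S_Q, 1)
  # fully introgressed: PH collapses to 0, PK to 1
  p1 <- hap_panel(G, array(0L, c(N, 2, L)))
  s1 <- realized_scores(p1)
  expect_equal(s1$S_PH, 0)
  expect_equal(s1$S_PK, 1)
  expect_equal(s1$S_Q, 0)
  # score bounds and ordering on a random panel
  p2 <- random_panel(8, 12)
  s2 <- realized_scores(p2)
  expect_true(all(unlist(s2[, -1]) >= 0 & unlist(s2[, -1]) <= 1))
  expect_lte(s2$S_PH, s2$S_H)
  expect_gte(s2$S_PK, s2$S_K)
})

test_that("individual scores aggregate to population scores", {
  set.seed(505)
  p <- random_panel(7, 9)
  ind <- realized_individual_scores(p, delta = 0.5)
  pop <- realized_scores(p)
  for (col in c("S_Q", "S_H", "S_K", "S_PH", "S_PK")) {
    expect_equal(mean(ind[[col]]), pop[[col]])
  }
  expect_equal(ind$S_WPH, 0.5 * ind$S_Q + 0.5 * ind$S_PH)
  expect_equal(ind$S_WPK, 0.5 * (1 - ind$S_Q) + 0.5 * ind$S_PK)
})
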
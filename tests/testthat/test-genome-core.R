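test_that("genome_map defaults to even spacing and validates positions", {
  gm <- genome_map(4, D = 2)
  expect_equal(gm$positions, c(0.5, 1, 1.5, 2))
  expect_equal(genome_map(0, D = 1)$positions, numeric(0))
  expect_error(genome_map(3, D = 1, positions = c(0.5, 0.4, 0.9)),
               "increasing")
  expect_error(genome_map(3, D = 1, positions = c(0.2, 0.5, 1.2)),
               "\\(0, D\\]")
  expect_error(genome_map(3, D = 1, positions = c(0.2, 0.5)), "length")
})

test_that("scripted crossover reproduces the hand-traced inheritance vector", {
  gm <- genome_map(4, D = 1)  # positions 0.25 0.5 0.75 1.0
  # h = 1, segments 0.6 then 2.0: SNPs below 0.6 from copy 1, rest copy 2
  expect_equal(simulate_gamete(gm, start_hap = 1, seg_lengths = c(0.6, 2)),
               c(1L, 1L, 2L, 2L), ignore_attr = TRUE)
  # first segment covers the chromosome: no crossover at all
  expect_equal(simulate_gamete(gm, start_hap = 2, seg_lengths = 1.5),
               rep(2L, 4), ignore_attr = TRUE)
  expect_equal(count_crossovers(simulate_gamete(gm, start_hap = 2,
                                                seg_lengths = 1.5)), 0L)
  # breakpoint exactly on a SNP starts the new segment at that SNP
  expect_equal(simulate_gamete(gm, start_hap = 1, seg_lengths = c(0.5, 2)),
               c(1L, 2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(count_crossovers(simulate_gamete(gm, start_hap = 1,
                                                seg_lengths = c(0.5, 2))), 1L)
  expect_error(simulate_gamete(gm, start_hap = 1, seg_lengths = 0.5), "cover")
  expect_identical(simulate_gamete(genome_map(0, D = 1)), integer(0))
})

test_that("crossover count per gamete is Poisson with mean and variance D", {
  set.seed(401)
  gm <- genome_map(250, D = 5)
  n <- 10000
  x <- vapply(seq_len(n), function(i) count_crossovers(simulate_gamete(gm)),
              numeric(1))
  se <- sqrt(5 / n)
  expect_lt(abs(mean(x) - 5), 3 * se)
  # Poisson variance equals the mean; var of sample variance ~ 2 mu^2/n + mu/n
  expect_lt(abs(var(x) - 5), 4 * sqrt((2 * 25 + 5) / n))
  # the start haplotype is uniform
  firsts <- vapply(seq_len(2000), function(i) simulate_gamete(gm)[1],
                   integer(1))
  expect_gt(mean(firsts == 1L), 0.45)
  expect_lt(mean(firsts == 1L), 0.55)
})

test_that("offspring propagate all three tracks with one inheritance vector", {
  set.seed(402)
  gm <- genome_map(30, D = 2)
  p <- random_panel(4, 30)
  off <- make_offspring(p, 2, 3, gm,
                        gamete_i = rep(c(1L, 2L), each = 15),
                        gamete_j = rep(2L, 30))
  expect_identical(off$G[1, 1:15], p$G[2, 1, 1:15])
  expect_identical(off$G[1, 16:30], p$G[2, 2, 16:30])
  expect_identical(off$A[1, 1:15], p$A[2, 1, 1:15])
  expect_identical(off$F[1, 16:30], p$F[2, 2, 16:30])
  expect_identical(off$G[2, ], p$G[3, 2, ])
  expect_error(make_offspring(p, 2, 2, gm), "self-mating")
})

# duplicate a 1-individual panel track into 2 identical individuals
abind2 <- function(tr) {
  out <- array(0L, c(2, 2, dim(tr)[3]))
  out[1, , ] <- tr[1, , ]
  out[2, , ] <- tr[1, , ]
  out
}

test_that("ancestry and founder labels are conserved through meiosis", {
  set.seed(403)
  gm <- genome_map(40, D = 3)
  # both parents fully target ancestry -> child fully target
  G <- array(rbinom(2 * 2 * 40, 1, 0.5), c(2, 2, 40))
  A <- array(1L, c(2, 2, 40))
  p <- hap_panel(G, A)
  off <- make_offspring(p, 1, 2, gm)
  expect_true(all(off$A == 1L))
  # founder labels of children are a subset of the parents' labels
  p2 <- random_panel(5, 40, n_labels = 7)
  for (k in 1:10) {
    off <- make_offspring(p2, 1, 4, gm)
    expect_true(all(off$F %in% c(p2$F[1, , ], p2$F[4, , ])))
  }
  # clone parents labelled (1,2): child labels stay within {1,2}
  F12 <- array(rep(c(1L, 2L), each = 1), c(1, 2, 40))
  pc <- hap_panel(p$G[1, , , drop = FALSE], p$A[1, , , drop = FALSE], F12)
  clone2 <- hap_panel(abind2(pc$G), abind2(pc$A), abind2(pc$F))
  off <- make_offspring(clone2, 1, 2, gm)
  expect_true(all(off$F %in% c(1L, 2L)))
})

test_that("simulated offspring converge to the expected pair measures", {
  set.seed(404)
  gm <- genome_map(12, D = 1)
  p <- random_panel(3, 12, n_labels = 5)
  i <- 1; j <- 3
  n <- 10000
  hq <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    off <- make_offspring(p, i, j, gm)
    hq[k, ] <- c(mean(off$G[1, ] != off$G[2, ]),
                 mean(off$A[1, ] + off$A[2, ]) / 2,
                 mean(off$F[1, ] == off$F[2, ]))
  }
  for (col in 1:3) {
    id <- c("H", "Q", "K")[col]
    M <- expected_pair_matrix(measure_spec(id), p)
    se <- sd(hq[, col]) / sqrt(n)
    expect_lt(abs(mean(hq[, col]) - M[i, j]), 3 * se + 1e-12)
  }
})

test_that("mean ancestry is a martingale under random mating", {
  set.seed(405)
  gm <- genome_map(50, D = 5)
  p <- random_panel(30, 50, p_anc = 0.6)
  q0 <- mean(p$A)
  finals <- vapply(1:20, function(r) {
    cur <- p
    for (g in 1:3) cur <- labreed:::wf_generation(cur, gm)
    mean(cur$A)
  }, numeric(1))
  expect_lt(abs(mean(finals) - q0), 3 * sd(finals) / sqrt(length(finals)))
})
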
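# Independent oracle for the pairwise expected measures: enumerate the four
# equiprobable gametic combinations a potential offspring of (i, j) could
# inherit at a locus, evaluate the *realized* single-individual statistic on
# each hypothetical child, and average. This routes through the offspring
# definition of each measure rather than the package's kernel expressions.

# realized value of one hypothetical child at one locus
child_locus_value <- function(id, g, a, f, delta = 0.5) {
  # g, a, f: length-2 child haplotype values
  switch(id,
    K   = as.numeric(f[1] == f[2]),
    H   = as.numeric(g[1] != g[2]),
    Q   = (a[1] + a[2]) / 2,
    PH  = as.numeric(a[1] + a[2] == 2) * as.numeric(g[1] != g[2]),
    PK  = 1 - as.numeric(a[1] + a[2] == 2) * as.numeric(f[1] != f[2]),
    WPH = (1 - delta) * (a[1] + a[2]) / 2 +
      delta * as.numeric(a[1] + a[2] == 2) * as.numeric(g[1] != g[2]),
    WPK = (1 - delta) * (1 - (a[1] + a[2]) / 2) +
      delta * (1 - as.numeric(a[1] + a[2] == 2) * as.numeric(f[1] != f[2])),
    stop("bad id")
  )
}

# expected measure for pair (i, j) at one locus, by offspring enumeration
oracle_locus <- function(id, Gi, Ai, Fi, Gj, Aj, Fj, l, delta = 0.5) {
  vals <- numeric(0)
  for (a in 1:2) {
    for (b in 1:2) {
      vals <- c(vals, child_locus_value(
        id,
        g = c(Gi[a, l], Gj[b, l]),
        a = c(Ai[a, l], Aj[b, l]),
        f = c(Fi[a, l], Fj[b, l]),
        delta = delta))
    }
  }
  mean(vals)
}

# full N x N oracle matrix by explicit loops over pairs and loci
oracle_matrix <- function(id, panel, delta = 0.5) {
  N <- n_individuals(panel)
  L <- n_loci(panel)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      acc <- 0
      for (l in seq_len(L)) {
        acc <- acc + oracle_locus(
          id,
          matrix(panel$G[i, , ], 2), matrix(panel$A[i, , ], 2),
          matrix(panel$F[i, , ], 2),
          matrix(panel$G[j, , ], 2), matrix(panel$A[j, , ], 2),
          matrix(panel$F[j, , ], 2), l, delta)
      }
      out[i, j] <- acc / L
    }
  }
  out
}

# random panel with arbitrary binary tracks and founder labels
random_panel <- function(N, L, n_labels = 2 * N, p_anc = 0.6, t = 0L) {
  G <- array(rbinom(N * 2 * L, 1, 0.5), c(N, 2, L))
  A <- array(rbinom(N * 2 * L, 1, p_anc), c(N, 2, L))
  F_ <- array(sample.int(n_labels, N * 2 * L, replace = TRUE), c(N, 2, L))
  hap_panel(G, A, F_, t = t)
}

# hand-built two-individual panel from per-haplotype vectors
panel_from_rows <- function(G_rows, A_rows, F_rows, t = 0L) {
  # each *_rows: list of individuals, each a 2 x L matrix
  N <- length(G_rows)
  L <- ncol(G_rows[[1]])
  G <- array(0L, c(N, 2, L)); A <- array(0L, c(N, 2, L))
  F_ <- array(1L, c(N, 2, L))
  for (i in seq_len(N)) {
    G[i, , ] <- G_rows[[i]]
    A[i, , ] <- A_rows[[i]]
    F_[i, , ] <- F_rows[[i]]
  }
  hap_panel(G, A, F_, t = t)
}

small_program_setup <- function(L = 120, N = 40, N_src = 60, T_init = 6) {
  gm <- genome_map(L, D = 5)
  cfg <- wild_history_config(L = L, N_A = N_src, N_I = N_src,
                             T_init = T_init, N = N)
  list(map = gm, history = cfg)
}
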
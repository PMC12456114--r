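#' Wild-history configuration
#'
#' Parameters of the pre-program history: two source populations (the
#' conservation *target* and the *introgressing* population) diverge from a
#' common ancestor under the Balding-Nichols drift model, the target
#' population receives a pulse of introgression, and the captive population
#' is formed by a sampling bottleneck followed by selection of the least
#' introgressed individuals.
#'
#' The introgression-rate schedule `alpha` has one entry per wild-history
#' generation: at generation `g`, each parent of each offspring is drawn
#' from the (static) introgressing population with probability `alpha[g]`
#' and from the current wild population otherwise. With the default
#' `T_init = 10` and pulses of 0.2 in the first two generations, the pulse
#' *ends* `T_init` generations before the breeding program starts (the two
#' captive-formation generations included) and *began* `T_init + 2`
#' generations before; `T_init + 2` is the introgression age used by the
#' delay sweeps.
#'
#' @param L Number of SNPs (default 500).
#' @param freq_low,freq_high Bounds of the uniform ancestral-frequency prior
#'   (defaults 0.05, 0.95).
#' @param F_A,F_I Balding-Nichols drift parameters of the target and
#'   introgressing populations (defaults 0.2 each; their sum is the
#'   by-construction divergence between the two populations, default 0.4).
#' @param N_A,N_I Diploid sizes of the target and introgressing source
#'   panels (defaults 500).
#' @param T_init Number of wild-history generations (default 10). Equal to
#'   the age of the end of the introgression pulse at program start.
#' @param alpha Introgression-rate schedule, length `T_init`; default pulses
#'   of 0.2 in generations 1 and 2, zero after.
#' @param p_bottleneck Fraction of wild individuals sampled as program
#'   founders (default 0.25).
#' @param p_captive Fraction of the bottleneck generation retained by
#'   minimum introgression (default 0.25).
#' @param N Captive capacity: diploids in the program (default 150).
#' @return A list of class `wild_history_config`.
#' @export
wild_history_config <- function(L = 500, freq_low = 0.05, freq_high = 0.95,
                                F_A = 0.2, F_I = 0.2, N_A = 500, N_I = 500,
                                T_init = 10,
                                alpha = if (T_init >= 2) c(0.2, 0.2, rep(0, T_init - 2)) else rep(0.2, T_init),
                                p_bottleneck = 0.25, p_captive = 0.25,
                                N = 150) {
  stopifnot(L >= 1, freq_low > 0, freq_high < 1, freq_low < freq_high,
            F_A >= 0, F_A < 1, F_I >= 0, F_I < 1,
            N_A >= 2, N_I >= 2, T_init >= 0,
            length(alpha) == T_init, all(alpha >= 0), all(alpha <= 1),
            p_bottleneck > 0, p_bottleneck <= 1,
            p_captive > 0, p_captive <= 1, N >= 2)
  structure(list(L = as.integer(L), freq_low = freq_low, freq_high = freq_high,
                 F_A = F_A, F_I = F_I, N_A = as.integer(N_A),
                 N_I = as.integer(N_I), T_init = as.integer(T_init),
                 alpha = alpha, p_bottleneck = p_bottleneck,
                 p_captive = p_captive, N = as.integer(N)),
            class = "wild_history_config")
}

#' Balding-Nichols per-locus population frequencies
#'
#' For each locus an ancestral frequency `f ~ U(freq_low, freq_high)` is
#' drawn, and each population's frequency follows the Balding-Nichols Beta
#' distribution `Beta(f (1-F)/F, (1-f)(1-F)/F)` with its drift parameter
#' `F`, so that `E[f_pop] = f` and `Var[f_pop] = F f (1-f)`. A drift
#' parameter of zero gives the degenerate point mass at `f`.
#'
#' @param config A [wild_history_config()].
#' @param n Number of loci to draw (default `config$L`).
#' @param f Optional fixed ancestral frequencies (length 1 or `n`); drawn
#'   from the uniform prior when `NULL`.
#' @return Tibble with columns `f` (ancestral), `f_A`, `f_I`.
#' @export
sample_population_frequencies <- function(config, n = config$L, f = NULL) {
  stopifnot(inherits(config, "wild_history_config"))
  if (is.null(f)) {
    f <- stats::runif(n, config$freq_low, config$freq_high)
  } else {
    f <- rep_len(as.numeric(f), n)
  }
  tibble::tibble(
    f = f,
    f_A = rbn(f, config$F_A),
    f_I = rbn(f, config$F_I)
  )
}

# One Balding-Nichols draw per element of f with drift parameter F.
rbn <- function(f, F_drift) {
  if (F_drift == 0) return(f)
  k <- (1 - F_drift) / F_drift
  stats::rbeta(length(f), f * k, (1 - f) * k)
}

# Panel of N diploids with haplotype alleles drawn Bernoulli(freqs[l])
# independently, constant ancestry value `ancestry`.
bernoulli_panel <- function(N, freqs, ancestry) {
  L <- length(freqs)
  G <- array(stats::rbinom(N * 2L * L, 1L,
                           rep(freqs, each = N * 2L)), c(N, 2L, L))
  A <- array(as.integer(ancestry), c(N, 2L, L))
  hap_panel(G, A, t = 0L)
}

#' Simulate the pre-program wild history
#'
#' Builds the target and introgressing source panels by independent
#' Bernoulli draws from their Balding-Nichols frequencies, then runs
#' `T_init` Wright-Fisher generations in which each parent of each offspring
#' is drawn from the introgressing panel with probability `alpha[g]`.
#' Ancestry is 1 throughout the target panel and 0 throughout the
#' introgressing panel, so the `A` track of the result records true local
#' ancestry of every inherited segment.
#'
#' @param config A [wild_history_config()].
#' @param genome_map A [genome_map()] with `L` matching the config.
#' @param freqs Optional tibble from [sample_population_frequencies()]
#'   (drawn if `NULL`).
#' @return A [hap_panel()] of `N_A` wild (post-introgression) individuals,
#'   with `t` equal to `T_init`.
#' @export
simulate_wild_history <- function(config, genome_map, freqs = NULL) {
  stopifnot(inherits(config, "wild_history_config"), is_genome_map(genome_map),
            genome_map$L == config$L)
  if (is.null(freqs)) freqs <- sample_population_frequencies(config)
  wild <- bernoulli_panel(config$N_A, freqs$f_A, 1L)
  intro <- bernoulli_panel(config$N_I, freqs$f_I, 0L)
  # give introgressing haplotypes their own founder-label space so labels
  # stay unique if inspected before re-initialisation at the bottleneck
  intro$F <- intro$F + 2L * config$N_A
  for (g in seq_len(config$T_init)) {
    wild <- wf_mixture_generation(wild, intro, config$alpha[g], genome_map)
  }
  wild
}

# One Wright-Fisher generation where each parent is drawn from `intro` with
# probability alpha, else from `wild`; the two parents of an offspring are
# distinct within their panels.
wf_mixture_generation <- function(wild, intro, alpha, genome_map) {
  N <- n_individuals(wild)
  L <- n_loci(wild)
  G <- array(0L, c(N, 2L, L)); A <- array(0L, c(N, 2L, L))
  F_ <- array(0L, c(N, 2L, L))
  Ni <- n_individuals(intro)
  for (k in seq_len(N)) {
    from_intro <- stats::runif(2) < alpha
    if (all(from_intro)) {
      pr <- sample.int(Ni, 2L)
      off <- make_offspring(intro, pr[1L], pr[2L], genome_map)
    } else if (!any(from_intro)) {
      pr <- sample.int(N, 2L)
      off <- make_offspring(wild, pr[1L], pr[2L], genome_map)
    } else {
      gi <- simulate_gamete(genome_map)
      gj <- simulate_gamete(genome_map)
      pw <- sample.int(N, 1L)
      pi <- sample.int(Ni, 1L)
      idx_w <- cbind(pw, gi, seq_len(L))
      idx_i <- cbind(pi, gj, seq_len(L))
      first_wild <- !from_intro[1L]
      hw <- list(G = wild$G[idx_w], A = wild$A[idx_w], F = wild$F[idx_w])
      hi <- list(G = intro$G[idx_i], A = intro$A[idx_i], F = intro$F[idx_i])
      o1 <- if (first_wild) hw else hi
      o2 <- if (first_wild) hi else hw
      off <- list(G = rbind(o1$G, o2$G), A = rbind(o1$A, o2$A),
                  F = rbind(o1$F, o2$F))
    }
    G[k, , ] <- off$G; A[k, , ] <- off$A; F_[k, , ] <- off$F
  }
  hap_panel(G, A, F_, t = wild$t + 1L)
}

#' Form the captive founder population
#'
#' Two generations create the breeding program from the wild panel:
#'
#' 1. *Bottleneck* — a fraction `p_bottleneck` of wild individuals is
#'    sampled uniformly. These are the program founders: their founder
#'    labels are re-initialised to unique values `1..2 N_F`. One round of
#'    uniform random breeding follows (keeping the bottleneck size).
#' 2. *Selection* — the fraction `p_captive` of that generation with the
#'    least introgression (highest mean target ancestry; ties by index) is
#'    retained and bred by Wright-Fisher mating up to the capacity `N`.
#'
#' @param wild_panel A [hap_panel()] from [simulate_wild_history()].
#' @param config A [wild_history_config()].
#' @param genome_map A [genome_map()].
#' @return A [hap_panel()] of `N` captive individuals with `t = 0` (program
#'   start) and attributes `n_founders` (bottleneck count) and
#'   `introgression_age` (`T_init + 2`, generations since the pulse began).
#' @export
form_captive_population <- function(wild_panel, config, genome_map) {
  stopifnot(is_hap_panel(wild_panel), inherits(config, "wild_history_config"))
  Nw <- n_individuals(wild_panel)
  n_f <- max(2L, floor(config$p_bottleneck * Nw))
  founders <- panel_subset(wild_panel, sample.int(Nw, n_f), t = 0L)
  founders$F <- init_founder_labels(n_f, n_loci(founders))
  bred <- wf_generation(founders, genome_map, n_out = n_f)
  # selection: keep the least introgressed fraction
  q <- realized_individual_scores(bred)$S_Q
  n_keep <- max(2L, floor(config$p_captive * n_f))
  keep <- order(-q, seq_along(q))[seq_len(n_keep)]
  if (length(keep) < 2L) stop("selection set is empty", call. = FALSE)
  selected <- panel_subset(bred, keep)
  captive <- wf_generation(selected, genome_map, n_out = config$N)
  captive$t <- 0L
  attr(captive, "n_founders") <- n_f
  attr(captive, "introgression_age") <- config$T_init + 2L
  captive
}

#' Simulate a complete captive founder population
#'
#' Convenience wrapper: draws frequencies, runs the wild history and forms
#' the captive population in one call.
#'
#' @inheritParams simulate_wild_history
#' @return A captive [hap_panel()] at `t = 0`; see
#'   [form_captive_population()].
#' @export
simulate_captive_founders <- function(config, genome_map, freqs = NULL) {
  wild <- simulate_wild_history(config, genome_map, freqs)
  form_captive_population(wild, config, genome_map)
}

#' Calibrate the introgression pulse to a target initial level
#'
#' The two-generation pulse rate `alpha` maps to a raw (pre-selection)
#' expected introgression of `1 - (1 - alpha)^2`, but the captive-formation
#' selection step removes part of it. This helper searches for the pulse
#' rate whose *post-selection* captive mean introgression matches `target`
#' within `tol`, by a short multiplicative fixed-point iteration on the raw
#' level (each evaluation simulates `reps` captive populations).
#'
#' @param target Desired mean introgressed fraction of the captive founders.
#' @param config A [wild_history_config()] providing all other parameters.
#' @param genome_map A [genome_map()].
#' @param reps Replicate simulations per evaluation (default 3).
#' @param tol Acceptable absolute error (default 0.02).
#' @param max_iter Iteration cap (default 6).
#' @return The calibrated config (with updated `alpha`), with the achieved
#'   level in attribute `achieved`.
#' @export
calibrate_initial_introgression <- function(target, config, genome_map,
                                            reps = 3, tol = 0.02,
                                            max_iter = 6) {
  stopifnot(target > 0, target < 1)
  q_raw <- min(0.95, target)
  achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    a <- 1 - sqrt(1 - q_raw)
    config$alpha <- c(a, a, rep(0, config$T_init - 2L))
    m <- mean(vapply(seq_len(reps), function(r) {
      cap <- simulate_captive_founders(config, genome_map)
      1 - mean(cap$A)
    }, numeric(1)))
    achieved <- m
    if (abs(m - target) <= tol) break
    q_raw <- min(0.98, max(1e-4, q_raw * target / max(m, 1e-6)))
  }
  attr(config, "achieved") <- achieved
  config
}
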
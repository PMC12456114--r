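#' Breeding-program configuration
#'
#' @param measure A [measure_spec()] or one of its id strings, or `"RANDOM"`
#'   for unselected Wright-Fisher mating (default `"PK"`).
#' @param rule `"ranked"` (iterative ranked-mean pairing) or `"threshold"`
#'   (keep the better fraction, then random mating).
#' @param capacity Captive population size `N`, fixed every generation
#'   (default 150).
#' @param offspring_mean Mean of the Poisson brood-size distribution per
#'   pair (default 4.2, the expected lifetime offspring from the demographic
#'   schedule; see [expected_offspring()]).
#' @param compliance Probability `c` that a recommended pairing is followed;
#'   with probability `1 - c` the recommended partner is replaced by a
#'   random unpaired lower-ranked individual (default 1).
#' @param threshold_quantile Quantile of individuals discarded by the
#'   threshold rule (default 0.5: the better half is retained).
#' @param n_generations Program length in generations (default 20).
#' @param delta Weight for the weighted measures (default 0.5).
#' @return A list of class `breeding_config`.
#' @export
breeding_config <- function(measure = "PK", rule = c("ranked", "threshold"),
                            capacity = 150, offspring_mean = 4.2,
                            compliance = 1.0, threshold_quantile = 0.5,
                            n_generations = 20, delta = 0.5) {
  rule <- match.arg(rule)
  if (is.character(measure)) {
    measure <- if (toupper(measure) == "RANDOM") "RANDOM"
               else measure_spec(measure, delta = delta)
  }
  stopifnot(inherits(measure, "measure_spec") || identical(measure, "RANDOM"),
            capacity >= 2, offspring_mean > 0,
            compliance > 0, compliance <= 1,
            threshold_quantile >= 0, threshold_quantile < 1,
            n_generations >= 0)
  structure(list(measure = measure, rule = rule,
                 capacity = as.integer(capacity),
                 offspring_mean = offspring_mean, compliance = compliance,
                 threshold_quantile = threshold_quantile,
                 n_generations = as.integer(n_generations), delta = delta),
            class = "breeding_config")
}

# sample() without the scalar-x surprise
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

#' Rank individuals by iterated mean pairwise score
#'
#' The ranked-mean selection procedure: at each of `N` iterations the
#' breeding score of every remaining individual is the mean of its pairwise
#' expected measure over the *other* remaining individuals, and the worst
#' individual (lowest score for a maximized measure, highest for a minimized
#' one) is pushed onto the stack and removed from the pool. The stack
#' therefore lists individuals from least to most promising, and each
#' individual's score reflects the pool it would actually breed within.
#' Ties are broken by ascending individual index.
#'
#' @param matrix A [expected_pair_matrix()] result (or any square symmetric
#'   matrix with a `measure` attribute).
#' @param direction `"maximize"` or `"minimize"`; defaults to the attached
#'   measure's direction.
#' @return Integer vector: the stack, worst first, best last.
#' @export
rank_individuals <- function(matrix, direction = NULL) {
  if (is.null(direction)) {
    m <- attr(matrix, "measure")
    if (is.null(m)) stop("`direction` required when matrix has no measure",
                         call. = FALSE)
    direction <- m$direction
  }
  M <- unclass(matrix)
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("`matrix` must be square", call. = FALSE)
  }
  N <- nrow(M)
  stopifnot(N >= 2)
  remaining <- rep(TRUE, N)
  rs <- rowSums(M)              # running sums over remaining columns
  stack <- integer(N)
  for (t in seq_len(N)) {
    idx <- which(remaining)
    if (length(idx) == 1L) {
      stack[t] <- idx
      break
    }
    B <- (rs[idx] - diag(M)[idx]) / (length(idx) - 1)  # exclude self term
    worst <- if (direction == "maximize") idx[which.min(B)] else idx[which.max(B)]
    stack[t] <- worst
    remaining[worst] <- FALSE
    rs <- rs - M[, worst]
  }
  stack
}

#' Pair ranked individuals and breed the next generation
#'
#' Consumes the ranking stack from the best end downwards, two individuals
#' per pair. Each pair draws a Poisson(`offspring_mean`) brood via
#' [make_offspring()] until the capacity `N` is reached (the last brood is
#' truncated to hit `N` exactly). Under partial compliance, each
#' recommendation is followed with probability `c`; otherwise the
#' recommended partner is skipped (it stays available) and an unpaired
#' lower-ranked individual is drawn uniformly instead. If every individual
#' has been paired and capacity is still short, pairing restarts from the
#' best pair with fresh Poisson and compliance draws. With an odd number of
#' individuals the single worst remains unpaired in a cycle.
#'
#' @param stack Integer stack from [rank_individuals()] (worst first).
#' @param panel The current-generation [hap_panel()].
#' @param config A [breeding_config()].
#' @param genome_map A [genome_map()].
#' @return The next-generation [hap_panel()] of exactly `capacity`
#'   individuals, with attribute `parents`: a two-column matrix of the
#'   parent indices of each offspring.
#' @export
pair_and_breed <- function(stack, panel, config, genome_map) {
  stopifnot(is_hap_panel(panel), inherits(config, "breeding_config"))
  N_next <- config$capacity
  if (N_next < 2) stop("capacity must be at least 2", call. = FALSE)
  ranked <- rev(stack)          # best first
  L <- n_loci(panel)
  G <- array(0L, c(N_next, 2L, L)); A <- array(0L, c(N_next, 2L, L))
  F_ <- array(0L, c(N_next, 2L, L))
  parents <- matrix(0L, N_next, 2L)
  k <- 0L
  while (k < N_next) {
    unpaired <- ranked
    while (length(unpaired) >= 2L && k < N_next) {
      p1 <- unpaired[1L]
      p2 <- unpaired[2L]
      if (config$compliance < 1 && stats::runif(1) > config$compliance) {
        # skip the recommended partner; draw a random lower-ranked substitute
        cands <- setdiff(unpaired[-1L], p2)
        if (length(cands) > 0L) p2 <- resample(cands)
      }
      unpaired <- setdiff(unpaired, c(p1, p2))
      n_off <- stats::rpois(1L, config$offspring_mean)
      n_off <- min(n_off, N_next - k)
      for (o in seq_len(n_off)) {
        off <- make_offspring(panel, p1, p2, genome_map)
        k <- k + 1L
        G[k, , ] <- off$G; A[k, , ] <- off$A; F_[k, , ] <- off$F
        parents[k, ] <- c(p1, p2)
      }
    }
  }
  out <- hap_panel(G, A, F_, t = panel$t + 1L)
  attr(out, "parents") <- parents
  out
}

#' Threshold breeding rule
#'
#' The simpler alternative to ranked pairing: individuals are ranked by
#' their realized individual score for the selected measure, the fraction
#' above the `threshold_quantile` is retained (better half by default; ties
#' by ascending index), and the retained set is bred by Wright-Fisher
#' random mating (distinct uniform parents per offspring) up to capacity.
#'
#' @param scores Numeric vector of per-individual scores (see
#'   [realized_individual_scores()]).
#' @param direction `"maximize"` or `"minimize"` for the score.
#' @param panel The current-generation [hap_panel()].
#' @param config A [breeding_config()].
#' @param genome_map A [genome_map()].
#' @return The next-generation [hap_panel()] of `capacity` individuals.
#' @export
threshold_breed <- function(scores, direction, panel, config, genome_map) {
  N <- n_individuals(panel)
  stopifnot(length(scores) == N)
  n_keep <- N - floor(config$threshold_quantile * N)
  ord <- if (direction == "maximize") order(-scores, seq_len(N))
         else order(scores, seq_len(N))
  keep <- ord[seq_len(n_keep)]
  if (length(keep) < 2L) stop("fewer than 2 individuals selected", call. = FALSE)
  sel <- panel_subset(panel, keep)
  wf_generation(sel, genome_map, n_out = config$capacity)
}

# Advance one program generation under the configured rule/measure.
breed_next_generation <- function(panel, config, genome_map) {
  if (identical(config$measure, "RANDOM")) {
    return(wf_generation(panel, genome_map, n_out = config$capacity))
  }
  if (config$rule == "ranked") {
    M <- expected_pair_matrix(config$measure, panel)
    stack <- rank_individuals(M)
    pair_and_breed(stack, panel, config, genome_map)
  } else {
    ind <- realized_individual_scores(panel, delta = config$delta)
    col <- paste0("S_", config$measure$id)
    threshold_breed(ind[[col]], config$measure$direction, panel, config,
                    genome_map)
  }
}

#' Run a captive breeding program
#'
#' Loops over generations: compute the pairwise measure matrix, rank (or
#' threshold), breed to capacity, and score the new generation. The
#' trajectory starts with the founder generation's scores (generation 0).
#'
#' @param panel The captive founder [hap_panel()] (generation 0).
#' @param config A [breeding_config()].
#' @param genome_map A [genome_map()].
#' @param replicate Optional replicate id recorded in every row.
#' @return A tibble of class `breeding_trajectory`: one row per generation
#'   with columns `replicate` (if given), `generation`, `S_Q`, `S_H`, `S_K`,
#'   `S_PH`, `S_PK`.
#' @examples
#' \donttest{
#' gm <- genome_map(100, D = 5)
#' cfg <- wild_history_config(L = 100, N_A = 60, N_I = 60, N = 40)
#' cap <- simulate_captive_founders(cfg, gm)
#' tr <- run_program(cap, breeding_config("PK", capacity = 40,
#'                                        n_generations = 3), gm)
#' tr
#' }
#' @export
run_program <- function(panel, config, genome_map, replicate = NULL) {
  stopifnot(is_hap_panel(panel), inherits(config, "breeding_config"))
  rows <- vector("list", config$n_generations + 1L)
  rows[[1L]] <- realized_scores(panel, replicate = replicate)
  cur <- panel
  for (g in seq_len(config$n_generations)) {
    cur <- breed_next_generation(cur, config, genome_map)
    rows[[g + 1L]] <- realized_scores(cur, replicate = replicate)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("breeding_trajectory", class(out))
  attr(out, "final_panel") <- cur
  out
}
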
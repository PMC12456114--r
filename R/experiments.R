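#' Full run configuration
#'
#' Bundles the genetic map, wild history, breeding program and seed into one
#' object, with every default equal to the standard study conditions:
#' `N = 150` captive diploids, `D = 5` Morgans, `L = 500` SNPs,
#' `delta = 0.5`, Poisson offspring mean 4.2, full compliance, `T_init = 10`
#' with two 0.2 introgression pulses, bottleneck and captive-selection
#' fractions 0.25, drift parameters 0.2, and a 20-generation horizon.
#'
#' @param L,D Map parameters (defaults 500 SNPs, 5 Morgans).
#' @param history A [wild_history_config()]; built from `L` and `N` when
#'   `NULL`.
#' @param breeding A [breeding_config()]; defaults when `NULL`.
#' @param N Captive capacity used for both blocks (default 150).
#' @param seed Optional integer seed recorded and applied by [run_replicates()].
#' @param ... Passed to [breeding_config()] when `breeding` is `NULL`.
#' @return A list of class `program_config` with elements `map`, `history`,
#'   `breeding`, `seed`.
#' @export
program_config <- function(L = 500, D = 5, history = NULL, breeding = NULL,
                           N = 150, seed = NULL, ...) {
  map <- genome_map(L, D)
  if (is.null(history)) history <- wild_history_config(L = L, N = N)
  if (is.null(breeding)) breeding <- breeding_config(capacity = N, ...)
  stopifnot(history$L == map$L)
  structure(list(map = map, history = history, breeding = breeding,
                 seed = seed), class = "program_config")
}

#' Run replicate breeding programs from scratch
#'
#' For each replicate: simulate a fresh captive founder population from the
#' wild history, then run the breeding program on it. Per-replicate seeds
#' are derived deterministically from `config$seed` (when set) so any
#' replicate can be reproduced in isolation.
#'
#' @param config A [program_config()].
#' @param replicates Number of replicates (default 10).
#' @return A `breeding_trajectory` tibble with a `replicate` column.
#' @export
run_replicates <- function(config, replicates = 10) {
  stopifnot(inherits(config, "program_config"))
  out <- lapply(seq_len(replicates), function(r) {
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, r))
    cap <- simulate_captive_founders(config$history, config$map)
    run_program(cap, config$breeding, config$map, replicate = r)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("breeding_trajectory", class(out))
  out
}

# Derive a 31-bit stream seed from a base seed and an index.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(k) %% 2147480000L
}

#' Compare breeding strategies on shared founder populations
#'
#' Runs every strategy x compliance combination on the *same* captive
#' founder panel within each replicate (a paired design: generation-0 scores
#' are identical across strategies, and differences between strategy curves
#' are not inflated by founder-panel noise).
#'
#' @param config A [program_config()] providing map, history and the base
#'   breeding settings (capacity, offspring mean, horizon, delta).
#' @param strategies Character vector of measure ids and/or `"RANDOM"`.
#' @param compliance Numeric vector of compliance rates (default 1).
#' @param replicates Number of shared-founder replicates (default 1).
#' @param founder_panels Optional list of pre-built captive founder panels
#'   (one per replicate), e.g. from [make_wildcat_like_fixture()]; the wild
#'   history is skipped when given.
#' @return Tibble with columns `strategy`, `compliance`, `replicate`,
#'   `generation` and the five scores.
#' @export
run_strategy_comparison <- function(config,
                                    strategies = c("RANDOM", "K", "H", "Q",
                                                   "PH", "PK", "WPH", "WPK"),
                                    compliance = 1.0, replicates = 1,
                                    founder_panels = NULL) {
  stopifnot(inherits(config, "program_config"))
  res <- list()
  for (r in seq_len(replicates)) {
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, r))
    cap <- if (is.null(founder_panels)) {
      simulate_captive_founders(config$history, config$map)
    } else {
      founder_panels[[r]]
    }
    for (s in strategies) {
      for (cc in compliance) {
        bc <- config$breeding
        bc$measure <- if (toupper(s) == "RANDOM") "RANDOM"
                      else measure_spec(s, delta = bc$delta)
        bc$compliance <- cc
        if (!is.null(config$seed)) {
          set.seed(derive_seed(config$seed,
                               1000L * r + 17L * match(s, strategies) +
                                 round(100 * cc)))
        }
        tr <- run_program(cap, bc, config$map, replicate = r)
        tr$strategy <- s
        tr$compliance <- cc
        res[[length(res) + 1L]] <- tr
      }
    }
  }
  out <- dplyr::relocate(dplyr::bind_rows(res), "strategy", "compliance")
  class(out) <- c("breeding_trajectory", class(out))
  out
}

#' Sensitivity sweep over one simulation parameter
#'
#' Varies one parameter over a grid, holding everything else at the
#' configured values, and summarises the end-of-horizon scores over
#' replicates (mean and 25%/75% quantiles), for each selection measure.
#'
#' Supported parameters:
#' * `initial_introgression` — target mean introgressed fraction of the
#'   captive founders; the pulse rate is calibrated per grid value with
#'   [calibrate_initial_introgression()].
#' * `genome_length_D` — chromosome length in Morgans (SNP count unchanged).
#' * `offspring_mean` — Poisson brood mean.
#' * `delay_generations` — age of the introgression pulse at program start,
#'   counted from the start of the two-generation pulse (`T_init + 2`);
#'   values must be at least 4.
#' * `capacity_N` — captive population size.
#'
#' @param parameter One of the names above.
#' @param grid Numeric vector of parameter values.
#' @param config Base [program_config()].
#' @param measures Character vector of measures to select on
#'   (default `c("WPH", "PK")`).
#' @param replicates Replicates per grid value (default 10).
#' @param horizon Program length in generations (default
#'   `config$breeding$n_generations`).
#' @return A list with `summary` (tibble: `parameter`, `value`, `measure`
#'   and mean/q25/q75 of each final score) and `final` (per-replicate final
#'   scores).
#' @export
run_sweep <- function(parameter, grid, config, measures = c("WPH", "PK"),
                      replicates = 10, horizon = NULL) {
  parameter <- match.arg(parameter,
                         c("initial_introgression", "genome_length_D",
                           "offspring_mean", "delay_generations",
                           "capacity_N"))
  stopifnot(length(grid) >= 1, replicates >= 1)
  if (!is.null(horizon)) config$breeding$n_generations <- as.integer(horizon)
  finals <- list()
  for (v in grid) {
    cfg <- sweep_apply(parameter, v, config)
    for (m in measures) {
      cfg$breeding$measure <- measure_spec(m, delta = cfg$breeding$delta)
      tr <- run_replicates(cfg, replicates = replicates)
      fin <- dplyr::filter(tr, .data$generation == max(.data$generation))
      fin$parameter <- parameter
      fin$value <- v
      fin$measure <- m
      finals[[length(finals) + 1L]] <- fin
    }
  }
  final <- dplyr::bind_rows(finals)
  summary <- final |>
    dplyr::group_by(.data$parameter, .data$value, .data$measure) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("S_Q", "S_H", "S_K", "S_PH", "S_PK")),
      list(mean = mean,
           q25 = ~ stats::quantile(.x, 0.25),
           q75 = ~ stats::quantile(.x, 0.75)),
      .names = "{.col}_{.fn}"), .groups = "drop")
  list(summary = summary, final = final)
}

# Return a program_config with one swept parameter applied.
sweep_apply <- function(parameter, value, config) {
  switch(
    parameter,
    initial_introgression = {
      config$history <- calibrate_initial_introgression(
        value, config$history, config$map)
      config
    },
    genome_length_D = {
      config$map <- genome_map(config$map$L, value)
      config
    },
    offspring_mean = {
      config$breeding$offspring_mean <- value
      config
    },
    delay_generations = {
      if (value < 4) stop("delay_generations must be at least 4", call. = FALSE)
      h <- config$history
      config$history <- wild_history_config(
        L = h$L, freq_low = h$freq_low, freq_high = h$freq_high,
        F_A = h$F_A, F_I = h$F_I, N_A = h$N_A, N_I = h$N_I,
        T_init = as.integer(value) - 2L,
        p_bottleneck = h$p_bottleneck, p_captive = h$p_captive, N = h$N)
      config
    },
    capacity_N = {
      config$breeding$capacity <- as.integer(value)
      config$history$N <- as.integer(value)
      config
    }
  )
}

#' Synthetic wildcat-like founder fixture
#'
#' Emulates the statistics of a small, heavily admixed felid panel observed
#' on one chromosome: 36 diploids on a 1.26-Morgan map, with per-haplotype
#' target-ancestry fractions of mean about 0.6 spanning roughly 0.14-1.
#' The panel is generated by simulating the wild history (Balding-Nichols
#' sources, a two-generation introgression pulse sized for 40% mean
#' introgression, short drift) and sampling 36 individuals; it is synthetic
#' throughout — no real genotypes are consumed. The captive program is then
#' founded as for the real program: individuals are ranked by genome-wide
#' target-ancestry fraction, the top `n_founders` kept (re-labelled as
#' founders), and one Wright-Fisher breeding step expands them to capacity.
#'
#' @param L SNP count (default 2000; the full-scale panel would use 17720).
#' @param n_panel Diploids in the observed panel (default 36).
#' @param n_founders Founders kept by ranked ancestry (default 24).
#' @param N Captive capacity (default 150).
#' @param D Map length in Morgans (default 1.26).
#' @return A list with `panel` (captive [hap_panel()] at `t = 0`), `map`,
#'   and `observed` (the 36-diploid pre-selection panel).
#' @export
make_wildcat_like_fixture <- function(L = 2000, n_panel = 36, n_founders = 24,
                                      N = 150, D = 1.26) {
  map <- genome_map(L, D)
  # pulse rate for 40% expected introgression: 1 - (1 - a)^2 = 0.4
  a <- 1 - sqrt(0.6)
  cfg <- wild_history_config(L = L, N_A = 100, N_I = 100, T_init = 6,
                             alpha = c(a, a, rep(0, 4)), N = N)
  wild <- simulate_wild_history(cfg, map)
  obs <- panel_subset(wild, sample.int(n_individuals(wild), n_panel), t = 0L)
  # founder construction: rank by genome-wide target fraction, keep the top
  q <- realized_individual_scores(obs)$S_Q
  keep <- order(-q, seq_along(q))[seq_len(n_founders)]
  founders <- panel_subset(obs, keep, t = 0L)
  founders$F <- init_founder_labels(n_founders, L)
  captive <- wf_generation(founders, map, n_out = N)
  captive$t <- 0L
  attr(captive, "n_founders") <- n_founders
  list(panel = captive, map = map, observed = obs)
}
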
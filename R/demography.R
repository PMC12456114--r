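#' Demographic schedule for expected lifetime offspring
#'
#' Converts stud-book style demographic observations into the expected
#' number of offspring per breeding pair per (simulated) generation — the
#' Poisson mean used by the breeding simulator. The default values describe
#' a small felid program: broods of 1-5 kittens with probabilities
#' (0.23, 0.36, 0.30, 0.10, 0.01), 30% survival to first year, 10% annual
#' mortality thereafter, 50% of adult females breeding per year, and
#' breeding attempted at ages 1 through 7. The per-age breeding probability
#' is the literal product `0.5 * (1 - 0.3) * (1 - 0.1)^(a-1)` at the
#' defaults.
#'
#' @param brood_probs Probability vector over brood sizes `1..length(...)`;
#'   must sum to 1.
#' @param first_year_survival First-year survival rate; enters the schedule
#'   as the single factor `(1 - first_year_survival)` at every age (see
#'   Details).
#' @param annual_mortality Annual mortality rate after the first year.
#' @param female_breeding_prob Probability an adult female breeds in a year.
#' @param max_age Last breeding age (default 7).
#'
#' @details The age-`a` breeding probability is
#' `female_breeding_prob * (1 - first_year_survival) *
#' (1 - annual_mortality)^(a - 1)`, with the first-year factor applied
#' identically at every age, exactly as the stud-book calculation is
#' written; it is not re-derived as a life table.
#'
#' @return A list of class `demography_config`.
#' @export
demography_config <- function(brood_probs = c(0.23, 0.36, 0.30, 0.10, 0.01),
                              first_year_survival = 0.3,
                              annual_mortality = 0.1,
                              female_breeding_prob = 0.5,
                              max_age = 7) {
  stopifnot(all(brood_probs >= 0), all(brood_probs <= 1),
            abs(sum(brood_probs) - 1) < 1e-9,
            first_year_survival >= 0, first_year_survival <= 1,
            annual_mortality >= 0, annual_mortality <= 1,
            female_breeding_prob >= 0, female_breeding_prob <= 1,
            max_age >= 1)
  structure(list(brood_probs = brood_probs,
                 first_year_survival = first_year_survival,
                 annual_mortality = annual_mortality,
                 female_breeding_prob = female_breeding_prob,
                 max_age = as.integer(max_age)),
            class = "demography_config")
}

#' Mean brood size
#' @param config A [demography_config()].
#' @return `sum(k * brood_probs[k])`; 2.3 at the defaults.
#' @export
mean_brood <- function(config = demography_config()) {
  sum(seq_along(config$brood_probs) * config$brood_probs)
}

#' Expected number of breeding attempts over a lifetime
#'
#' Sums the per-age breeding probabilities
#' `female_breeding_prob * (1 - 0.3-style first-year factor) *
#' (1 - annual_mortality)^(a-1)` over ages `1..max_age`; 1.83 at the
#' defaults.
#' @param config A [demography_config()].
#' @return A number.
#' @export
expected_breeding_attempts <- function(config = demography_config()) {
  a <- seq_len(config$max_age)
  sum(config$female_breeding_prob * (1 - config$first_year_survival) *
        (1 - config$annual_mortality)^(a - 1))
}

#' Expected lifetime offspring per pair
#'
#' The product of [mean_brood()] and [expected_breeding_attempts()]; 4.2 at
#' the defaults. This feeds `offspring_mean` in [breeding_config()].
#' @param config A [demography_config()].
#' @return A number.
#' @export
expected_offspring <- function(config = demography_config()) {
  mean_brood(config) * expected_breeding_attempts(config)
}
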
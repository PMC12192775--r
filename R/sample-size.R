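#' Watson finite-population sample size
#'
#' Closed-form sample size for estimating a proportion in a finite
#' population:
#' \deqn{n = \frac{P(1-P)}{A^2/Z^2 + P(1-P)/N} \cdot \frac{1}{R}}
#' where `N` is the population size (fruit available per sampling
#' occasion), `P` the assumed population variance as a proportion, `A` the
#' desired precision, `Z` the standard-normal quantile for the confidence
#' level, and `R` the response rate. `N = Inf` drops the finite-population
#' term, giving the classical infinite-population size. The result is
#' rounded to the nearest integer with ties up.
#'
#' @param N Population size (fruit per sampling occasion); may be `Inf`.
#' @param P Assumed population variance as a proportion (default 0.5, the
#'   conservative maximum).
#' @param A Desired precision as a decimal (e.g. 0.05 for 5\%).
#' @param Z Standard-normal quantile: 1.96 for 95\% confidence, 1.6449 for
#'   90\%, 2.5758 for 99\%.
#' @param R Estimated response rate in (0, 1]; 1 when every sampled fruit is
#'   cut and inspected.
#' @return Required sample size (integer). The unrounded value is attached
#'   as attribute `"exact"`.
#' @examples
#' watson_n(population_size(1.5, 505, 0.84))        # 1.5 ha orchard: 240
#' watson_n(8484)                                   # 20 ha orchard: 368
#' watson_n(8484, A = 0.10)                         # 10% precision: 95
#' watson_n(Inf)                                    # no finite correction: 384
#' @export
watson_n <- function(N, P = 0.5, A = 0.05, Z = 1.96, R = 1) {
  stopifnot(length(N) == 1L, length(P) == 1L, length(A) == 1L,
            length(Z) == 1L, length(R) == 1L)
  if (!(N > 0)) stop("N must be positive (or Inf)", call. = FALSE)
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  if (A <= 0) stop("precision A must be positive", call. = FALSE)
  if (Z <= 0) stop("Z must be positive", call. = FALSE)
  if (R <= 0 || R > 1) stop("response rate R must lie in (0, 1]", call. = FALSE)
  pq <- P * (1 - P)
  fpc <- if (is.finite(N)) pq / N else 0
  exact <- (pq / (A^2 / Z^2 + fpc)) / R
  structure(as.integer(round_half_up(exact)), exact = exact)
}

#' Weekly fruit population of an orchard
#'
#' The sampling-occasion population `N` for [watson_n()]: fruit dropping
#' per week over the whole orchard, i.e. area (ha) x planting density
#' (trees/ha) x weekly drop (fruit/tree/week).
#'
#' @param area_ha Orchard area in hectares.
#' @param trees_per_ha Planting density; 505 trees/ha corresponds to the
#'   common 6.0 m x 3.3 m spacing.
#' @param drop_per_tree_week Weekly fruit drop per tree (default 0.84).
#' @return Fruit available per weekly sampling occasion.
#' @examples
#' population_size(20, 505, 0.84)   # 8484 fruit per week on 20 ha
#' @export
population_size <- function(area_ha, trees_per_ha = 505, drop_per_tree_week = 0.84) {
  stopifnot(area_ha > 0, trees_per_ha > 0, drop_per_tree_week >= 0)
  area_ha * trees_per_ha * drop_per_tree_week
}

#' Worst-case harvest infestation percentage
#'
#' If the drop threshold is met every week right up to harvest, about three
#' weeks' worth of infested fruit (at `residual_infested_per_tree` per
#' tree) are still hanging at picking. This converts that residue into a
#' percentage of the harvested crop:
#' `100 * trees_per_ha * residual / (yield_t_ha * 1000 / carton_kg * fruit_per_carton)`.
#'
#' @param yield_t_ha Crop yield in tonnes per hectare.
#' @param carton_kg Carton mass in kg.
#' @param fruit_per_carton Average fruit per carton.
#' @param trees_per_ha Planting density.
#' @param residual_infested_per_tree Infested fruit still on the tree at
#'   harvest.
#' @return Percentage of harvested fruit infested.
#' @examples
#' harvest_infestation_pct(45, 15, 72, 555, 0.3)   # about 0.08%
#' @export
harvest_infestation_pct <- function(yield_t_ha = 45, carton_kg = 15,
                                    fruit_per_carton = 72, trees_per_ha = 555,
                                    residual_infested_per_tree = 0.3) {
  stopifnot(yield_t_ha > 0, carton_kg > 0, fruit_per_carton > 0, trees_per_ha > 0,
            residual_infested_per_tree >= 0)
  fruit_per_ha <- yield_t_ha * 1000 / carton_kg * fruit_per_carton
  100 * trees_per_ha * residual_infested_per_tree / fruit_per_ha
}

#' Fruit per tree implied by a harvest scenario
#'
#' @inheritParams harvest_infestation_pct
#' @return Average fruit per tree.
#' @examples
#' fruit_per_tree(45, 15, 72, 555)   # about 389 fruit/tree
#' @export
fruit_per_tree <- function(yield_t_ha = 45, carton_kg = 15,
                           fruit_per_carton = 72, trees_per_ha = 555) {
  stopifnot(yield_t_ha > 0, carton_kg > 0, fruit_per_carton > 0, trees_per_ha > 0)
  yield_t_ha * 1000 / carton_kg * fruit_per_carton / trees_per_ha
}
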
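#' Configuration for a synthetic orchard
#'
#' Describes one orchard on a rectangular planting grid together with the
#' weekly fruit-drop and infestation process used by [generate_orchard()].
#' Defaults mirror the field situation the package emulates: Navel orange
#' blocks of roughly 500--1500 trees, a mean drop of 0.84 fruit per tree per
#' week, and fruit recorded in collection lots of 10 or 20.
#'
#' @param orchard_id Character label for the orchard.
#' @param n_rows,trees_per_row Planting grid dimensions (both must be at
#'   least 2, and the grid must hold at least 20 trees so that four sets of
#'   five data trees fit).
#' @param n_weeks Number of weekly monitoring rounds before harvest.
#' @param mean_drop Expected total fruit dropped per tree per week
#'   (infested plus uninfested). Default 0.84.
#' @param infestation_rate Expected infested fruit per tree per week.
#'   Either a single value used for every week or a vector of length
#'   `n_weeks` (one value per week, e.g. a declining trend). Must not exceed
#'   `mean_drop`.
#' @param dispersion_k Negative-binomial shape for per-tree infested counts;
#'   `Inf` (the default) gives Poisson, i.e. spatially random, counts.
#'   Smaller values give stronger clumping (variance = mu + mu^2/k).
#' @param gradient_strength Strength (>= 0) of the centre-elevated
#'   infestation multiplier; 0 (default) gives a homogeneous orchard. See
#'   Details.
#' @param lot_size Fruit per collection lot, 10 or 20.
#' @param seed Optional integer seed; identical seeds give identical
#'   simulated orchards. `NULL` uses the ambient RNG stream.
#'
#' @details
#' The spatial multiplier models wind-sheltering: a tree's expected
#' infestation is scaled by `1 + gradient_strength * 2 * b`, where `b` is
#' its normalised distance to the nearest orchard edge (0 at the border,
#' 0.5 at the centre), then renormalised so the orchard-mean rate equals
#' `infestation_rate` exactly. Interior trees -- including the data trees at
#' the quadrant centres -- therefore carry more infestation than border
#' rows when `gradient_strength > 0`.
#'
#' @return An object of class `orchard_config` (a validated list).
#' @seealso [generate_orchard()], [select_data_trees()], [collect_lots()]
#' @examples
#' cfg <- orchard_config("demo", n_rows = 20, trees_per_row = 40,
#'                       n_weeks = 4, infestation_rate = 0.15, seed = 1)
#' cfg$n_trees
#' @export
orchard_config <- function(orchard_id,
                           n_rows,
                           trees_per_row,
                           n_weeks = 12,
                           mean_drop = 0.84,
                           infestation_rate = 0.05,
                           dispersion_k = Inf,
                           gradient_strength = 0,
                           lot_size = 20,
                           seed = NULL) {
  stopifnot(is.character(orchard_id), length(orchard_id) == 1L)
  n_rows <- as.integer(n_rows)
  trees_per_row <- as.integer(trees_per_row)
  n_weeks <- as.integer(n_weeks)
  if (is.na(n_rows) || n_rows < 2L || is.na(trees_per_row) || trees_per_row < 2L) {
    stop("n_rows and trees_per_row must both be integers >= 2", call. = FALSE)
  }
  if (n_rows * trees_per_row < 20L) {
    stop("the grid must hold at least 20 trees (four sets of five data trees)",
         call. = FALSE)
  }
  if (is.na(n_weeks) || n_weeks < 1L) stop("n_weeks must be >= 1", call. = FALSE)
  stopifnot(is.numeric(mean_drop), length(mean_drop) == 1L, mean_drop >= 0)
  stopifnot(is.numeric(infestation_rate), all(infestation_rate >= 0))
  if (!length(infestation_rate) %in% c(1L, n_weeks)) {
    stop("infestation_rate must have length 1 or n_weeks", call. = FALSE)
  }
  if (any(infestation_rate > mean_drop)) {
    stop("infestation_rate must not exceed mean_drop (infested fruit are part of the drop)",
         call. = FALSE)
  }
  stopifnot(is.numeric(dispersion_k), length(dispersion_k) == 1L, dispersion_k > 0)
  stopifnot(is.numeric(gradient_strength), length(gradient_strength) == 1L,
            gradient_strength >= 0)
  if (!lot_size %in% c(10L, 20L)) stop("lot_size must be 10 or 20", call. = FALSE)

  structure(
    list(orchard_id = orchard_id,
         n_rows = n_rows,
         trees_per_row = trees_per_row,
         n_trees = n_rows * trees_per_row,
         n_weeks = n_weeks,
         mean_drop = mean_drop,
         infestation_rate = infestation_rate,
         dispersion_k = dispersion_k,
         gradient_strength = gradient_strength,
         lot_size = as.integer(lot_size),
         seed = seed),
    class = "orchard_config"
  )
}

#' @export
print.orchard_config <- function(x, ...) {
  cat(sprintf("<orchard_config '%s'> %d x %d grid (%d trees), %d week(s)\n",
              x$orchard_id, x$n_rows, x$trees_per_row, x$n_trees, x$n_weeks))
  cat(sprintf("  mean drop %.3g fruit/tree/week; infestation %s/tree/week\n",
              x$mean_drop, paste(signif(x$infestation_rate, 3), collapse = ", ")))
  cat(sprintf("  dispersion k = %s; gradient %.3g; lot size %d\n",
              format(x$dispersion_k), x$gradient_strength, x$lot_size))
  invisible(x)
}

# Quadrant index (1 top-left, 2 top-right, 3 bottom-left, 4 bottom-right)
# for grid coordinates. Split lines at floor(n/2).
quadrant_of <- function(row, pos, n_rows, trees_per_row) {
  top <- row <= n_rows %/% 2L
  left <- pos <= trees_per_row %/% 2L
  ifelse(top, ifelse(left, 1L, 2L), ifelse(left, 3L, 4L))
}

# Centre-elevated multiplier, normalised to mean exactly 1 over the grid.
gradient_multiplier <- function(row, pos, n_rows, trees_per_row, strength) {
  if (strength == 0) return(rep(1, length(row)))
  x <- (pos - 0.5) / trees_per_row
  y <- (row - 0.5) / n_rows
  b <- pmin(x, 1 - x, y, 1 - y)   # distance to nearest edge, in (0, 0.5]
  g <- 1 + strength * 2 * b
  g / mean(g)
}
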
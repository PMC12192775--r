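#' Simulate weekly fruit-drop censuses for an orchard
#'
#' Draws, for every tree and week, the number of fruit dropped and the
#' number of those that are infested. Infested counts are negative binomial
#' with orchard-mean `infestation_rate` (Poisson when `dispersion_k = Inf`);
#' uninfested drop is Poisson with mean `mean_drop - infestation_rate`, so
#' total drop averages `mean_drop` and infested fruit are always a subset of
#' the dropped fruit (all infested fruit abscise).
#'
#' @param config An [orchard_config()].
#' @return A data frame with one row per tree-week: `orchard_id`, `week`,
#'   `row`, `pos`, `quadrant`, `is_data_tree`, `dropped`, `infested`.
#' @examples
#' cfg <- orchard_config("demo", 10, 10, n_weeks = 2,
#'                       infestation_rate = 0.1, seed = 42)
#' rec <- generate_orchard(cfg)
#' aggregate(cbind(dropped, infested) ~ week, rec, sum)
#' @export
generate_orchard <- function(config) {
  stopifnot(inherits(config, "orchard_config"))
  n <- config$n_trees
  row <- rep(seq_len(config$n_rows), each = config$trees_per_row)
  pos <- rep(seq_len(config$trees_per_row), times = config$n_rows)
  quad <- quadrant_of(row, pos, config$n_rows, config$trees_per_row)
  g <- gradient_multiplier(row, pos, config$n_rows, config$trees_per_row,
                           config$gradient_strength)
  dt <- select_data_trees(config)
  is_dt <- paste(row, pos) %in% paste(dt$row, dt$pos)

  rates <- rep(config$infestation_rate, length.out = config$n_weeks)

  with_seed(config$seed, {
    weeks <- vector("list", config$n_weeks)
    for (w in seq_len(config$n_weeks)) {
      mu <- rates[w] * g
      infested <- if (is.finite(config$dispersion_k)) {
        stats::rnbinom(n, size = config$dispersion_k, mu = mu)
      } else {
        stats::rpois(n, lambda = mu)
      }
      clean <- stats::rpois(n, lambda = config$mean_drop - rates[w])
      weeks[[w]] <- data.frame(
        orchard_id = config$orchard_id,
        week = w,
        row = row,
        pos = pos,
        quadrant = quad,
        is_data_tree = is_dt,
        dropped = clean + infested,
        infested = infested,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, weeks)
  })
}

#' Place four sets of five data trees
#'
#' Selects five contiguous trees centred in each of the four quadrants of
#' the planting grid, mirroring the trial layout in which one marked set of
#' five data trees sits in the middle of every quadrant. Within a quadrant
#' the set is a run of five trees in the central row (or central column when
#' rows are too short; a compact block around the quadrant centroid as a
#' last resort).
#'
#' @param config An [orchard_config()], or any list with `n_rows` and
#'   `trees_per_row`.
#' @return A data frame with 20 rows: `set` (`"A"`--`"D"`), `quadrant`,
#'   `row`, `pos`. Sets are pairwise disjoint.
#' @examples
#' select_data_trees(orchard_config("demo", 20, 40, infestation_rate = 0))
#' @export
select_data_trees <- function(config) {
  n_rows <- config$n_rows
  trees_per_row <- config$trees_per_row
  stopifnot(n_rows >= 2L, trees_per_row >= 2L)
  rs <- n_rows %/% 2L
  cs <- trees_per_row %/% 2L
  bounds <- list(
    list(q = 1L, r1 = 1L, r2 = rs, c1 = 1L, c2 = cs),
    list(q = 2L, r1 = 1L, r2 = rs, c1 = cs + 1L, c2 = trees_per_row),
    list(q = 3L, r1 = rs + 1L, r2 = n_rows, c1 = 1L, c2 = cs),
    list(q = 4L, r1 = rs + 1L, r2 = n_rows, c1 = cs + 1L, c2 = trees_per_row)
  )
  sets <- lapply(bounds, function(b) {
    h <- b$r2 - b$r1 + 1L
    w <- b$c2 - b$c1 + 1L
    if (h * w < 5L) {
      stop("grid too small: each quadrant must contain at least 5 trees",
           call. = FALSE)
    }
    if (w >= 5L) {
      r <- b$r1 + (h - 1L) %/% 2L
      c0 <- b$c1 + (w - 5L) %/% 2L
      data.frame(quadrant = b$q, row = r, pos = c0:(c0 + 4L))
    } else if (h >= 5L) {
      c <- b$c1 + (w - 1L) %/% 2L
      r0 <- b$r1 + (h - 5L) %/% 2L
      data.frame(quadrant = b$q, row = r0:(r0 + 4L), pos = c)
    } else {
      cells <- expand.grid(row = b$r1:b$r2, pos = b$c1:b$c2)
      d2 <- (cells$row - (b$r1 + b$r2) / 2)^2 + (cells$pos - (b$c1 + b$c2) / 2)^2
      cells <- cells[order(d2, cells$row, cells$pos), ][1:5, ]
      data.frame(quadrant = b$q, row = cells$row, pos = cells$pos)
    }
  })
  out <- do.call(rbind, sets)
  out$set <- LETTERS[out$quadrant]
  rownames(out) <- NULL
  out[, c("set", "quadrant", "row", "pos")]
}
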
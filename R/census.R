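#' Construct an orchard-week census
#'
#' Low-level constructor validating the conservation invariants: lot fruit
#' counts sum to `total_fruit`, lot infested counts sum to `infested_fruit`,
#' and no lot holds more infested than fruit.
#'
#' @param orchard_id,week Identifiers of the orchard-week.
#' @param n_trees Total trees in the orchard.
#' @param lots Data frame with `lot_index`, `fruit_count`, `infested_count`
#'   (may have zero rows for a fruitless week).
#' @return An object of class `orchard_census`.
#' @export
orchard_census <- function(orchard_id, week, n_trees, lots) {
  stopifnot(is.data.frame(lots))
  stop_if_missing_cols(lots, c("lot_index", "fruit_count", "infested_count"), "lots")
  if (nrow(lots) > 0L) {
    if (any(lots$fruit_count <= 0L)) stop("lot fruit_count must be positive", call. = FALSE)
    if (any(lots$infested_count < 0L) || any(lots$infested_count > lots$fruit_count)) {
      stop("lot infested_count must lie in [0, fruit_count]", call. = FALSE)
    }
    if (any(diff(lots$lot_index) <= 0L)) {
      stop("lot_index must be strictly increasing", call. = FALSE)
    }
  }
  stopifnot(n_trees >= 1L)
  structure(
    list(orchard_id = orchard_id,
         week = as.integer(week),
         n_trees = as.integer(n_trees),
         total_fruit = as.integer(sum(lots$fruit_count)),
         infested_fruit = as.integer(sum(lots$infested_count)),
         lots = lots),
    class = "orchard_census"
  )
}

#' @export
print.orchard_census <- function(x, ...) {
  cat(sprintf("<orchard_census '%s' week %d> %d trees; %d fruit in %d lot(s), %d infested (rate %.4f/tree)\n",
              x$orchard_id, x$week, x$n_trees, x$total_fruit, nrow(x$lots),
              x$infested_fruit,
              if (x$n_trees > 0) x$infested_fruit / x$n_trees else NA_real_))
  invisible(x)
}

#' Pool one week's fallen fruit into ordered collection lots
#'
#' Emulates a sanitation team walking the orchard and crating fruit in the
#' order collected: trees are visited in serpentine row order (row 1 left to
#' right, row 2 right to left, ...) or in random order, their fruit pooled
#' into a single sequence, and the sequence chunked into lots of `lot_size`
#' fruit (the final lot may be smaller). Within a tree the infested and
#' uninfested fruit are shuffled.
#'
#' @param records Tree-week records from [generate_orchard()] restricted to
#'   a single orchard-week (one row per tree).
#' @param lot_size Fruit per lot (10 or 20).
#' @param order `"serpentine"` (default) or `"random"` tree traversal.
#' @param seed Optional seed for the within-tree shuffle (and the random
#'   traversal); `NULL` uses the ambient RNG stream.
#' @return An [orchard_census()] whose `lots` component has one row per lot.
#' @examples
#' cfg <- orchard_config("demo", 10, 10, n_weeks = 1,
#'                       infestation_rate = 0.2, seed = 7)
#' collect_lots(generate_orchard(cfg), lot_size = 10, seed = 7)
#' @export
collect_lots <- function(records, lot_size = 20, order = c("serpentine", "random"),
                         seed = NULL) {
  order <- match.arg(order)
  stop_if_missing_cols(records, c("orchard_id", "week", "row", "pos", "dropped", "infested"),
                       "records")
  if (length(unique(records$orchard_id)) > 1L || length(unique(records$week)) > 1L) {
    stop("collect_lots() expects records from a single orchard-week", call. = FALSE)
  }
  if (!lot_size %in% c(10L, 20L)) stop("lot_size must be 10 or 20", call. = FALSE)
  if (any(records$infested > records$dropped)) {
    stop("infested counts exceed dropped counts", call. = FALSE)
  }
  n_trees <- nrow(records)
  if (n_trees == 0L) stop("empty record set: no trees", call. = FALSE)

  with_seed(seed, {
    ord <- if (order == "serpentine") {
      flip <- records$row %% 2L == 0L
      order(records$row, ifelse(flip, -records$pos, records$pos))
    } else {
      sample.int(n_trees)
    }
    rec <- records[ord, ]
    # fruit-level infestation status, pooled in collection order
    status <- unlist(lapply(seq_len(n_trees), function(i) {
      d <- rec$dropped[i]
      if (d == 0L) return(logical(0))
      s <- c(rep(TRUE, rec$infested[i]), rep(FALSE, d - rec$infested[i]))
      if (d > 1L) s[sample.int(d)] else s
    }), use.names = FALSE)

    if (length(status) == 0L) {
      lots <- data.frame(lot_index = integer(0), fruit_count = integer(0),
                         infested_count = integer(0))
    } else {
      idx <- ceiling(seq_along(status) / lot_size)
      lots <- data.frame(
        lot_index = sort(unique(idx)),
        fruit_count = as.integer(tabulate(idx)),
        infested_count = as.integer(vapply(split(status, idx), sum, 1L))
      )
    }
    orchard_census(records$orchard_id[1L], records$week[1L], n_trees, lots)
  })
}

#' Collect every week of a simulated orchard into lots
#'
#' Convenience wrapper applying [collect_lots()] to each week of a
#' multi-week record set.
#'
#' @inheritParams collect_lots
#' @param records Tree-week records for one orchard (any number of weeks).
#' @return A list of [orchard_census()] objects, one per week, in week order.
#' @export
collect_season <- function(records, lot_size = 20,
                           order = c("serpentine", "random"), seed = NULL) {
  order <- match.arg(order)
  weeks <- sort(unique(records$week))
  with_seed(seed, {
    lapply(weeks, function(w) {
      collect_lots(records[records$week == w, , drop = FALSE],
                   lot_size = lot_size, order = order, seed = NULL)
    })
  })
}

#' Flatten censuses to a per-lot data frame
#'
#' @param censuses A single [orchard_census()] or a list of them.
#' @return Data frame with `orchard_id`, `week`, `n_trees`, `lot_index`,
#'   `fruit_count`, `infested_count`.
#' @export
lots_table <- function(censuses) {
  if (inherits(censuses, "orchard_census")) censuses <- list(censuses)
  out <- lapply(censuses, function(cn) {
    if (nrow(cn$lots) == 0L) return(NULL)
    cbind(data.frame(orchard_id = cn$orchard_id, week = cn$week,
                     n_trees = cn$n_trees, stringsAsFactors = FALSE),
          cn$lots)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(orchard_id = character(0), week = integer(0),
                      n_trees = integer(0), lot_index = integer(0),
                      fruit_count = integer(0), infested_count = integer(0))
  }
  rownames(out) <- NULL
  out
}
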
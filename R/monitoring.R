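#' Infested fruit per tree per week
#'
#' The monitoring metric: infested fallen fruit collected over the period,
#' divided by the total number of trees and by the number of weeks covered.
#' Per-week rates use `n_weeks = 1`; season aggregates divide by the number
#' of monitored weeks.
#'
#' @param infested Number of infested fruit (vectorised).
#' @param n_trees Total trees in the orchard (or tree set).
#' @param n_weeks Number of weekly intervals covered (default 1).
#' @return Infested fruit per tree per week.
#' @examples
#' infestation_rate(1, 678, 12)   # one fruit over a 12-week season
#' @export
infestation_rate <- function(infested, n_trees, n_weeks = 1) {
  if (any(n_trees <= 0)) stop("n_trees must be positive", call. = FALSE)
  if (any(n_weeks <= 0)) stop("n_weeks must be positive", call. = FALSE)
  if (any(infested < 0)) stop("infested must be non-negative", call. = FALSE)
  infested / (n_trees * n_weeks)
}

#' Is the action threshold exceeded?
#'
#' Exceedance is strict: the protocol acts on *more than* `threshold`
#' infested fruit per tree per week, so a rate exactly at the threshold is
#' not an exceedance. Comparisons are made on unrounded rates.
#'
#' @param rate Infestation rate(s) (infested fruit/tree/week).
#' @param threshold Action threshold; default 0.1.
#' @return Logical vector.
#' @export
exceeds_threshold <- function(rate, threshold = 0.1) {
  stopifnot(threshold > 0)
  rate > threshold
}

#' Compare data-tree monitoring with the whole-orchard census
#'
#' For each orchard-week in `records`, computes the infestation rate of
#' each five-tree data set (by quadrant), the pooled 20-tree rate, and the
#' whole-orchard rate, together with strict threshold-exceedance flags.
#' The whole-orchard rate uses every tree in the records (the sanitation
#' census is exhaustive, so record totals equal census totals).
#'
#' @param records Tree-week records from [generate_orchard()] (any number
#'   of orchards and weeks); must contain `is_data_tree` and `quadrant`.
#' @param threshold Action threshold (infested fruit/tree/week).
#' @return A data frame with one row per orchard-week: set rates `set_a` ..
#'   `set_d`, `all_sets` (pooled 20 trees), `whole_orchard`, and logical
#'   exceedance flags `exceed_a` .. `exceed_d`, `exceed_sets`,
#'   `exceed_orchard`. The threshold is kept in attribute `"threshold"`.
#' @export
compare_protocols <- function(records, threshold = 0.1) {
  stop_if_missing_cols(records,
                       c("orchard_id", "week", "quadrant", "is_data_tree", "infested"),
                       "records")
  if (!any(records$is_data_tree)) stop("records contain no data trees", call. = FALSE)
  key <- interaction(records$orchard_id, records$week, drop = TRUE)
  rows <- lapply(split(records, key), function(rw) {
    dt <- rw[rw$is_data_tree, ]
    set_rate <- vapply(1:4, function(q) {
      s <- dt[dt$quadrant == q, ]
      if (nrow(s) == 0L) stop("missing data-tree records for a quadrant", call. = FALSE)
      sum(s$infested) / nrow(s)
    }, numeric(1))
    pooled <- sum(dt$infested) / nrow(dt)
    orchard <- sum(rw$infested) / nrow(rw)
    data.frame(orchard_id = rw$orchard_id[1L], week = rw$week[1L],
               n_trees = nrow(rw),
               set_a = set_rate[1], set_b = set_rate[2],
               set_c = set_rate[3], set_d = set_rate[4],
               all_sets = pooled, whole_orchard = orchard,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$orchard_id, out$week), ]
  for (col in c("a", "b", "c", "d")) {
    out[[paste0("exceed_", col)]] <- exceeds_threshold(out[[paste0("set_", col)]], threshold)
  }
  out$exceed_sets <- exceeds_threshold(out$all_sets, threshold)
  out$exceed_orchard <- exceeds_threshold(out$whole_orchard, threshold)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Season-aggregate protocol table
#'
#' Aggregates tree-week records over the whole monitoring period: per
#' orchard, the season rate of each data-tree set, the pooled sets, and the
#' whole orchard, dividing by the number of monitored weeks (the format of
#' the published season tables).
#'
#' @inheritParams compare_protocols
#' @return A data frame with one row per orchard.
#' @export
season_protocol_table <- function(records, threshold = 0.1) {
  stop_if_missing_cols(records,
                       c("orchard_id", "week", "quadrant", "is_data_tree", "infested"),
                       "records")
  rows <- lapply(split(records, records$orchard_id), function(ro) {
    nw <- length(unique(ro$week))
    dt <- ro[ro$is_data_tree, ]
    n_dt_trees <- nrow(dt) / nw
    set_rate <- vapply(1:4, function(q) {
      s <- dt[dt$quadrant == q, ]
      infestation_rate(sum(s$infested), nrow(s) / nw, nw)
    }, numeric(1))
    data.frame(orchard_id = ro$orchard_id[1L], n_weeks = nw,
               set_a = set_rate[1], set_b = set_rate[2],
               set_c = set_rate[3], set_d = set_rate[4],
               all_sets = infestation_rate(sum(dt$infested), n_dt_trees, nw),
               whole_orchard = infestation_rate(sum(ro$infested), nrow(ro) / nw, nw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Summary statistics of data-tree performance
#'
#' Reduces a table of orchard-week protocol comparisons to the four summary
#' percentages used to judge the five-data-tree system:
#' \enumerate{
#'   \item per set-week cases: \% with set rate >= whole-orchard rate;
#'   \item per orchard-week: \% where *no* set reached the orchard rate;
#'   \item per set-week cases: \% where the orchard exceeded the threshold
#'     but the set did not;
#'   \item per orchard-week *with* an orchard exceedance: \% where no set
#'     flagged it (0 when the orchard never exceeded).
#' }
#'
#' @param comparisons Output of [compare_protocols()].
#' @param threshold Action threshold; defaults to the one stored on
#'   `comparisons`.
#' @return Named numeric vector of four percentages:
#'   `pct_set_ge_orchard`, `pct_weeks_no_set_ge`,
#'   `pct_cases_missed_exceedance`, `pct_weeks_missed_exceedance`.
#' @export
table4_summary <- function(comparisons, threshold = NULL) {
  threshold <- threshold %||% attr(comparisons, "threshold") %||% 0.1
  stopifnot(nrow(comparisons) >= 1L)
  sets <- as.matrix(comparisons[, c("set_a", "set_b", "set_c", "set_d")])
  orch <- comparisons$whole_orchard
  ge <- sets >= orch                       # case-level: set at least orchard rate
  set_ex <- sets > threshold
  orch_ex <- orch > threshold
  missed_case <- set_ex == FALSE & orch_ex  # orchard over, this set silent
  wk_missed <- if (any(orch_ex)) {
    100 * mean(rowSums(set_ex[orch_ex, , drop = FALSE]) == 0L)
  } else 0
  c(pct_set_ge_orchard = 100 * mean(ge),
    pct_weeks_no_set_ge = 100 * mean(rowSums(ge) == 0L),
    pct_cases_missed_exceedance = 100 * mean(missed_case),
    pct_weeks_missed_exceedance = wk_missed)
}

#' Cumulative first-n sample curve for a census
#'
#' Walks the census fruit in collection order (lot by lot) and reports, for
#' growing sample sizes, the infested proportion among the first `n` fruit
#' and the whole-orchard rate extrapolated from it
#' (`proportion * total_fruit / n_trees`). At `n = total_fruit` the
#' extrapolated rate equals the census rate exactly. Within a lot, where
#' the collection order of individual fruit is not recorded, the lot's
#' infested fruit are spread evenly (rounded interpolation).
#'
#' @param census An [orchard_census()] with at least one fruit.
#' @param n_grid Sample sizes to evaluate; default every `n` from 1 to
#'   `total_fruit`.
#' @return Data frame with `n`, `infested`, `proportion`,
#'   `extrapolated_rate`.
#' @export
cumulative_sample_curve <- function(census, n_grid = NULL) {
  stopifnot(inherits(census, "orchard_census"))
  total <- census$total_fruit
  if (total < 1L) stop("census contains no fruit", call. = FALSE)
  n_grid <- n_grid %||% seq_len(total)
  n_grid <- as.integer(n_grid)
  if (any(n_grid < 1L) || any(n_grid > total)) {
    stop("n_grid values must lie in [1, total_fruit]", call. = FALSE)
  }
  cum_fruit <- cumsum(census$lots$fruit_count)
  cum_inf <- cumsum(census$lots$infested_count)
  inf_at <- function(n) {
    l <- findInterval(n, cum_fruit, left.open = TRUE) + 1L  # lot containing fruit n
    before_f <- if (l > 1L) cum_fruit[l - 1L] else 0L
    before_i <- if (l > 1L) cum_inf[l - 1L] else 0L
    r <- n - before_f
    before_i + round_half_up(census$lots$infested_count[l] * r /
                               census$lots$fruit_count[l])
  }
  infested <- vapply(n_grid, inf_at, numeric(1))
  prop <- infested / n_grid
  data.frame(n = n_grid,
             infested = infested,
             proportion = prop,
             extrapolated_rate = prop * total / census$n_trees)
}
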
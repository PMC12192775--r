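# Shared helpers: small deterministic objects built in code.

# A census with given totals; infested fruit packed into the earliest lots.
make_census <- function(total, infested, n_trees = 800, lot_size = 20,
                        id = "cen", week = 1) {
  stopifnot(infested <= total)
  n_full <- total %/% lot_size
  fruit <- c(rep(lot_size, n_full), if (total %% lot_size) total %% lot_size)
  inf <- pmin(fruit, pmax(0, infested - c(0, cumsum(fruit))[seq_along(fruit)]))
  orchard_census(id, week, n_trees,
                 data.frame(lot_index = seq_along(fruit),
                            fruit_count = as.integer(fruit),
                            infested_count = as.integer(inf)))
}

# Tree-week records with prescribed per-tree counts on a given grid.
manual_records <- function(dropped, infested, n_rows, trees_per_row,
                           orchard_id = "man", week = 1) {
  cfg <- orchard_config(orchard_id, n_rows, trees_per_row, n_weeks = 1,
                        mean_drop = 1, infestation_rate = 0, seed = 1)
  rec <- generate_orchard(cfg)
  rec$week <- week
  rec$dropped <- as.integer(dropped)
  rec$infested <- as.integer(infested)
  stopifnot(all(rec$infested <= rec$dropped))
  rec
}

# Per-lot table simulated straight from a log-linear count model
# (offset log fruit_count), for dispersion / trend checks.
simulate_lots <- function(n_weeks, lots_per_week, fruit = 20,
                          b0, b1 = 0, theta = Inf, orchard_id = "sim") {
  week <- rep(seq_len(n_weeks), each = lots_per_week)
  mu <- exp(b0 + b1 * week) * fruit
  y <- if (is.finite(theta)) rnbinom(length(mu), size = theta, mu = mu)
       else rpois(length(mu), mu)
  data.frame(orchard_id = orchard_id, week = week, n_trees = NA_integer_,
             lot_index = seq_along(week), fruit_count = fruit,
             infested_count = y, stringsAsFactors = FALSE)
}
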
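#' Published reference tables
#'
#' Small fixtures shipping the printed field-trial tables used for checks
#' and worked examples: orchard details (`"orchards"`), fruit totals per
#' orchard and season (`"fruit_totals"`, including the printed Total rows),
#' and the season infestation-rate tables for the high-infestation
#' (`"infestation_2021"`) and low-infestation (`"infestation_2022"`)
#' seasons.
#'
#' @param name One of `"orchards"`, `"fruit_totals"`, `"infestation_2021"`,
#'   `"infestation_2022"`.
#' @return A data frame.
#' @examples
#' t3 <- fcm_table("infestation_2021")
#' round(mean(t3$whole_orchard), 2)
#' @export
fcm_table <- function(name = c("orchards", "fruit_totals",
                               "infestation_2021", "infestation_2022")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("table_", name, ".csv"),
                      package = "fcmonitor", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write tree-week records to CSV
#'
#' One row per tree-week (`orchard_id`, `week`, `row`, `pos`, `quadrant`,
#' `is_data_tree`, `dropped`, `infested`).
#'
#' @param records Output of [generate_orchard()].
#' @param path Destination file.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_orchard_csv <- function(records, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("file exists; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write collection lots to CSV
#'
#' One row per lot (`orchard_id`, `week`, `n_trees`, `lot_index`,
#' `fruit_count`, `infested_count`); the format read back by
#' [load_census_csv()].
#'
#' @param censuses A list of [orchard_census()] objects (or one census).
#' @inheritParams write_orchard_csv
#' @return Invisibly, `path`.
#' @export
write_lots_csv <- function(censuses, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("file exists; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  utils::write.csv(lots_table(censuses), path, row.names = FALSE)
  invisible(path)
}

#' Read censuses from a lot CSV
#'
#' Validates the schema and the count invariants row by row (pointing at the
#' offending row on failure) and reassembles one [orchard_census()] per
#' orchard-week.
#'
#' @param path CSV written by [write_lots_csv()] or following its schema.
#' @return A list of [orchard_census()] objects, ordered by orchard and
#'   week.
#' @export
load_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("orchard_id", "week", "n_trees", "lot_index",
                             "fruit_count", "infested_count"),
                       basename(path))
  bad <- which(df$infested_count > df$fruit_count | df$infested_count < 0 |
                 df$fruit_count <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid lot counts at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  key <- interaction(df$orchard_id, df$week, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$lot_index), ]
    if (length(unique(g$n_trees)) != 1L) {
      stop(sprintf("inconsistent n_trees for orchard %s week %s",
                   g$orchard_id[1L], g$week[1L]), call. = FALSE)
    }
    orchard_census(g$orchard_id[1L], g$week[1L], g$n_trees[1L],
                   g[, c("lot_index", "fruit_count", "infested_count")])
  })
  ord <- order(vapply(out, function(cn) cn$orchard_id, character(1)),
               vapply(out, function(cn) cn$week, integer(1)))
  unname(out[ord])
}

#' Run the full monitoring evaluation pipeline
#'
#' Simulates a batch of orchards, then evaluates the monitoring protocols
#' end to end: data-tree versus whole-orchard comparison with its four
#' summary percentages, Monte Carlo sampling-coverage curve with minimal
#' adequate sample sizes, per-orchard dispersion verdicts, mean-variance
#' ratios, and the season time trend. All randomness flows from `seed`;
#' identical seeds give identical reports.
#'
#' @param orchard_rates Named or unnamed vector of per-orchard infestation
#'   rates (infested fruit/tree/week); one orchard is simulated per entry.
#' @param n_weeks Weeks of monitoring.
#' @param n_rows,trees_per_row Grid dimensions shared by all orchards.
#' @param mean_drop,dispersion_k,gradient_strength,lot_size Passed to
#'   [orchard_config()].
#' @param threshold Action threshold.
#' @param coverage_sizes Subsample-size grid for the coverage curve.
#' @param coverage_iterations Monte Carlo iterations per census and size.
#' @param adequacy Adequacy levels reported for the coverage curve.
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `comparisons.csv`, `lots.csv`, `coverage.csv` there.
#' @param overwrite Allow overwriting files in `out_dir`.
#' @return A list (the report): `seed`, `scenario`, `protocol`
#'   (comparisons + summary), `coverage` (curve + minimal n), `dispersion`
#'   (verdict table + mean-variance ratios), `trend`.
#' @export
run_evaluation <- function(orchard_rates,
                           n_weeks = 9,
                           n_rows = 20, trees_per_row = 40,
                           mean_drop = 0.84,
                           dispersion_k = Inf,
                           gradient_strength = 0,
                           lot_size = 20,
                           threshold = 0.1,
                           coverage_sizes = seq(25, 300, by = 25),
                           coverage_iterations = 999,
                           adequacy = c(0.95, 0.90),
                           seed = 1,
                           out_dir = NULL,
                           overwrite = FALSE) {
  stopifnot(length(orchard_rates) >= 1L, all(orchard_rates >= 0))
  ids <- names(orchard_rates) %||% sprintf("orchard_%02d", seq_along(orchard_rates))

  with_seed(seed, {
    records <- list()
    censuses <- list()
    for (i in seq_along(orchard_rates)) {
      cfg <- orchard_config(ids[i], n_rows, trees_per_row, n_weeks = n_weeks,
                            mean_drop = mean_drop,
                            infestation_rate = orchard_rates[[i]],
                            dispersion_k = dispersion_k,
                            gradient_strength = gradient_strength,
                            lot_size = lot_size, seed = NULL)
      rec <- generate_orchard(cfg)
      records[[i]] <- rec
      censuses <- c(censuses, collect_season(rec, lot_size = lot_size))
    }
    records <- do.call(rbind, records)
    lots <- lots_table(censuses)

    comparisons <- compare_protocols(records, threshold = threshold)
    summary4 <- table4_summary(comparisons)

    nonempty <- Filter(function(cn) cn$total_fruit >= 1L, censuses)
    curve <- coverage_curve(nonempty, sample_sizes = coverage_sizes,
                            iterations = coverage_iterations, seed = NULL)
    min_n <- vapply(adequacy, function(a) minimal_adequate_n(curve, a), integer(1))
    names(min_n) <- paste0("adequacy_", adequacy)

    total_infested <- sum(lots$infested_count)
    disp <- if (total_infested >= 2L) {
      dispersion_table(lots)
    } else NULL
    trend <- if (total_infested >= 2L && n_weeks >= 3L) {
      tryCatch(trend_test(lots), error = function(e) NULL)
    } else NULL

    report <- list(
      seed = seed,
      scenario = list(orchards = ids, rates = unname(orchard_rates),
                      n_weeks = n_weeks, n_trees = n_rows * trees_per_row,
                      mean_drop = mean_drop, dispersion_k = dispersion_k,
                      gradient_strength = gradient_strength,
                      lot_size = lot_size, threshold = threshold),
      protocol = list(summary = as.list(round(summary4, 2)),
                      comparisons = comparisons),
      coverage = list(curve = as.data.frame(curve),
                      iterations = coverage_iterations,
                      minimal_adequate_n = as.list(min_n)),
      dispersion = list(verdicts = disp,
                        mean_variance = mean_variance_table(lots),
                        skipped = is.null(disp)),
      trend = if (is.null(trend)) NULL else
        list(family = trend$family, slope = trend$slope, se = trend$se,
             weekly_change = trend$weekly_change,
             statistic = trend$statistic, df = trend$df,
             p_value = trend$p_value)
    )

    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      wr <- function(x, f) {
        p <- file.path(out_dir, f)
        if (file.exists(p) && !overwrite) {
          stop(sprintf("%s exists; pass overwrite = TRUE", p), call. = FALSE)
        }
        p
      }
      utils::write.csv(comparisons, wr(comparisons, "comparisons.csv"),
                       row.names = FALSE)
      utils::write.csv(lots, wr(lots, "lots.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(curve), wr(curve, "coverage.csv"),
                       row.names = FALSE)
      jsonlite::write_json(report, wr(report, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", force = TRUE)
    }
    report
  })
}
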
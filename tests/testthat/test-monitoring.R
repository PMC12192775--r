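test_that("the infestation metric divides by trees and weeks", {
  expect_equal(infestation_rate(0, 800), 0)
  expect_equal(infestation_rate(1, 678, 12), 1 / 8136)
  expect_equal(round(infestation_rate(1, 678, 12), 4), 1e-4)
  expect_equal(infestation_rate(81, 810), 0.1)
  expect_false(exceeds_threshold(infestation_rate(81, 810)))  # boundary is not exceedance
  expect_true(exceeds_threshold(infestation_rate(82, 810)))
  expect_error(infestation_rate(1, 0), "n_trees")
  expect_error(infestation_rate(1, 10, 0), "n_weeks")
})

test_that("protocol comparison: zero orchard, pooled-rate bounds, monotone thresholds", {
  cfg <- orchard_config("p", 10, 10, n_weeks = 4, mean_drop = 1,
                        infestation_rate = 0.25, seed = 21)
  rec <- generate_orchard(cfg)

  zero <- rec
  zero$infested <- 0L
  cmp0 <- compare_protocols(zero)
  expect_true(all(cmp0$whole_orchard == 0))
  expect_true(all(cmp0$all_sets == 0))
  expect_false(any(cmp0$exceed_orchard | cmp0$exceed_sets))

  cmp <- compare_protocols(rec)
  sets <- as.matrix(cmp[, c("set_a", "set_b", "set_c", "set_d")])
  expect_true(all(cmp$all_sets >= apply(sets, 1, min) - 1e-12))
  expect_true(all(cmp$all_sets <= apply(sets, 1, max) + 1e-12))
  expect_equal(cmp$all_sets, rowMeans(sets))  # equal five-tree sets

  # raising the threshold never increases any exceedance count
  flags <- vapply(c(0.05, 0.1, 0.2, 0.4),
                  function(th) sum(as.matrix(compare_protocols(rec, th)[,
                    c("exceed_a", "exceed_b", "exceed_c", "exceed_d",
                      "exceed_sets", "exceed_orchard")])),
                  numeric(1))
  expect_true(all(diff(flags) <= 0))
})

test_that("season aggregation is consistent with weekly comparisons", {
  cfg <- orchard_config("s", 10, 10, n_weeks = 5, mean_drop = 1,
                        infestation_rate = 0.2, seed = 31)
  rec <- generate_orchard(cfg)
  cmp <- compare_protocols(rec)
  season <- season_protocol_table(rec)
  expect_equal(season$whole_orchard, mean(cmp$whole_orchard))
  expect_equal(season$all_sets, mean(cmp$all_sets))
  expect_equal(season$set_b, mean(cmp$set_b))
  expect_equal(season$n_weeks, 5L)
})

test_that("data-tree performance summary handles the extreme cases", {
  base <- data.frame(orchard_id = "o", week = 1, n_trees = 100,
                     set_a = 0.3, set_b = 0.4, set_c = 0.5, set_d = 0.2,
                     all_sets = 0.35, whole_orchard = 0.15)
  s <- table4_summary(base, threshold = 0.1)
  expect_equal(unname(s), c(100, 0, 0, 0))

  worst <- transform(base, set_a = 0, set_b = 0, set_c = 0, set_d = 0)
  s <- table4_summary(worst, threshold = 0.1)
  expect_equal(unname(s), c(0, 100, 100, 100))

  # below-threshold orchard-week: no exceedance statistics triggered
  quiet <- transform(base, whole_orchard = 0.05)
  s <- table4_summary(quiet, threshold = 0.1)
  expect_equal(unname(s[3:4]), c(0, 0))
})

test_that("no orchard exceedance is ever missed when set rates dominate", {
  # batch shaped like the high-infestation season: 7 orchards x 9 weeks
  rates <- c(0.15, 0.02, 0.17, 0.06, 0.09, 0.18, 0.21)
  set.seed(91)
  recs <- do.call(rbind, lapply(seq_along(rates), function(i) {
    generate_orchard(orchard_config(sprintf("o%02d", i), 20, 40, n_weeks = 9,
                                    mean_drop = 0.84, infestation_rate = rates[i],
                                    gradient_strength = 2, seed = NULL))
  }))
  cmp <- compare_protocols(recs)
  s <- table4_summary(cmp)
  expect_true(all(s >= 0 & s <= 100))
  # whenever every set rate reaches the orchard rate, an orchard exceedance
  # cannot be missed; the summary must reflect that on the dominated subset
  sets <- as.matrix(cmp[, c("set_a", "set_b", "set_c", "set_d")])
  dom <- cmp[apply(sets, 1, min) >= cmp$whole_orchard, ]
  expect_gt(nrow(dom), 0)
  sdom <- table4_summary(dom, threshold = 0.1)
  expect_equal(unname(sdom["pct_set_ge_orchard"]), 100)
  expect_equal(unname(sdom["pct_weeks_missed_exceedance"]), 0)
  expect_equal(unname(sdom["pct_cases_missed_exceedance"]), 0)
})

test_that("cumulative sample curve interpolates lots and closes on the census rate", {
  cen <- orchard_census("c", 1, 50,
    data.frame(lot_index = 1:3, fruit_count = c(10L, 10L, 5L),
               infested_count = c(2L, 0L, 3L)))
  curve <- cumulative_sample_curve(cen)
  expect_equal(nrow(curve), 25L)
  expect_equal(curve$infested[curve$n == 10], 2)
  expect_equal(curve$infested[curve$n == 15], 2)
  expect_equal(curve$infested[curve$n == 22], 3)   # 2 + round(3 * 2/5)
  expect_equal(curve$proportion[25], 5 / 25)
  expect_equal(curve$extrapolated_rate[25], 5 / 50)  # closure: census rate

  none <- orchard_census("c", 1, 50,
    data.frame(lot_index = 1:2, fruit_count = c(10L, 10L), infested_count = 0L))
  expect_true(all(cumulative_sample_curve(none)$extrapolated_rate == 0))

  empty <- orchard_census("c", 1, 50,
    data.frame(lot_index = integer(0), fruit_count = integer(0),
               infested_count = integer(0)))
  expect_error(cumulative_sample_curve(empty), "no fruit")
})

test_that("published season table values are carried by the fixture", {
  t3 <- fcm_table("infestation_2021")
  r <- t3[t3$orchard == "23A", ]
  expect_equal(c(r$set_a, r$set_b, r$set_c, r$set_d), c(0.29, 0.65, 0.64, 0.22))
  expect_equal(r$all_sets, 0.48)
  expect_equal(r$whole_orchard, 0.21)
  expect_true(all(exceeds_threshold(unlist(r[, -1]))))
})
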
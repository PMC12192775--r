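test_that("orchard_config rejects impossible orchards", {
  expect_error(orchard_config("x", 1, 30, infestation_rate = 0), "n_rows")
  expect_error(orchard_config("x", 4, 4, infestation_rate = 0), "20 trees")
  expect_error(orchard_config("x", 10, 10, mean_drop = 0.5, infestation_rate = 0.6),
               "mean_drop")
  expect_error(orchard_config("x", 10, 10, infestation_rate = 0, lot_size = 15),
               "lot_size")
  expect_error(orchard_config("x", 10, 10, infestation_rate = 0, n_weeks = 0),
               "n_weeks")
})

test_that("zero infestation rate gives a clean orchard and seeding is reproducible", {
  cfg <- orchard_config("x", 6, 6, n_weeks = 3, infestation_rate = 0, seed = 11)
  rec <- generate_orchard(cfg)
  expect_true(all(rec$infested == 0))
  expect_identical(rec, generate_orchard(cfg))
  expect_equal(nrow(rec), 6 * 6 * 3)
  # a different seed moves the draws
  cfg2 <- orchard_config("x", 6, 6, n_weeks = 3, infestation_rate = 0, seed = 12)
  expect_false(identical(generate_orchard(cfg2)$dropped, rec$dropped))
})

test_that("simulated means match the configured drop and infestation rates", {
  cfg <- orchard_config("x", 100, 100, n_weeks = 1, mean_drop = 0.84,
                        infestation_rate = 0.1, seed = 5)
  rec <- generate_orchard(cfg)
  n <- nrow(rec)
  expect_lt(abs(mean(rec$dropped) - 0.84), 3 * sd(rec$dropped) / sqrt(n))
  expect_lt(abs(mean(rec$infested) - 0.1), 3 * sd(rec$infested) / sqrt(n))
  expect_true(all(rec$infested <= rec$dropped))
})

test_that("the spatial gradient preserves the orchard-mean rate", {
  cfg <- orchard_config("x", 40, 40, n_weeks = 1, mean_drop = 1,
                        infestation_rate = 0.3, gradient_strength = 3, seed = 2)
  rec <- generate_orchard(cfg)
  expect_lt(abs(mean(rec$infested) - 0.3), 3 * sd(rec$infested) / sqrt(nrow(rec)))
  # centre block carries more infestation than the border rows in expectation
  g <- fcmonitor:::gradient_multiplier(rec$row, rec$pos, 40, 40, 3)
  expect_equal(mean(g), 1, tolerance = 1e-12)
  expect_gt(min(g[rec$row %in% 19:22 & rec$pos %in% 19:22]),
            max(g[rec$row == 1]))
})

test_that("data-tree sets are five contiguous trees per quadrant, pairwise disjoint", {
  # minimal grid: every tree is a data tree
  dt <- select_data_trees(list(n_rows = 2L, trees_per_row = 10L))
  expect_equal(nrow(dt), 20L)
  expect_equal(as.integer(table(dt$quadrant)), rep(5L, 4))
  expect_equal(nrow(unique(dt[, c("row", "pos")])), 20L)

  for (dims in list(c(4L, 6L), c(10L, 4L), c(6L, 6L), c(20L, 40L))) {
    dt <- select_data_trees(list(n_rows = dims[1], trees_per_row = dims[2]))
    expect_equal(nrow(unique(dt[, c("row", "pos")])), 20L)
    expect_equal(as.integer(table(dt$quadrant)), rep(5L, 4))
    # every selected tree lies in its own quadrant
    q <- fcmonitor:::quadrant_of(dt$row, dt$pos, dims[1], dims[2])
    expect_equal(q, dt$quadrant)
  }

  # interior centroids on a comfortably large grid
  dt <- select_data_trees(list(n_rows = 20L, trees_per_row = 40L))
  cen <- aggregate(cbind(row, pos) ~ quadrant, dt, mean)
  expect_true(all(cen$row > 1 & cen$row < 20 & cen$pos > 1 & cen$pos < 40))
  expect_true(all(cen$row != 10.5))  # strictly inside one half, not on the split

  expect_error(select_data_trees(list(n_rows = 3L, trees_per_row = 7L)),
               "too small")
})

test_that("lot collection chunks fruit and conserves every total", {
  rec <- manual_records(dropped = c(9, 6, 4, 3, 3, rep(0, 31)),
                        infested = c(2, 1, 0, 1, 1, rep(0, 31)),
                        n_rows = 6, trees_per_row = 6)
  cen <- collect_lots(rec, lot_size = 10, seed = 3)
  expect_s3_class(cen, "orchard_census")
  expect_equal(cen$lots$fruit_count, c(10L, 10L, 5L))
  expect_equal(cen$total_fruit, sum(rec$dropped))
  expect_equal(cen$infested_fruit, sum(rec$infested))
  expect_equal(sum(cen$lots$infested_count), cen$infested_fruit)
  expect_equal(cen$n_trees, 36L)

  # all fruit infested: every lot saturated
  rec$infested <- rec$dropped
  cen <- collect_lots(rec, lot_size = 10, seed = 3)
  expect_equal(cen$lots$infested_count, cen$lots$fruit_count)

  # fruitless week: a census with zero fruit and zero lots
  rec$dropped <- rec$infested <- 0L
  cen <- collect_lots(rec, lot_size = 10)
  expect_equal(cen$total_fruit, 0L)
  expect_equal(nrow(cen$lots), 0L)

  expect_error(collect_lots(rec, lot_size = 15), "lot_size")
})

test_that("serpentine collection exposes the centre gradient, random order removes it", {
  cfg <- orchard_config("g", 20, 20, n_weeks = 1, mean_drop = 1,
                        infestation_rate = 0.3, gradient_strength = 4,
                        lot_size = 20, seed = NULL)
  contrast <- function(order) {
    # infested proportion in the central half of lots minus the first quarter
    cen <- collect_lots(generate_orchard(cfg), lot_size = 20, order = order)
    k <- nrow(cen$lots)
    early <- seq_len(max(1, floor(k / 4)))
    mid <- seq(floor(k / 4) + 1, floor(3 * k / 4))
    with(cen$lots, sum(infested_count[mid]) / sum(fruit_count[mid]) -
                     sum(infested_count[early]) / sum(fruit_count[early]))
  }
  set.seed(41)
  serp <- replicate(400, contrast("serpentine"))
  rand <- replicate(400, contrast("random"))
  expect_gt(mean(serp) / (sd(serp) / sqrt(length(serp))), 5)   # strong signal
  expect_lt(abs(mean(rand)) / (sd(rand) / sqrt(length(rand))), 3)  # no signal
})

test_that("tree-level clumping inflates the lot-level mean-variance ratio", {
  # Under spatially random (Poisson) infestation the pooled fruit statuses
  # are iid Bernoulli(p), so per-lot counts are Binomial(lot_size, p) with
  # variance/mean = 1 - p, slightly below 1. Clumped trees push the ratio
  # above 1.
  ratio_for <- function(k) {
    cfg <- orchard_config("k", 25, 40, n_weeks = 1, mean_drop = 0.84,
                          infestation_rate = 0.1, dispersion_k = k, seed = NULL)
    cen <- collect_lots(generate_orchard(cfg), lot_size = 20)
    mean_variance_ratio(cen$lots$infested_count)
  }
  set.seed(77)
  clumped <- replicate(50, ratio_for(0.2))
  random <- replicate(50, ratio_for(Inf))
  p <- 0.1 / 0.84
  expect_gt(mean(clumped), 1)
  expect_lt(abs(mean(random) - (1 - p)), 3 * sd(random) / sqrt(length(random)))
  expect_gt(t.test(clumped, random)$statistic, 3)
})
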
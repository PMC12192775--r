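#' Lower bound of a binomial confidence interval
#'
#' Two-sided confidence interval lower bound for an observed proportion
#' `infested / total`. The default is the Wilson score interval, which is
#' well behaved at the small counts typical of infestation censuses; a
#' normal (Wald) approximation is available for sensitivity analysis. Both
#' return 0 when `infested = 0`.
#'
#' @param infested Number of infested fruit observed.
#' @param total Total fruit observed (>= 1).
#' @param level Two-sided confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"normal"`.
#' @return Lower confidence bound for the true infested proportion.
#' @examples
#' ci_lower_bound(50, 500)            # Wilson: about 0.0767
#' ci_lower_bound(0, 500)             # zero count: 0
#' @export
ci_lower_bound <- function(infested, total, level = 0.95,
                           method = c("wilson", "normal")) {
  method <- match.arg(method)
  stopifnot(total >= 1, infested >= 0, infested <= total,
            level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- infested / total
  lo <- if (method == "wilson") {
    (p + z^2 / (2 * total) -
       z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2))) / (1 + z^2 / total)
  } else {
    p - z * sqrt(p * (1 - p) / total)
  }
  max(0, lo)
}

#' Monte Carlo sampling adequacy of a subsample size
#'
#' Draws `iterations` random fruit subsamples of size `n`, with
#' replacement, from a census (equivalently: binomial draws at the census
#' infested proportion), and scores an iteration *adequate* when its
#' infested proportion is at or above the lower bound of the census's
#' two-sided confidence interval. Returns the fraction of adequate
#' iterations -- the sampling coverage of subsample size `n` for this
#' orchard-week.
#'
#' @param census An [orchard_census()] (or any list with `infested_fruit`
#'   and `total_fruit`), `total_fruit >= 1`.
#' @param n Subsample size (>= 1).
#' @param iterations Monte Carlo iterations (default 9999).
#' @param level,method Passed to [ci_lower_bound()].
#' @param seed Optional seed; `NULL` uses the ambient stream.
#' @return Coverage in [0, 1].
#' @examples
#' cen <- orchard_census("x", 1, 800,
#'   data.frame(lot_index = 1:10, fruit_count = 20, infested_count = 2))
#' resample_adequacy(cen, n = 50, iterations = 999, seed = 1)
#' @export
resample_adequacy <- function(census, n, iterations = 9999, level = 0.95,
                              method = c("wilson", "normal"), seed = NULL) {
  method <- match.arg(method)
  if (census$total_fruit < 1L) stop("census contains no fruit", call. = FALSE)
  if (n < 1L) stop("subsample size n must be >= 1", call. = FALSE)
  stopifnot(iterations >= 1L)
  p <- census$infested_fruit / census$total_fruit
  lo <- ci_lower_bound(census$infested_fruit, census$total_fruit,
                       level = level, method = method)
  with_seed(seed, {
    x <- stats::rbinom(iterations, size = n, prob = p)
    mean(x / n >= lo - 1e-12)
  })
}

#' Sampling-coverage curve over subsample sizes
#'
#' Computes the Monte Carlo sampling coverage of each subsample size in
#' `sample_sizes` for every census, and pools by averaging across
#' orchard-weeks. Censuses with identical (total, infested) pairs share the
#' same coverage by construction, so duplicated censuses leave the pooled
#' curve unchanged.
#'
#' @param censuses A list of [orchard_census()] objects (or one census).
#' @param sample_sizes Increasing subsample sizes; default 5-fruit steps
#'   from 5 to `min(500, smallest census total)`.
#' @param iterations Monte Carlo iterations per census and size (default
#'   9999).
#' @param level,method Passed to [ci_lower_bound()].
#' @param seed Optional seed making the whole curve reproducible.
#' @return An object of class `coverage_curve`: a data frame with `n` and
#'   pooled `coverage`, with the per-census coverage matrix in attribute
#'   `"per_census"` and the Monte Carlo settings in attributes.
#' @export
coverage_curve <- function(censuses, sample_sizes = NULL, iterations = 9999,
                           level = 0.95, method = c("wilson", "normal"),
                           seed = NULL) {
  method <- match.arg(method)
  if (inherits(censuses, "orchard_census")) censuses <- list(censuses)
  if (length(censuses) == 0L) stop("no censuses supplied", call. = FALSE)
  totals <- vapply(censuses, function(cn) cn$total_fruit, numeric(1))
  if (any(totals < 1)) stop("every census must contain at least one fruit", call. = FALSE)
  if (is.null(sample_sizes)) {
    top <- min(500, min(totals))
    sample_sizes <- if (top >= 5) seq(5, top, by = 5) else seq_len(top)
  }
  sample_sizes <- sort(unique(as.integer(sample_sizes)))
  stopifnot(all(sample_sizes >= 1L))

  key <- vapply(censuses, function(cn) paste(cn$total_fruit, cn$infested_fruit),
                character(1))
  uniq <- !duplicated(key)
  with_seed(seed, {
    per_uniq <- sapply(censuses[uniq], function(cn) {
      vapply(sample_sizes, function(n) {
        resample_adequacy(cn, n, iterations = iterations,
                          level = level, method = method, seed = NULL)
      }, numeric(1))
    })
    per_uniq <- matrix(per_uniq, nrow = length(sample_sizes))
    colnames(per_uniq) <- key[uniq]
    per_census <- per_uniq[, match(key, key[uniq]), drop = FALSE]
    out <- data.frame(n = sample_sizes, coverage = rowMeans(per_census))
    attr(out, "per_census") <- per_census
    attr(out, "iterations") <- iterations
    attr(out, "level") <- level
    attr(out, "method") <- method
    attr(out, "n_censuses") <- length(censuses)
    class(out) <- c("coverage_curve", "data.frame")
    out
  })
}

#' Smallest adequate subsample size
#'
#' @param curve A [coverage_curve()].
#' @param adequacy Required coverage (e.g. 0.95 or 0.90).
#' @return The smallest `n` on the curve's grid with coverage at or above
#'   `adequacy`, or `NA_integer_` when the grid never reaches it.
#' @export
minimal_adequate_n <- function(curve, adequacy = 0.95) {
  stopifnot(nrow(curve) >= 1L, adequacy > 0, adequacy <= 1)
  ok <- which(curve$coverage >= adequacy)
  if (length(ok) == 0L) NA_integer_ else as.integer(curve$n[min(ok)])
}

#' @export
print.coverage_curve <- function(x, ...) {
  cat(sprintf("<coverage_curve> %d size(s) %d-%d, %d census(es), %d iterations (%s CI, level %.2f)\n",
              nrow(x), min(x$n), max(x$n), attr(x, "n_censuses"),
              attr(x, "iterations"), attr(x, "method"), attr(x, "level")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Plot a sampling-coverage curve
#'
#' Coverage against subsample size with reference lines at the adequacy
#' levels (0.95 solid red, 0.90 dashed grey by default).
#'
#' @param x A [coverage_curve()].
#' @param adequacy Reference levels to draw.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.coverage_curve <- function(x, adequacy = c(0.95, 0.90), ...) {
  plot(x$n, x$coverage, type = "b", pch = 16, ylim = c(min(x$coverage, 0.8), 1),
       xlab = "Subsample size (fruit)", ylab = "Sampling coverage", ...)
  cols <- c("red", "grey40")
  for (i in seq_along(adequacy)) {
    graphics::abline(h = adequacy[i], lty = i, col = cols[(i - 1) %% 2 + 1])
  }
  invisible(x)
}
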
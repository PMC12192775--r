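#' Mean-variance ratio of per-lot infested counts
#'
#' The classical aggregation index for count data: sample variance divided
#' by sample mean. Values near 1 indicate randomly dispersed (Poisson-like)
#' counts; values above 1 indicate clumping.
#'
#' @param counts Per-lot infested counts for one orchard-week (>= 2 lots).
#' @return Variance/mean ratio; `NA` when the mean is 0.
#' @examples
#' mean_variance_ratio(c(0, 0, 0, 4))   # 4
#' @export
mean_variance_ratio <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 lots", call. = FALSE)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Mean-variance ratios per orchard-week
#'
#' @param lots Per-lot data frame (see [lots_table()]) with `orchard_id`,
#'   `week`, `infested_count`.
#' @return Data frame with `orchard_id`, `week`, `n_lots`, `mv_ratio`
#'   (`NA` for fruitless or single-lot weeks).
#' @export
mean_variance_table <- function(lots) {
  stop_if_missing_cols(lots, c("orchard_id", "week", "infested_count"), "lots")
  key <- interaction(lots$orchard_id, lots$week, drop = TRUE)
  rows <- lapply(split(lots, key), function(lw) {
    data.frame(orchard_id = lw$orchard_id[1L], week = lw$week[1L],
               n_lots = nrow(lw),
               mv_ratio = if (nrow(lw) >= 2L) mean_variance_ratio(lw$infested_count)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$orchard_id, out$week), ]
  rownames(out) <- NULL
  out
}

#' Fit a count model to per-lot infested counts
#'
#' Log-linear model for per-lot infested counts as a function of week, with
#' the log of each lot's fruit count as an offset (so the linear predictor
#' models infestation per fruit). Families: Poisson (random dispersion) or
#' negative binomial (clumped; shape estimated by maximum likelihood via
#' [MASS::glm.nb()]).
#'
#' Degenerate data (all counts zero) sit at the boundary where the
#' log-likelihood tends to 0; such fits are returned with `loglik = 0` and
#' `degenerate = TRUE`. When the data are equi- or under-dispersed the
#' negative-binomial shape MLE is at its upper (+Inf, Poisson) boundary; the
#' fit is then reported with `theta = Inf` and the Poisson log-likelihood,
#' so the negative binomial never scores below its Poisson special case.
#'
#' @param lots Per-lot data frame with `week`, `fruit_count`,
#'   `infested_count` (single orchard, any number of weeks).
#' @param family `"poisson"` or `"negbin"`.
#' @return An object of class `count_model_fit`: list with `family`,
#'   `coefficients` (log scale), `theta` (negbin shape; `Inf` at the
#'   Poisson boundary; `NA` for Poisson fits), `loglik`, `df`,
#'   `converged`, `degenerate`, `boundary`, `n_lots`, and the underlying
#'   `fit` object (when available).
#' @export
fit_count_model <- function(lots, family = c("poisson", "negbin")) {
  family <- match.arg(family)
  stop_if_missing_cols(lots, c("week", "fruit_count", "infested_count"), "lots")
  if (any(lots$fruit_count <= 0)) stop("fruit_count must be positive", call. = FALSE)
  if (any(lots$infested_count < 0)) stop("infested_count must be non-negative", call. = FALSE)
  n <- nrow(lots)
  if (n < 2L) stop("need at least 2 lots", call. = FALSE)

  base <- list(family = family, n_lots = n, degenerate = FALSE,
               boundary = FALSE, converged = TRUE, theta = NA_real_, fit = NULL)

  if (sum(lots$infested_count) == 0L) {
    # boundary: mu -> 0 gives log-likelihood -> 0 for both families
    base$degenerate <- TRUE
    base$boundary <- TRUE
    base$coefficients <- c(`(Intercept)` = -Inf)
    base$loglik <- 0
    base$df <- 0L
    return(structure(base, class = "count_model_fit"))
  }

  use_week <- length(unique(lots$week)) >= 2L
  fml <- if (use_week) {
    infested_count ~ week + offset(log(fruit_count))
  } else {
    infested_count ~ 1 + offset(log(fruit_count))
  }

  pois <- suppressWarnings(stats::glm(fml, family = stats::poisson(), data = lots))
  if (family == "poisson") {
    base$coefficients <- stats::coef(pois)
    base$loglik <- as.numeric(stats::logLik(pois))
    base$df <- attr(stats::logLik(pois), "df")
    base$converged <- pois$converged
    base$fit <- pois
    return(structure(base, class = "count_model_fit"))
  }

  ll_pois <- as.numeric(stats::logLik(pois))
  nb <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = lots)),
    error = function(e) NULL
  )
  ll_nb <- if (is.null(nb)) -Inf else as.numeric(stats::logLik(nb))
  if (ll_nb < ll_pois) {
    # shape MLE at the +Inf (Poisson) boundary; report the boundary fit
    base$boundary <- TRUE
    base$theta <- Inf
    base$coefficients <- stats::coef(pois)
    base$loglik <- ll_pois
    base$df <- attr(stats::logLik(pois), "df") + 1L
    base$fit <- pois
  } else {
    base$theta <- nb$theta
    base$coefficients <- stats::coef(nb)
    base$loglik <- ll_nb
    base$df <- attr(stats::logLik(nb), "df")
    base$converged <- nb$converged %||% TRUE
    base$fit <- nb
  }
  structure(base, class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("<count_model_fit %s> %d lots, logLik %.3f%s%s\n",
              x$family, x$n_lots, x$loglik,
              if (!is.na(x$theta)) sprintf(", theta %.3g", x$theta) else "",
              if (x$degenerate) " (degenerate: all counts zero)"
              else if (x$boundary) " (shape at Poisson boundary)" else ""))
  if (!x$degenerate) print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio dispersion test
#'
#' Compares the negative-binomial fit to its nested Poisson special case by
#' twice the log-likelihood difference, referred to a chi-squared
#' distribution with 1 degree of freedom. A significant improvement
#' (p < 0.05) classifies the counts as *clumped*; otherwise *random*. The
#' df-1 reference is conservative because the shape parameter sits on the
#' boundary of its space under the null.
#'
#' @param fit_pois,fit_nb `count_model_fit` objects for the same lots, with
#'   families `"poisson"` and `"negbin"`.
#' @return An object of class `dispersion_verdict`: list with
#'   `distribution` (`"clumped"`/`"random"`), `statistic`, `df` (1),
#'   `p_value`.
#' @seealso [classify_dispersion()] for the one-call version.
#' @export
dispersion_test <- function(fit_pois, fit_nb) {
  stopifnot(inherits(fit_pois, "count_model_fit"),
            inherits(fit_nb, "count_model_fit"))
  if (fit_pois$family != "poisson" || fit_nb$family != "negbin") {
    stop("arguments must be a poisson fit and a negbin fit, in that order",
         call. = FALSE)
  }
  if (fit_pois$n_lots != fit_nb$n_lots) {
    stop("fits are based on different numbers of lots", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_nb$loglik - fit_pois$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(
    list(distribution = if (p < 0.05) "clumped" else "random",
         statistic = stat, df = 1L, p_value = p),
    class = "dispersion_verdict"
  )
}

#' @export
print.dispersion_verdict <- function(x, ...) {
  cat(sprintf("Dispersion: %s (X^2 = %.2f, df = %d, p = %.4g)\n",
              x$distribution, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classify dispersion of one orchard's lots
#'
#' Fits the Poisson and negative-binomial count models and runs
#' [dispersion_test()].
#'
#' @inheritParams fit_count_model
#' @return A `dispersion_verdict`.
#' @export
classify_dispersion <- function(lots) {
  dispersion_test(fit_count_model(lots, "poisson"),
                  fit_count_model(lots, "negbin"))
}

#' Per-orchard dispersion verdict table
#'
#' Runs the Poisson-vs-negative-binomial comparison for every orchard in a
#' lot table, optionally restricted to a window of weeks (refitting from
#' scratch on the window). Orchards with fewer than 2 infested fruit are
#' excluded (no dispersion to speak of), mirroring standard practice.
#'
#' @param lots Per-lot data frame with `orchard_id`, `week`, `fruit_count`,
#'   `infested_count`.
#' @param weeks Optional vector of weeks to restrict to.
#' @param min_infested Minimum infested fruit for an orchard to be fitted
#'   (default 2).
#' @return Data frame with one row per fitted orchard: `orchard_id`,
#'   `n_lots`, `total_infested`, `distribution`, `statistic`, `df`,
#'   `p_value`. Excluded orchards are listed in attribute `"excluded"`.
#' @export
dispersion_table <- function(lots, weeks = NULL, min_infested = 2L) {
  stop_if_missing_cols(lots, c("orchard_id", "week", "fruit_count", "infested_count"),
                       "lots")
  if (!is.null(weeks)) lots <- lots[lots$week %in% weeks, , drop = FALSE]
  if (nrow(lots) == 0L) stop("no lots in the selected weeks", call. = FALSE)
  excluded <- character(0)
  rows <- lapply(split(lots, lots$orchard_id), function(lo) {
    tot <- sum(lo$infested_count)
    if (tot < min_infested || nrow(lo) < 2L) {
      excluded <<- c(excluded, lo$orchard_id[1L])
      return(NULL)
    }
    v <- classify_dispersion(lo)
    data.frame(orchard_id = lo$orchard_id[1L], n_lots = nrow(lo),
               total_infested = tot, distribution = v$distribution,
               statistic = v$statistic, df = v$df, p_value = v$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(orchard_id = character(0), n_lots = integer(0),
                      total_infested = integer(0), distribution = character(0),
                      statistic = numeric(0), df = integer(0), p_value = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Time trend of infestation across the season
#'
#' Negative-binomial regression of per-lot infested counts on week, with
#' log fruit count as offset and orchard as a fixed effect when several
#' orchards are present. The week slope is tested with a Wald chi-squared
#' statistic (df 1); `weekly_change` is the multiplicative change in
#' infestation per additional week (e.g. 0.87 for a 13\% weekly decline).
#' Falls back to a Poisson fit (reported in `family`) when the
#' negative-binomial shape sits at its Poisson boundary.
#'
#' @param lots Per-lot data frame with `orchard_id`, `week`, `fruit_count`,
#'   `infested_count`, spanning at least 3 distinct weeks.
#' @return An object of class `trend_fit`: list with `slope` (log scale),
#'   `se`, `weekly_change`, `statistic` (Wald X^2), `df`, `p_value`,
#'   `family`, and the underlying `fit`.
#' @export
trend_test <- function(lots) {
  stop_if_missing_cols(lots, c("orchard_id", "week", "fruit_count", "infested_count"),
                       "lots")
  if (length(unique(lots$week)) < 3L) {
    stop("need at least 3 distinct weeks for a trend", call. = FALSE)
  }
  lots <- lots[lots$fruit_count > 0, , drop = FALSE]
  multi <- length(unique(lots$orchard_id)) > 1L
  fml <- if (multi) {
    infested_count ~ week + factor(orchard_id) + offset(log(fruit_count))
  } else {
    infested_count ~ week + offset(log(fruit_count))
  }
  pois <- suppressWarnings(stats::glm(fml, family = stats::poisson(), data = lots))
  nb <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = lots)),
                 error = function(e) NULL)
  use_nb <- !is.null(nb) &&
    as.numeric(stats::logLik(nb)) >= as.numeric(stats::logLik(pois))
  fit <- if (use_nb) nb else pois
  sm <- summary(fit)$coefficients
  est <- sm["week", "Estimate"]
  se <- sm["week", "Std. Error"]
  x2 <- (est / se)^2
  structure(
    list(slope = est, se = se, weekly_change = exp(est),
         statistic = x2, df = 1L,
         p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE),
         family = if (use_nb) "negbin" else "poisson",
         theta = if (use_nb) nb$theta else Inf,
         fit = fit),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend (%s): weekly change x%.3f (slope %.4f +/- %.4f), X^2 = %.2f, df = %d, p = %.4g\n",
              x$family, x$weekly_change, x$slope, x$se, x$statistic, x$df,
              x$p_value))
  invisible(x)
}
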
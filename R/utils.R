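# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL means "use the ambient stream"
# so that pipeline drivers can seed once at the top.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Nearest-integer rounding with ties going up (239.5 -> 240), as opposed to
# base round()'s round-half-to-even.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
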
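# Internal helpers: error signalling and seeded evaluation.

abort_covalid <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "covalid_error"), ...)
}

abort_validation <- function(msg, ...) {
  abort_covalid(msg, class = c("covalid_validation_error"), ...)
}

abort_no_cases <- function(msg, ...) {
  abort_covalid(msg, class = c("covalid_no_available_cases", "covalid_validation_error"),
                ...)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_covalid(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = c("covalid_missing_column", "covalid_validation_error")
    )
  }
  invisible(df)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("`seed` must be a single non-missing integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` reproducible child seeds from one root seed, so independent
# generators draw from non-overlapping streams.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rater_groups <- function() c("patient", "proxy", "hcp")
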
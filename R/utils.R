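# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so no function in the package leaks global random
#' state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# stable short hash of an R object (used to stamp pipeline artifacts)
config_hash <- function(x) {
  rlang::hash(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse ISO dates; anything that does not resolve to a real calendar day -> NA
parse_iso_date <- function(x) {
  suppressWarnings(data.table::as.IDate(as.character(x), format = "%Y-%m-%d"))
}

as_idate <- function(x) data.table::as.IDate(x)

# age in years at `date` given `birth_date`; a year is 365.25 days
age_years <- function(birth_date, date) {
  as.numeric(as_idate(date) - as_idate(birth_date)) / 365.25
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
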
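# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators never disturb user-level randomness.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# numeric formatting used for every file the package writes; fixed so that
# identical inputs always produce byte-identical output
fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- ""
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# strict numeric parse: NA on anything non-numeric rather than a coercion
# warning, so callers can raise their own positioned errors
parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}
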
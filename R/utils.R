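# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the reporting convention used
#' throughout the package is the spreadsheet-style "round half up", so that
#' e.g. `100 * 1139 / 1816` prints as `62.7`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, reporting convention
#'
#' @param count numerator count(s).
#' @param n denominator (group size).
#' @param digits decimal places kept (default 1, the convention used in all
#'   summary exports).
#' @return numeric percentage(s) on the 0-100 scale.
#' @examples
#' percent_of(1139, 1816) # 62.7
#' @export
percent_of <- function(count, n, digits = 1) {
  stopifnot(is.numeric(count), is.numeric(n), all(n > 0))
  round_half_up(100 * count / n, digits)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Seeds are always explicit arguments in this package; no function touches
# global RNG state permanently.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_ncp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

LINEAGES <- c("tracheophyte", "vertebrate")
CATEGORIES <- c("material", "non_material", "regulating")
SOURCES <- c("references", "expert", "analytics")
PLANT_SUBGROUPS <- c("angiosperm", "pinophyte", "lycopodiophyte", "pteridophyte")
ANIMAL_SUBGROUPS <- c("bird", "mammal", "amphibian", "reptile")
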
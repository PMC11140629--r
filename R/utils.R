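#' @importFrom stats plogis qlogis rnorm runif rbinom rlnorm qnorm var sd
#' @importFrom tibble tibble as_tibble
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Tri-state conjunction
#'
#' Combines a logical vector (with NAs meaning "not evaluable") into a single
#' tri-state value: `FALSE` wins over `NA`, which wins over `TRUE`. Used to
#' aggregate per-visit conditions into a sustained-status flag: one definite
#' failure anywhere settles the outcome even when other visits are missing.
#'
#' @param x logical vector, possibly with NAs.
#' @param empty value to return for a zero-length vector (default `NA`).
#' @return a single logical value (`TRUE`, `FALSE` or `NA`).
#' @export
tri_all <- function(x, empty = NA) {
  if (length(x) == 0L) return(empty)
  if (any(!x, na.rm = TRUE)) return(FALSE)
  if (anyNA(x)) return(NA)
  TRUE
}

#' Tri-state disjunction
#'
#' `TRUE` wins over `NA`, which wins over `FALSE`.
#'
#' @inheritParams tri_all
#' @return a single logical value.
#' @export
tri_any <- function(x, empty = NA) {
  if (length(x) == 0L) return(empty)
  if (any(x, na.rm = TRUE)) return(TRUE)
  if (anyNA(x)) return(NA)
  FALSE
}

## tri-state AND of two vectors, elementwise (FALSE dominates NA)
tri_and <- function(a, b) {
  out <- a & b
  out[which(a %in% FALSE | b %in% FALSE)] <- FALSE
  out
}

## stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

## truncated normal draw by inverse CDF (vectorised, deterministic under seed)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## draw k substream seeds (< 2^31) from a master seed
substream_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
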
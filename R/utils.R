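## Small internal helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a proportion as a percentage string, truncated to two decimals
#'
#' Percentages are truncated (floored) at the second decimal, the convention
#' used by the summary tables this package mirrors: 875/2554 prints as
#' \code{"34.25\%"} (not 34.26), 360/2554 as \code{"14.09\%"}.  Undefined
#' ratios (0/0, \code{NA}) print as \code{"-"}.
#'
#' @param x numeric vector of proportions in \[0, 1\] (e.g. 0.3425).
#' @return character vector like \code{"34.25\%"}.
#' @examples
#' formatPercent(875 / 2554)  # "34.25%"
#' @export
formatPercent <- function(x) {
  out <- rep("-", length(x))
  ok <- is.finite(x)
  ## small epsilon guards against 0.35 * 10000 = 3499.999... artefacts
  out[ok] <- sprintf("%.2f%%", floor(x[ok] * 10000 + 1e-9) / 100)
  out
}

## Truncated percentage as a bare number (34.25), same convention as
## formatPercent(); NA for undefined ratios.
truncPercent <- function(x) {
  ifelse(is.finite(x), floor(x * 10000 + 1e-9) / 100, NA_real_)
}

## Deterministic sub-stream seed for stage k of a run seeded with `seed`.
## Distinct k give distinct seeds; result always a valid 32-bit seed.
subSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 + k * 48271 + 11) %% 2147483629) + 1L
}

## Polynomial rolling hash of a character vector, as 8 hex digits.  Used only
## to fingerprint configurations in run manifests.
textHash <- function(txt) {
  bytes <- as.double(charToRaw(paste(txt, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## stopifnot() with a formatted message
assertThat <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
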
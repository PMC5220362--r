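#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim phyper rbinom rexp rlnorm rpois runif setNames
#'   wilcox.test cor.test median quantile approx
#' @importFrom utils read.delim write.table combn head tail
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical unordered pair key
#'
#' Builds a deterministic "a|b" key with the two ids sorted, so that a pair
#' of gene families can be used as a set element regardless of order.
#'
#' @param a,b character vectors of family ids (recycled to common length).
#' @return character vector of keys.
#' @keywords internal
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}

## positive modulo, works on doubles (bp coordinates)
pmod <- function(x, m) ((x %% m) + m) %% m
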
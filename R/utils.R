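## Internal helpers shared across modules.

## Genotype codes used throughout the package:
##   0 = hom_a, 1 = het, 2 = hom_b, NA = missing.
GENO_HOM_A <- 0L
GENO_HET <- 1L
GENO_HOM_B <- 2L

#' Interval size in megabases, display convention
#'
#' Physical intervals are 1-based inclusive, so a block bounded by its first
#' and last SNP spans `end_bp - start_bp + 1` bases. Sizes are displayed in
#' Mb rounded half-up to 2 decimals (base `round()` rounds half to even,
#' which does not reproduce published block sizes such as 2.09 Mb for
#' 46,893,645-48,980,899).
#'
#' @param start_bp,end_bp 1-based inclusive positions of the first and last
#'   marker of the interval.
#' @return Numeric size in Mb, rounded half-up to 2 decimals.
#' @examples
#' interval_size_mb(46893645, 48980899)  # 2.09
#' @export
interval_size_mb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp >= start_bp))
  round_half_up((end_bp - start_bp + 1) / 1e6, 2L)
}

round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Maximal runs of TRUE in a logical vector -> two-column matrix (start, end).
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
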
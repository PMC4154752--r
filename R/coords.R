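#' Coordinate conventions
#'
#' All coordinates inside the package are 0-based half-open (`[start, end)`),
#' the convention of BED and PAF. GFF3 and NUCmer show-coords output are
#' 1-based inclusive; the two converters below are the only places where the
#' conversion happens, so every reader/writer funnels through them.
#'
#' @param start0,end0 0-based half-open interval bounds.
#' @param start1,end1 1-based inclusive interval bounds.
#' @return A two-column data frame with the converted bounds.
#' @name coords
NULL

#' @rdname coords
#' @export
zero_to_one_based <- function(start0, end0) {
  stopifnot(all(end0 > start0))
  data.frame(start = start0 + 1L, end = end0)
}

#' @rdname coords
#' @export
one_to_zero_based <- function(start1, end1) {
  stopifnot(all(end1 >= start1), all(start1 >= 1L))
  data.frame(start = start1 - 1L, end = end1)
}

# IRanges is 1-based inclusive; helpers to move a 0-based half-open
# (start, end) data frame in and out of it.
as_iranges0 <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

iranges_to_df0 <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}
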
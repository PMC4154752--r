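#' Alignment blocks
#'
#' An alignment block is one local contig-to-reference alignment: the unit all
#' placement, gap, and assessment computations consume. Blocks are stored as an
#' ordinary data frame with a fixed column set so they can be filtered and
#' split with base R; coordinates are 0-based half-open on both sequences and
#' reverse-strand reference intervals are stored in forward orientation with a
#' strand flag.
#'
#' @param contig_id,ref_id Character labels.
#' @param contig_start,contig_end,ref_start,ref_end Integer 0-based half-open
#'   bounds; `contig_start < contig_end` on the forward contig strand.
#' @param strand `"+"` or `"-"`.
#' @param identity Fraction of matching bases in `[0, 1]`.
#' @return A data frame of class `alignment_blocks` with one row per block and
#'   an `aligned_length` column equal to `ref_end - ref_start`.
#' @export
alignment_blocks <- function(contig_id, contig_start, contig_end,
                             ref_id, ref_start, ref_end,
                             strand = "+", identity = 1) {
  df <- data.frame(
    contig_id = as.character(contig_id),
    contig_start = as.integer(contig_start),
    contig_end = as.integer(contig_end),
    ref_id = as.character(ref_id),
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    strand = as.character(strand),
    identity = as.numeric(identity),
    stringsAsFactors = FALSE
  )
  df$aligned_length <- df$ref_end - df$ref_start
  validate_blocks(df)
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

validate_blocks <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$aligned_length <= 0L)) {
    stop("alignment blocks must have ref_end > ref_start")
  }
  if (any(df$contig_end <= df$contig_start)) {
    stop("alignment blocks must have contig_end > contig_start")
  }
  if (any(df$identity < 0 | df$identity > 1)) {
    stop("identity must lie in [0, 1]")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(df)
}

empty_blocks <- function() {
  alignment_blocks(character(), integer(), integer(),
                   character(), integer(), integer(),
                   character(), numeric())
}
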
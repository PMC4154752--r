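#' Select the best placement of one contig on the reference
#'
#' Mirrors delta-filter's best-query mapping: among all local alignment
#' blocks of a contig, selects the subset that is non-overlapping in contig
#' coordinates (pairwise overlap at most `overlap_tolerance` bases, to absorb
#' alignment-end jitter) and maximizes the identity-weighted aligned length
#' `sum(identity * aligned_length)`. Solved exactly by weighted interval
#' scheduling after shrinking every contig interval by half the tolerance at
#' each end: two blocks overlap by more than the tolerance exactly when
#' their shrunk intervals still overlap, so compatible chains are chains of
#' disjoint shrunk intervals. Blocks whose contig span is at most the
#' tolerance shrink away entirely; they are compatible with every other
#' block and always selected. Ties are broken by fewer blocks, then leftmost
#' reference start, then lexicographic `ref_id`.
#'
#' Reference-side overlaps between selected blocks are allowed (the chain is
#' constrained on the contig only), matching best-query filtering.
#'
#' @param blocks [alignment_blocks()] all sharing one `contig_id`.
#' @param overlap_tolerance Maximum tolerated pairwise overlap in contig
#'   coordinates (bases).
#' @return A `contig_placement` list: `contig_id`, `blocks` (chain sorted by
#'   contig coordinate) and `score`.
#' @export
best_placement <- function(blocks, overlap_tolerance = 50L) {
  if (nrow(blocks) == 0L) {
    out <- list(contig_id = NA_character_, blocks = blocks, score = 0)
    class(out) <- "contig_placement"
    return(out)
  }
  if (length(unique(blocks$contig_id)) != 1L) {
    stop("best_placement expects blocks of a single contig")
  }
  w_all <- blocks$identity * blocks$aligned_length
  span <- blocks$contig_end - blocks$contig_start
  free <- which(span <= overlap_tolerance)
  long <- which(span > overlap_tolerance)
  # doubled coordinates keep the half-tolerance shrink integral
  s <- 2L * blocks$contig_start[long] + overlap_tolerance
  e <- 2L * blocks$contig_end[long] - overlap_tolerance
  w <- w_all[long]
  ord <- order(e, s)
  s <- s[ord]; e <- e[ord]; w <- w[ord]
  n <- length(w)
  # dp[i]: best over blocks 1..i; track chosen set
  best_score <- numeric(n + 1L)
  best_n <- integer(n + 1L)
  best_set <- vector("list", n + 1L)
  best_set[[1L]] <- integer(0)
  for (i in seq_len(n)) {
    # predecessor: rightmost j with e[j] <= s[i]
    p <- 0L
    for (j in seq_len(i - 1L)) if (e[j] <= s[i]) p <- j
    # candidates: skip block i, or take block i on top of best up to p
    sc_skip <- best_score[i]; n_skip <- best_n[i]
    sc_take <- best_score[p + 1L] + w[i]; n_take <- best_n[p + 1L] + 1L
    take <- sc_take > sc_skip + 1e-12 ||
      (abs(sc_take - sc_skip) <= 1e-12 && n_take < n_skip)
    if (take) {
      best_score[i + 1L] <- sc_take
      best_n[i + 1L] <- n_take
      best_set[[i + 1L]] <- c(best_set[[p + 1L]], i)
    } else {
      best_score[i + 1L] <- sc_skip
      best_n[i + 1L] <- n_skip
      best_set[[i + 1L]] <- best_set[[i]]
    }
  }
  sel <- c(long[ord[best_set[[n + 1L]]]], free)
  chain <- blocks[sel, , drop = FALSE]
  chain <- chain[order(chain$contig_start, chain$ref_id, chain$ref_start), ,
                 drop = FALSE]
  rownames(chain) <- NULL
  out <- list(contig_id = blocks$contig_id[1],
              blocks = chain,
              score = sum(chain$identity * chain$aligned_length))
  class(out) <- "contig_placement"
  out
}

#' Best placement for every contig in a block table
#'
#' @param blocks [alignment_blocks()] for any number of contigs.
#' @param overlap_tolerance Passed to [best_placement()].
#' @return Named list of `contig_placement` objects.
#' @export
best_placements <- function(blocks, overlap_tolerance = 50L) {
  split_blocks <- split(seq_len(nrow(blocks)), blocks$contig_id)
  out <- lapply(split_blocks, function(i) {
    best_placement(blocks[i, , drop = FALSE], overlap_tolerance)
  })
  out[order(names(out))]
}

#' @export
print.contig_placement <- function(x, ...) {
  cat(sprintf("contig_placement: %s, %d block(s), score %.1f\n",
              x$contig_id, nrow(x$blocks), x$score))
  invisible(x)
}

#' High-stringency alignment filter
#'
#' Keeps blocks with identity at or above `min_identity` and aligned length
#' at or above `min_len` (both bounds inclusive). Placements left without
#' blocks are dropped; their contig ids are reported in the `dropped`
#' attribute.
#'
#' @param placements List of `contig_placement` objects.
#' @param min_identity Minimum block identity (default 0.99).
#' @param min_len Minimum aligned length in bases (default 1000).
#' @return Filtered placement list.
#' @export
stringent_filter <- function(placements, min_identity = 0.99, min_len = 1000L) {
  dropped <- character(0)
  out <- list()
  for (p in placements) {
    keep <- p$blocks$identity >= min_identity &
      p$blocks$aligned_length >= min_len
    if (!any(keep)) {
      dropped <- c(dropped, p$contig_id)
      next
    }
    p$blocks <- p$blocks[keep, , drop = FALSE]
    rownames(p$blocks) <- NULL
    p$score <- sum(p$blocks$identity * p$blocks$aligned_length)
    out[[p$contig_id]] <- p
  }
  attr(out, "dropped") <- dropped
  out
}

placement_blocks <- function(placements) {
  if (inherits(placements, "contig_placement")) placements <- list(placements)
  dfs <- lapply(placements, `[[`, "blocks")
  df <- do.call(rbind, dfs)
  if (is.null(df)) empty_blocks() else df
}

#' Genome fraction, duplication ratio, and per-scaffold coverage summary
#'
#' Genome fraction is the proportion of reference bases covered by at least
#' one selected block; duplication ratio is total aligned block bases over
#' covered reference bases. The per-scaffold table counts aligned contigs,
#' alignment gaps (maximal uncovered intervals, terminal ones included),
#' aligned bases and percent aligned.
#'
#' @param placements List of `contig_placement` objects (or raw
#'   [alignment_blocks()]).
#' @param ref_lengths Named integer vector of reference sequence lengths.
#' @return List with `genome_fraction`, `duplication_ratio`, `per_ref`.
#' @export
genome_fraction_and_duplication <- function(placements, ref_lengths) {
  blocks <- if (is.data.frame(placements)) placements else
    placement_blocks(placements)
  if (nrow(blocks) > 0) {
    missing_ref <- setdiff(blocks$ref_id, names(ref_lengths))
    if (length(missing_ref) > 0) {
      stop("ref_lengths missing for: ", paste(missing_ref, collapse = ", "))
    }
    if (any(blocks$ref_end > ref_lengths[blocks$ref_id])) {
      stop("alignment block extends beyond reference length")
    }
  }
  per_ref <- lapply(names(ref_lengths), function(ref) {
    b <- blocks[blocks$ref_id == ref, , drop = FALSE]
    len <- ref_lengths[[ref]]
    if (nrow(b) == 0) {
      return(data.frame(ref_id = ref, aligned_contigs = 0L, gaps = 1L,
                        aligned_bases = 0L, covered_bases = 0L,
                        percent_aligned = 0))
    }
    covered_ir <- IRanges::reduce(as_iranges0(b$ref_start, b$ref_end))
    covered <- sum(BiocGenerics::width(covered_ir))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), covered_ir)
    data.frame(
      ref_id = ref,
      aligned_contigs = length(unique(b$contig_id)),
      gaps = length(gaps),
      aligned_bases = sum(b$aligned_length),
      covered_bases = covered,
      percent_aligned = 100 * covered / len
    )
  })
  per_ref <- do.call(rbind, per_ref)
  covered_total <- sum(per_ref$covered_bases)
  list(
    genome_fraction = covered_total / sum(ref_lengths),
    duplication_ratio = if (covered_total > 0)
      sum(per_ref$aligned_bases) / covered_total else NA_real_,
    per_ref = per_ref
  )
}
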
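#' Coverage-gap-limited pseudo-assembly
#'
#' Simulates the contiguity an assembler could achieve if coverage gaps were
#' the only limitation: read placements on the reference merge into the same
#' pseudo-contig when their intervals overlap by at least `min_overlap`
#' bases (transitively closed), and merged regions shorter than `min_len`
#' are discarded. Both thresholds are inclusive ("at least"). Reported
#' intervals are the union spans of the merged reads.
#'
#' @param read_placements Data frame with `ref_id`, `start`, `end` (0-based
#'   half-open), e.g. the `ref_start`/`ref_end` columns of a read alignment
#'   table.
#' @param min_overlap Minimum pairwise overlap to merge (default 800).
#' @param min_len Minimum retained region length (default 1000).
#' @return Data frame of pseudo-contigs: `ref_id`, `start`, `end`, `length`,
#'   `n_reads`.
#' @export
pseudo_assemble <- function(read_placements, min_overlap = 800L,
                            min_len = 1000L) {
  df <- normalize_intervals(read_placements)
  if (any(df$end < df$start)) stop("negative-length interval")
  if (nrow(df) == 0L) {
    return(data.frame(ref_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_reads = integer()))
  }
  out <- lapply(split(df, df$ref_id), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    n <- nrow(d)
    cl_start <- numeric(0); cl_end <- numeric(0); cl_n <- integer(0)
    alive <- logical(0)
    open <- integer(0)  # indices of clusters still reachable by later reads
    for (i in seq_len(n)) {
      s <- d$start[i]; e <- d$end[i]
      # with starts sorted, overlap(j, i) = min(end_j, end_i) - start_i, so a
      # read joins every cluster holding a read whose end reaches
      # s + min_overlap, provided its own end does too
      joins <- if (e - s >= min_overlap) {
        open[cl_end[open] >= s + min_overlap]
      } else integer(0)
      if (length(joins) == 0L) {
        cl_start <- c(cl_start, s); cl_end <- c(cl_end, e)
        cl_n <- c(cl_n, 1L); alive <- c(alive, TRUE)
        open <- c(open, length(cl_start))
      } else {
        tgt <- joins[1]
        cl_start[tgt] <- min(cl_start[joins], s)
        cl_end[tgt] <- max(cl_end[joins], e)
        cl_n[tgt] <- sum(cl_n[joins]) + 1L
        alive[joins[-1]] <- FALSE
        open <- setdiff(open, joins[-1])
      }
      # later reads start at >= s, so clusters ending before s + min_overlap
      # can never be joined again
      open <- open[cl_end[open] >= s + min_overlap]
    }
    res <- data.frame(ref_id = d$ref_id[1], start = cl_start[alive],
                      end = cl_end[alive], n_reads = cl_n[alive],
                      stringsAsFactors = FALSE)
    res$length <- res$end - res$start
    res[res$length >= min_len, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$ref_id, out$start), c("ref_id", "start", "end", "length",
                                      "n_reads")]
}

normalize_intervals <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("ref_start", "ref_end") %in% names(x))) {
      data.frame(ref_id = x$ref_id, start = x$ref_start, end = x$ref_end,
                 stringsAsFactors = FALSE)
    } else {
      stopifnot(all(c("ref_id", "start", "end") %in% names(x)))
      x[c("ref_id", "start", "end")]
    }
  } else {
    stop("expected a data frame of intervals")
  }
}

#' Alignment gaps: uncovered reference intervals
#'
#' The per-scaffold complement of the covered intervals, terminal gaps
#' included.
#'
#' @param covered Data frame of covered intervals (`ref_id`, `start`, `end`,
#'   or a placement list / alignment blocks).
#' @param ref_lengths Named integer vector of scaffold lengths.
#' @return Data frame of gaps: `ref_id`, `start`, `end`, `length`.
#' @export
alignment_gaps <- function(covered, ref_lengths) {
  if (inherits(covered, "contig_placement") ||
      (is.list(covered) && !is.data.frame(covered))) {
    covered <- placement_blocks(covered)
  }
  df <- normalize_intervals(covered)
  out <- lapply(names(ref_lengths), function(ref) {
    d <- df[df$ref_id == ref, , drop = FALSE]
    full <- IRanges::IRanges(1L, ref_lengths[[ref]])
    cov <- if (nrow(d)) IRanges::reduce(as_iranges0(d$start, d$end)) else
      IRanges::IRanges()
    g <- iranges_to_df0(IRanges::setdiff(full, cov))
    if (nrow(g) == 0) return(NULL)
    data.frame(ref_id = ref, start = g$start, end = g$end,
               length = g$end - g$start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), start = integer(),
                      end = integer(), length = integer())
  }
  rownames(out) <- NULL
  out
}

#' Characterize gap content: GC, repeat classes, TE-family overlap
#'
#' Computes per-gap GC content from the reference sequence, the fraction of
#' total gap bases overlapped by each annotation class (classes are computed
#' independently, so fractions can sum above 1 when annotations overlap),
#' the number of TE copies per family intersecting at least one gap, and —
#' when a second gap set is supplied — the fraction of gaps explained by it
#' (>= 1 bp intersection).
#'
#' @param gaps Data frame `ref_id`, `start`, `end`.
#' @param genome A `genome_bundle` or DNAStringSet of reference sequences.
#' @param annotations Data frame with `ref_id`, `start`, `end`, `class`
#'   (one of `TE`, `satellite`, `simple`, `low_complexity`) and `family`
#'   (for TEs). Defaults to the bundle's TE annotations when `genome` is a
#'   bundle.
#' @param explained_by Optional second interval set (e.g. coverage gaps):
#'   the fraction of `gaps` intersecting it is reported.
#' @return List with `gc_per_gap`, `mean_gc`, `fraction_by_class`,
#'   `te_family_gap_counts`, and `fraction_gaps_explained_by_coverage` when
#'   `explained_by` is given.
#' @export
gap_content <- function(gaps, genome, annotations = NULL,
                        explained_by = NULL) {
  seqs <- if (inherits(genome, "genome_bundle")) genome$seqs else genome
  if (is.null(annotations)) {
    if (!inherits(genome, "genome_bundle")) {
      stop("annotations required when genome is not a genome_bundle")
    }
    annotations <- data.frame(
      ref_id = genome$tes$ref_id, start = genome$tes$start,
      end = genome$tes$end, class = "TE", family = genome$tes$family,
      stringsAsFactors = FALSE
    )
  }
  known <- c("TE", "satellite", "simple", "low_complexity")
  if (!all(annotations$class %in% known)) {
    stop("unknown annotation class: ",
         paste(setdiff(unique(annotations$class), known), collapse = ", "))
  }
  gc_per_gap <- vapply(seq_len(nrow(gaps)), function(i) {
    v <- Biostrings::Views(seqs[[gaps$ref_id[i]]],
                           gaps$start[i] + 1L, gaps$end[i])
    Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[1, 1]
  }, 0)
  gap_len <- gaps$end - gaps$start
  mean_gc <- if (sum(gap_len) > 0)
    sum(gc_per_gap * gap_len) / sum(gap_len) else NA_real_

  gap_gr <- GenomicRanges::GRanges(gaps$ref_id,
                                   as_iranges0(gaps$start, gaps$end))
  ann_gr <- GenomicRanges::GRanges(annotations$ref_id,
                                   as_iranges0(annotations$start,
                                               annotations$end))
  fraction_by_class <- vapply(known, function(cl) {
    a <- IRanges::reduce(ann_gr[annotations$class == cl])
    if (length(a) == 0) return(0)
    ov <- GenomicRanges::intersect(gap_gr, a, ignore.strand = TRUE)
    sum(BiocGenerics::width(ov)) / sum(gap_len)
  }, 0)

  te <- annotations[annotations$class == "TE", , drop = FALSE]
  te_family_gap_counts <- if (nrow(te) > 0) {
    te_gr <- GenomicRanges::GRanges(te$ref_id, as_iranges0(te$start, te$end))
    hit <- GenomicRanges::countOverlaps(te_gr, gap_gr) > 0
    counts <- tapply(hit, te$family, sum)
    data.frame(family = names(counts), copies_overlapping_gaps = as.integer(counts),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(), copies_overlapping_gaps = integer())
  }

  out <- list(gc_per_gap = gc_per_gap, mean_gc = mean_gc,
              fraction_by_class = fraction_by_class,
              te_family_gap_counts = te_family_gap_counts)
  if (!is.null(explained_by)) {
    b <- normalize_intervals(explained_by)
    b_gr <- GenomicRanges::GRanges(b$ref_id, as_iranges0(b$start, b$end))
    out$fraction_gaps_explained_by_coverage <-
      mean(GenomicRanges::countOverlaps(gap_gr, b_gr) > 0)
    out$n_gaps_explained <-
      sum(GenomicRanges::countOverlaps(gap_gr, b_gr) > 0)
  }
  out
}
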
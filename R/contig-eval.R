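#' N(x)/L(x) contiguity metrics
#'
#' `N_x` is the length of the first contig (descending order) at which the
#' cumulative length reaches `x` percent of the total assembly length (or of
#' `genome_size` when given, yielding NG/LG); `L_x` is that contig's 1-based
#' rank. When the cumulative length never reaches the threshold (small
#' assembly against a large genome size), `N_x` is 0 and `L_x` the contig
#' count, flagged with `reached = FALSE`.
#'
#' @param lengths Positive contig lengths.
#' @param x Percentage in `(0, 100]` (default 50).
#' @param genome_size Optional reference size in bases for NG/LG metrics.
#' @return List with `N`, `L` and `reached`.
#' @export
nx_metrics <- function(lengths, x = 50, genome_size = NULL) {
  stopifnot(length(lengths) > 0, all(lengths > 0), x > 0, x <= 100)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  target <- (x / 100) * if (is.null(genome_size)) sum(lengths) else genome_size
  cum <- cumsum(lengths)
  idx <- which(cum >= target)
  if (length(idx) == 0L) {
    return(list(N = 0, L = length(lengths), reached = FALSE))
  }
  list(N = lengths[idx[1]], L = idx[1], reached = TRUE)
}

#' Assembly size metrics table
#'
#' Basic size statistics plus the N50/NG50 family for a set of contigs, the
#' assembly analogue of a QUAST summary.
#'
#' @param contigs DNAStringSet of contigs (or numeric lengths).
#' @param genome_size Optional genome size for NG/LG metrics.
#' @return List of metrics.
#' @export
assembly_metrics <- function(contigs, genome_size = NULL) {
  if (inherits(contigs, "DNAStringSet")) {
    lengths <- Biostrings::width(contigs)
    gc <- sum(Biostrings::letterFrequency(contigs, "GC")) / sum(lengths)
  } else {
    lengths <- as.numeric(contigs)
    gc <- NA_real_
  }
  n50 <- nx_metrics(lengths, 50)
  out <- list(
    n_contigs = length(lengths),
    total_size = sum(lengths),
    longest = max(lengths),
    shortest = min(lengths),
    mean = mean(lengths),
    median = stats::median(lengths),
    gc_content = gc,
    N50 = n50$N, L50 = n50$L
  )
  if (!is.null(genome_size)) {
    ng50 <- nx_metrics(lengths, 50, genome_size)
    out$NG50 <- ng50$N
    out$LG50 <- ng50$L
  }
  out
}

#' Detect misassembly breakpoints in a contig placement
#'
#' Classifies each junction between adjacent blocks of a contig's placement
#' chain: different reference sequences give a translocation; same reference
#' with opposite strands an inversion; same reference and strand with a
#' reference-vs-contig gap inconsistency above `inconsistency_threshold`
#' bases, or reference order contradicting contig order, a relocation.
#' The aligned lengths of the chain pieces obtained by breaking at every
#' event are returned as input to NA50-style metrics.
#'
#' @param placement A `contig_placement`.
#' @param inconsistency_threshold Bases (default 1000, the usual QUAST
#'   convention).
#' @return List with `events` (data frame) and `broken_lengths`.
#' @export
detect_misassemblies <- function(placement, inconsistency_threshold = 1000L) {
  b <- placement$blocks
  events <- list()
  breakpoints <- integer(0)
  if (nrow(b) >= 2L) {
    for (i in seq_len(nrow(b) - 1L)) {
      l <- b[i, ]; r <- b[i + 1L, ]
      kind <- NA_character_
      inconsistency <- NA_real_
      if (l$ref_id != r$ref_id) {
        kind <- "translocation"
      } else if (l$strand != r$strand) {
        kind <- "inversion"
      } else {
        contig_gap <- r$contig_start - l$contig_end
        ref_gap <- if (l$strand == "+") r$ref_start - l$ref_end else
          l$ref_start - r$ref_end
        inconsistency <- ref_gap - contig_gap
        if (abs(inconsistency) > inconsistency_threshold) kind <- "relocation"
      }
      if (!is.na(kind)) {
        breakpoints <- c(breakpoints, i)
        events[[length(events) + 1L]] <- data.frame(
          contig_id = placement$contig_id, kind = kind,
          left_block = i, right_block = i + 1L,
          contig_pos = l$contig_end,
          inconsistency = inconsistency,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  broken_lengths <- if (nrow(b) > 0) {
    piece_of <- cumsum(c(0L, seq_len(nrow(b) - 1L) %in% breakpoints)) + 1L
    as.numeric(tapply(b$aligned_length, piece_of, sum))
  } else numeric(0)
  list(
    events = if (length(events)) do.call(rbind, events) else
      data.frame(contig_id = character(), kind = character(),
                 left_block = integer(), right_block = integer(),
                 contig_pos = integer(), inconsistency = numeric()),
    broken_lengths = broken_lengths
  )
}

#' NA50-style metrics over all placements
#'
#' Breaks every contig chain at detected misassembly events and computes the
#' N(x) metric over the resulting aligned piece lengths.
#'
#' @param placements List of `contig_placement` objects.
#' @param x Percentage (default 50).
#' @param genome_size Optional size for the NGA variant.
#' @param inconsistency_threshold Passed to [detect_misassemblies()].
#' @return List with `N`, `L`, `reached`, `events` and `broken_lengths`.
#' @export
na_metrics <- function(placements, x = 50, genome_size = NULL,
                       inconsistency_threshold = 1000L) {
  res <- lapply(placements, detect_misassemblies, inconsistency_threshold)
  broken <- unlist(lapply(res, `[[`, "broken_lengths"))
  events <- do.call(rbind, lapply(res, `[[`, "events"))
  nx <- nx_metrics(broken, x, genome_size)
  list(N = nx$N, L = nx$L, reached = nx$reached,
       events = events, broken_lengths = broken)
}

#' Mismatches and indels per 100 kbp of aligned sequence
#'
#' Realigns every selected block (global alignment of the block-bounded
#' contig and reference subsequences) and counts mismatch bases and indel
#' events per 100 kbp of aligned reference bases. An indel event is one gap
#' run; runs of at most `short_indel_max` bases are short indels, longer
#' runs long indels.
#'
#' @param placements List of `contig_placement` objects.
#' @param contig_seqs,ref_seqs DNAStringSets holding the contigs and
#'   reference scaffolds named by id.
#' @param short_indel_max Short/long indel boundary in bases (default 5).
#' @return List of per-100-kbp rates plus raw counts.
#' @export
per100kbp_errors <- function(placements, contig_seqs, ref_seqs,
                             short_indel_max = 5L) {
  blocks <- placement_blocks(placements)
  n_mismatch <- 0L; n_short <- 0L; n_long <- 0L
  total_aligned <- 0
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (!b$contig_id %in% names(contig_seqs) ||
        !b$ref_id %in% names(ref_seqs) ||
        b$contig_end > length(contig_seqs[[b$contig_id]]) ||
        b$ref_end > length(ref_seqs[[b$ref_id]])) {
      stop("block coordinates inconsistent with supplied sequences")
    }
    cs <- Biostrings::subseq(contig_seqs[[b$contig_id]],
                             b$contig_start + 1L, b$contig_end)
    if (b$strand == "-") cs <- Biostrings::reverseComplement(cs)
    rs <- Biostrings::subseq(ref_seqs[[b$ref_id]], b$ref_start + 1L, b$ref_end)
    if (length(cs) == length(rs)) {
      # equal lengths: a gap-free comparison is the optimal global alignment
      # under these penalties unless mismatches are pervasive
      n_mismatch <- n_mismatch +
        sum(as.raw(cs) != as.raw(rs))
    } else {
      cnt <- aligned_error_counts(cs, rs, short_indel_max)
      n_mismatch <- n_mismatch + cnt$mismatch
      n_short <- n_short + cnt$short
      n_long <- n_long + cnt$long
    }
    total_aligned <- total_aligned + b$aligned_length
  }
  list(
    mismatches_per_100kbp = 1e5 * n_mismatch / total_aligned,
    short_indels_per_100kbp = 1e5 * n_short / total_aligned,
    long_indels_per_100kbp = 1e5 * n_long / total_aligned,
    mismatches = n_mismatch, short_indels = n_short, long_indels = n_long,
    aligned_bases = total_aligned
  )
}

# Mismatch and gap-run counts from a (tiled) global alignment of two
# sequences of different lengths. Tiles keep the dynamic-programming matrix
# under Biostrings' size limit; a gap run crossing a tile boundary counts as
# two events, a negligible bias at the 20 kbp tile size.
aligned_error_counts <- function(cs, rs, short_indel_max, tile = 20000L) {
  lc <- length(cs); lr <- length(rs)
  n_tiles <- max(1L, ceiling(max(lc, lr) / tile))
  cb <- round(seq(0L, lc, length.out = n_tiles + 1L))
  rb <- round(seq(0L, lr, length.out = n_tiles + 1L))
  mism <- 0L; short <- 0L; long <- 0L
  gap_runs <- function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "-")
    r$lengths[r$values]
  }
  for (t in seq_len(n_tiles)) {
    if (cb[t + 1L] == cb[t] || rb[t + 1L] == rb[t]) {
      long <- long + 1L
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::subseq(cs, cb[t] + 1L, cb[t + 1L]),
      Biostrings::subseq(rs, rb[t] + 1L, rb[t + 1L]),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2
    )
    mism <- mism + Biostrings::nmismatch(aln)
    runs <- c(gap_runs(as.character(Biostrings::alignedPattern(aln))),
              gap_runs(as.character(Biostrings::alignedSubject(aln))))
    short <- short + sum(runs <= short_indel_max)
    long <- long + sum(runs > short_indel_max)
  }
  list(mismatch = mism, short = short, long = long)
}

#' Merge contigs sharing long exact end overlaps into supercontigs
#'
#' Repeatedly merges the pair of contigs with the longest suffix-prefix
#' overlap of at least `min_overlap` bases and at most `max_mismatch`
#' mismatches (reverse-complement orientation included), keeping one copy of
#' the overlap. Ties are resolved by contig id; the greedy order and every
#' merge are logged.
#'
#' @param contigs Named DNAStringSet.
#' @param min_overlap Minimum overlap length in bases (default 1000).
#' @param max_mismatch Maximum mismatches tolerated in the overlap
#'   (default 0: perfect identity).
#' @return List with `contigs` (supercontigs) and `log` (data frame of
#'   merges).
#' @export
merge_end_overlaps <- function(contigs, min_overlap = 1000L,
                               max_mismatch = 0L) {
  stopifnot(length(contigs) > 0)
  seqs <- as.character(contigs)
  log <- list()

  n_mm <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  best_overlap <- function(a, b) {
    # longest suffix of a equal (within max_mismatch) to a prefix of b
    kmax <- min(nchar(a), nchar(b))
    for (k in seq(kmax, min_overlap)) {
      if (n_mm(substr(a, nchar(a) - k + 1L, nchar(a)),
               substr(b, 1L, k)) <= max_mismatch) return(k)
    }
    0L
  }
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))

  repeat {
    ids <- names(seqs)
    if (length(ids) < 2L) break
    best <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        a <- seqs[[i]]
        if (min(nchar(a), nchar(seqs[[j]])) < min_overlap) next
        for (orient in c("+", "-")) {
          b <- if (orient == "+") seqs[[j]] else rc(seqs[[j]])
          k <- best_overlap(a, b)
          if (k >= min_overlap &&
              (is.null(best) || k > best$k ||
               (k == best$k && paste(ids[i], ids[j]) <
                paste(ids[best$i], ids[best$j])))) {
            best <- list(i = i, j = j, k = k, orient = orient, b = b)
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- paste0(seqs[[best$i]],
                     substr(best$b, best$k + 1L, nchar(best$b)))
    new_id <- paste0(ids[best$i], "+", ids[best$j])
    log[[length(log) + 1L]] <- data.frame(
      left = ids[best$i], right = ids[best$j], overlap = best$k,
      orientation = best$orient, supercontig = new_id,
      stringsAsFactors = FALSE
    )
    seqs <- seqs[-c(best$i, best$j)]
    seqs[new_id] <- merged
  }
  out <- Biostrings::DNAStringSet(seqs)
  list(contigs = out,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(left = character(), right = character(),
                    overlap = integer(), orientation = character(),
                    supercontig = character()))
}
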
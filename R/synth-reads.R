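#' Configuration for the synthetic long-read simulator
#'
#' Defaults emulate TruSeq synthetic long-reads: a left-skewed length
#' distribution with a hard 1.5 kbp minimum, mean near 4.4 kbp and a local
#' maximum near 8.5 kbp; per-base mismatch/insertion/deletion rates of
#' 0.0509%/0.0166%/0.0290%; mismatches elevated over the first 100 read
#' bases; and GC-biased start-position sampling (low-GC windows
#' under-sampled).
#'
#' @param min_length Minimum read length in bases.
#' @param modal_length Location of the long-read mode in bases.
#' @param mean_length Target mean read length (informational; the mixture
#'   below is parameterized to approximate it).
#' @param mismatch_rate,insertion_rate,deletion_rate Per-base error rates,
#'   each in `[0, 0.01]`.
#' @param start_mismatch_multiplier Multiplier (>= 1) applied to the mismatch
#'   rate over the first 100 read bases.
#' @param target_depth Fold coverage of the genome to simulate.
#' @param gc_bias_strength Steepness `k` of the logistic start-position
#'   weight `1 / (1 + exp(-k * (GC_500bp - 0.35)))`; 0 disables the bias.
#' @param seed Integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(min_length = 1500L, modal_length = 8500L,
                            mean_length = 4400L,
                            mismatch_rate = 0.000509,
                            insertion_rate = 0.000166,
                            deletion_rate = 0.000290,
                            start_mismatch_multiplier = 1,
                            target_depth = 10,
                            gc_bias_strength = 0,
                            seed = 1L) {
  rates <- c(mismatch_rate, insertion_rate, deletion_rate)
  stopifnot(
    min_length <= modal_length,
    all(rates >= 0), all(rates <= 0.01),
    target_depth > 0,
    start_mismatch_multiplier >= 1
  )
  structure(
    list(min_length = as.integer(min_length),
         modal_length = as.integer(modal_length),
         mean_length = as.integer(mean_length),
         mismatch_rate = mismatch_rate,
         insertion_rate = insertion_rate,
         deletion_rate = deletion_rate,
         start_mismatch_multiplier = start_mismatch_multiplier,
         target_depth = target_depth,
         gc_bias_strength = gc_bias_strength,
         seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

# Read lengths: 75% short log-normal component + 25% long component with
# median 0.9 * modal_length, truncated at min_length by resampling. The
# short component dominates (the empirical distribution is left-skewed with
# mean ~4.4 kbp) while the long component produces the secondary mode.
draw_read_lengths <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    m <- n - length(out)
    long <- stats::runif(m) < 0.25
    len <- numeric(m)
    len[long] <- stats::rlnorm(sum(long), log(0.9 * cfg$modal_length), 0.12)
    len[!long] <- stats::rlnorm(sum(!long), log(2400), 0.45)
    len <- as.integer(round(len))
    out <- c(out, len[len >= cfg$min_length])
  }
  out[seq_len(n)]
}

# Builds the read string and its =/X/I/D operation string from a source
# segment and event offsets (0-based, in read orientation). Deletion events
# sit between read bases and are recorded at the read offset 5' of them.
apply_read_events <- function(seg_chars, mm_off, ins_off, del_off) {
  span <- length(seg_chars)
  ev_off <- c(mm_off, ins_off, del_off)
  if (length(ev_off) == 0L) {
    return(list(read = paste(seg_chars, collapse = ""),
                ops = sprintf("%d=", span)))
  }
  ev_type <- rep(c("X", "I", "D"),
                 c(length(mm_off), length(ins_off), length(del_off)))
  # insertions at an offset happen before that source base; order I before
  # X/D at equal offsets
  o <- order(ev_off, match(ev_type, c("I", "X", "D")))
  events <- list(off = ev_off[o], type = ev_type[o])
  read <- character(0)
  ops_len <- integer(0)
  ops_type <- character(0)
  push <- function(type, len) {
    k <- length(ops_type)
    if (k > 0L && ops_type[k] == type) {
      ops_len[k] <<- ops_len[k] + len
    } else {
      ops_type[k + 1L] <<- type
      ops_len[k + 1L] <<- len
    }
  }
  cur <- 0L  # next unconsumed source offset
  for (i in seq_along(events$off)) {
    o <- events$off[i]
    if (o > cur) {
      read <- c(read, seg_chars[(cur + 1L):o])
      push("=", o - cur)
      cur <- o
    }
    t <- events$type[i]
    if (t == "X") {
      read <- c(read, sample(setdiff(BASES, seg_chars[cur + 1L]), 1L))
      push("X", 1L)
      cur <- cur + 1L
    } else if (t == "I") {
      read <- c(read, sample(BASES, 1L))
      push("I", 1L)
    } else {
      push("D", 1L)
      cur <- cur + 1L
    }
  }
  if (cur < span) {
    read <- c(read, seg_chars[(cur + 1L):span])
    push("=", span - cur)
  }
  list(read = paste(read, collapse = ""),
       ops = paste0(ops_len, ops_type, collapse = ""))
}

#' Simulate synthetic long reads from a genome bundle
#'
#' Draws read lengths from a truncated log-normal mixture, start positions
#' with a logistic GC-bias weight over 500 bp windows, and per-base
#' mismatch/insertion/deletion errors (mismatches elevated over the first
#' 100 bases). Optional heterozygous sites introduce the alternate allele in
#' 50% of overlapping reads, mimicking residual heterozygosity of an inbred
#' line. The true source interval and the exact alignment operations of
#' every read are recorded.
#'
#' @param genome A `genome_bundle`.
#' @param cfg A [read_sim_config()].
#' @param het_sites Optional data frame with columns `ref_id`, `pos`
#'   (0-based) and `alt` (alternate base), e.g. from [plant_het_sites()].
#' @return A `simulated_reads` list with `reads` (DNAStringSet) and
#'   `alignments` (data frame: `read_id`, `ref_id`, `ref_start`, `ref_end`,
#'   `strand`, `mapq`, `ops` with `=XID` run-length operations in read
#'   orientation).
#' @export
simulate_reads <- function(genome, cfg, het_sites = NULL) {
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  seqs <- genome$seqs
  slens <- Biostrings::width(seqs)
  if (max(slens) < cfg$min_length) {
    stop("depth unattainable: no scaffold is as long as min_length")
  }
  genome_len <- sum(slens)

  # GC-weighted 500 bp start windows
  win <- 500L
  wtab <- do.call(rbind, lapply(seq_along(seqs), function(s) {
    n_win <- max(1L, slens[s] %/% win)
    starts <- (seq_len(n_win) - 1L) * win
    ends <- pmin(starts + win, slens[s])
    v <- Biostrings::Views(seqs[[s]], start = starts + 1L, end = ends)
    gc <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
    data.frame(scaffold = s, win_start = starts, win_end = ends, gc = gc)
  }))
  k <- cfg$gc_bias_strength
  wtab$weight <- 1 / (1 + exp(-k * (wtab$gc - 0.35))) *
    (wtab$win_end - wtab$win_start)

  target_bases <- cfg$target_depth * genome_len
  # plain character caches avoid per-read S4 subsequence extraction
  seq_strs <- as.character(seqs)
  rc_strs <- as.character(Biostrings::reverseComplement(seqs))
  reads <- character(0)
  a_ref <- character(0); a_start <- integer(0); a_end <- integer(0)
  a_strand <- character(0); a_ops <- character(0)
  total <- 0
  read_i <- 0L
  batch <- max(100L, ceiling(target_bases / cfg$mean_length / 4))

  while (total < target_bases) {
    lens <- draw_read_lengths(batch, cfg)
    widx <- sample.int(nrow(wtab), batch, replace = TRUE, prob = wtab$weight)
    strands <- sample(c("+", "-"), batch, replace = TRUE)
    h <- pmin(100L, lens)
    n_mm1 <- stats::rbinom(batch, h, min(1, cfg$mismatch_rate * cfg$start_mismatch_multiplier))
    n_mm2 <- stats::rbinom(batch, lens - h, cfg$mismatch_rate)
    n_ins <- stats::rbinom(batch, lens, cfg$insertion_rate)
    n_del <- stats::rbinom(batch, lens, cfg$deletion_rate)
    for (b in seq_len(batch)) {
      if (total >= target_bases) break
      len <- lens[b]
      span <- len + n_del[b] - n_ins[b]
      s <- wtab$scaffold[widx[b]]
      if (span > slens[s] || span < 1L) next
      start <- wtab$win_start[widx[b]] +
        as.integer(floor(stats::runif(1, 0, win)))
      if (start + span > slens[s]) start <- slens[s] - span
      strand <- strands[b]
      seg <- if (strand == "+") {
        substr(seq_strs[[s]], start + 1L, start + span)
      } else {
        # the read is the reverse complement of [start, start+span); on the
        # cached reverse-complement string that is a forward substring
        substr(rc_strs[[s]], slens[s] - start - span + 1L, slens[s] - start)
      }
      seg_chars <- strsplit(seg, "", fixed = TRUE)[[1]]

      # event offsets in read orientation; mismatches and deletions consume
      # distinct source offsets, insertions sit between them
      n_mm <- n_mm1[b] + n_mm2[b]
      mm_del <- integer(0)
      if (n_mm + n_del[b] > 0) {
        n1 <- min(h[b], span)
        pool1 <- seq_len(n1) - 1L
        pool2 <- if (n1 < span) n1:(span - 1L) else integer(0)
        mm1 <- if (n_mm1[b] > 0) sample(pool1, min(n_mm1[b], length(pool1))) else integer(0)
        rest <- if (length(pool2)) sample(pool2, min(n_mm2[b] + n_del[b], length(pool2))) else integer(0)
        mm2 <- utils::head(rest, n_mm2[b])
        del <- utils::tail(rest, max(0L, length(rest) - n_mm2[b]))
        mm_off <- c(mm1, mm2)
        del_off <- del
      } else {
        mm_off <- integer(0); del_off <- integer(0)
      }
      ins_off <- if (n_ins[b] > 0) sample(span + 1L, n_ins[b], replace = TRUE) - 1L else integer(0)

      # residual heterozygosity: alternate allele in 50% of overlapping reads
      if (!is.null(het_sites) && nrow(het_sites) > 0) {
        ref_name <- names(seqs)[s]
        hs <- het_sites[het_sites$ref_id == ref_name &
                        het_sites$pos >= start & het_sites$pos < start + span, ,
                        drop = FALSE]
        if (nrow(hs) > 0) {
          carry <- stats::runif(nrow(hs)) < 0.5
          hs <- hs[carry, , drop = FALSE]
          if (nrow(hs) > 0) {
            off <- hs$pos - start
            alt <- hs$alt
            if (strand == "-") {
              off <- span - 1L - off
              alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[alt])
            }
            keep <- !(off %in% c(mm_off, del_off))
            off <- off[keep]; alt <- alt[keep]
            # plant the alternate allele directly (it differs from ref)
            for (j in seq_along(off)) {
              seg_chars[off[j] + 1L] <- alt[j]
            }
            # record as mismatch runs via a dedicated marker: the base is
            # already substituted, so mark offsets as pre-substituted
            # mismatches (handled below by X events that keep the base)
            mm_off <- c(mm_off, off)
            attr(mm_off, "planted") <- off
          }
        }
      }

      planted <- attr(mm_off, "planted")
      res <- apply_read_events(seg_chars, as.integer(mm_off),
                               as.integer(ins_off), as.integer(del_off))
      # het substitutions were already applied to seg_chars; undo the random
      # re-substitution apply_read_events performed at those offsets
      if (!is.null(planted) && length(planted) > 0) {
        rc <- strsplit(res$read, "", fixed = TRUE)[[1]]
        # read offset of a source offset = source offset + insertions before it
        for (o in planted) {
          shift <- sum(ins_off <= o) - sum(del_off < o)
          rc[o + shift + 1L] <- seg_chars[o + 1L]
        }
        res$read <- paste(rc, collapse = "")
      }

      read_i <- read_i + 1L
      reads[read_i] <- res$read
      a_ref[read_i] <- names(seqs)[s]
      a_start[read_i] <- start
      a_end[read_i] <- start + span
      a_strand[read_i] <- strand
      a_ops[read_i] <- res$ops
      total <- total + len
    }
  }

  reads <- Biostrings::DNAStringSet(reads)
  names(reads) <- sprintf("read_%06d", seq_len(read_i))
  alignments <- data.frame(
    read_id = names(reads), ref_id = a_ref, ref_start = a_start,
    ref_end = a_end, strand = a_strand, mapq = 60L, ops = a_ops,
    stringsAsFactors = FALSE
  )
  out <- list(reads = reads, alignments = alignments, config = cfg)
  class(out) <- "simulated_reads"
  out
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d reads, %s bases (mean %.0f bp)\n",
              length(x$reads), format(sum(Biostrings::width(x$reads)), big.mark = ","),
              mean(Biostrings::width(x$reads))))
  invisible(x)
}

#' Plant biallelic heterozygous sites in a genome
#'
#' Draws site positions uniformly over the genome and assigns each an
#' alternate allele differing from the reference base. Sites model residual
#' heterozygosity of an inbred line: every site is biallelic at frequency
#' 0.5, so half the overlapping reads carry the alternate allele.
#'
#' @param genome A `genome_bundle`.
#' @param n_sites Number of heterozygous sites.
#' @param seed Integer seed.
#' @return Data frame with `ref_id`, `pos` (0-based), `ref`, `alt`.
#' @export
plant_het_sites <- function(genome, n_sites, seed = 1L) {
  set.seed(as.integer(seed))
  slens <- Biostrings::width(genome$seqs)
  s <- sample.int(length(slens), n_sites, replace = TRUE, prob = slens)
  pos <- as.integer(floor(stats::runif(n_sites) * slens[s]))
  ref <- vapply(seq_len(n_sites), function(i) {
    as.character(Biostrings::Views(genome$seqs[[s[i]]], pos[i] + 1L, pos[i] + 1L))
  }, "")
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
  out <- data.frame(ref_id = names(genome$seqs)[s], pos = pos,
                    ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("ref_id", "pos")]), ]
  out[order(out$ref_id, out$pos), ]
}
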
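#' Simulate draft contigs with planted assembly failures
#'
#' Builds contigs as reference segments between planted gaps, optionally
#' collapses tandem same-family TE pairs to a single copy, splices distant
#' segments together (relocations/translocations), and sprinkles per-base
#' substitution noise. Every annotated feature receives a truth label
#' (`perfect`, `diverged`, `broken`, `absent`) consistent with the plan, and
#' the true placement of every contig segment is emitted as alignment
#' blocks.
#'
#' @param genome A `genome_bundle`.
#' @param failure_plan List with optional elements:
#'   * `gap_intervals`: data frame `ref_id`, `start`, `end` (0-based
#'     half-open) of reference stretches left out of the contigs, or a
#'     single count of random 1-5 kbp gaps to draw;
#'   * `collapse_tandems`: logical, replace each planted tandem pair by a
#'     single copy (the 3' copy is dropped);
#'   * `relocation_count`: number of contig pairs spliced into one contig;
#'   * `divergence_noise`: per-base substitution rate applied to contigs;
#'   * `seed`: integer seed.
#' @return A `simulated_contigs` list with `contigs` (DNAStringSet), `blocks`
#'   (true [alignment_blocks()]), `truth` (per-feature data frame
#'   `feature_id`, `feature_type`, `planted_status`, `planted_identity`) and
#'   `misassemblies` (planted junctions).
#' @export
simulate_contigs <- function(genome, failure_plan = list()) {
  plan <- utils::modifyList(
    list(gap_intervals = NULL, collapse_tandems = FALSE,
         relocation_count = 0L, divergence_noise = 0, seed = 1L),
    failure_plan
  )
  set.seed(as.integer(plan$seed))
  seqs <- genome$seqs
  slens <- stats::setNames(Biostrings::width(seqs), names(seqs))

  gaps <- plan$gap_intervals
  if (!is.null(gaps) && !is.data.frame(gaps)) {
    # convenience: a single count draws that many random gaps of 1-5 kbp
    stopifnot(is.numeric(gaps), length(gaps) == 1L, gaps >= 0)
    n <- as.integer(gaps)
    if (n == 0L) {
      gaps <- NULL
    } else {
      ref <- sample(names(seqs), n, replace = TRUE,
                    prob = slens / sum(slens))
      len <- sample(1000:5000, n, replace = TRUE)
      start <- vapply(seq_len(n), function(i) {
        sample.int(slens[[ref[i]]] - len[i], 1L) - 1L
      }, 0L)
      gaps <- data.frame(ref_id = ref, start = start, end = start + len,
                         stringsAsFactors = FALSE)
    }
  }
  if (!is.null(gaps) && nrow(gaps) > 0) {
    if (any(gaps$start < 0) || any(gaps$end > slens[gaps$ref_id]) ||
        any(gaps$end <= gaps$start)) {
      stop("gap intervals must lie within genome bounds")
    }
  }
  plan$gap_intervals <- gaps

  # each contig is an ordered list of reference intervals; initially the
  # covered segments between gaps, one contig per segment
  contigs <- list()
  for (ref in names(seqs)) {
    g <- if (is.null(gaps)) NULL else gaps[gaps$ref_id == ref, , drop = FALSE]
    if (is.null(g) || nrow(g) == 0) {
      segs <- data.frame(start = 0L, end = slens[[ref]])
    } else {
      covered <- IRanges::setdiff(
        IRanges::IRanges(1L, slens[[ref]]),
        IRanges::reduce(as_iranges0(g$start, g$end))
      )
      segs <- iranges_to_df0(covered)
    }
    for (i in seq_len(nrow(segs))) {
      contigs[[length(contigs) + 1L]] <- data.frame(
        ref_id = ref, start = segs$start[i], end = segs$end[i],
        stringsAsFactors = FALSE
      )
    }
  }

  # collapse tandem pairs: remove the 3' copy's interval from the contig
  collapsed_ids <- character(0)
  if (isTRUE(plan$collapse_tandems) && nrow(genome$tes) > 0) {
    pairs <- split(genome$tes[!is.na(genome$tes$tandem_pair), , drop = FALSE],
                   genome$tes$tandem_pair[!is.na(genome$tes$tandem_pair)])
    for (p in pairs) {
      if (nrow(p) != 2L) next
      victim <- p[which.max(p$start), , drop = FALSE]
      for (ci in seq_along(contigs)) {
        iv <- contigs[[ci]]
        hit <- which(iv$ref_id == victim$ref_id &
                     iv$start <= victim$start & iv$end >= victim$end)
        if (length(hit) == 1L) {
          row <- iv[hit, ]
          repl <- data.frame(
            ref_id = row$ref_id,
            start = c(row$start, victim$end),
            end = c(victim$start, row$end),
            stringsAsFactors = FALSE
          )
          repl <- repl[repl$end > repl$start, , drop = FALSE]
          contigs[[ci]] <- rbind(
            if (hit > 1L) iv[seq_len(hit - 1L), ],
            repl,
            if (hit < nrow(iv)) iv[(hit + 1L):nrow(iv), ]
          )
          collapsed_ids <- c(collapsed_ids, victim$feature_id)
          break
        }
      }
    }
  }

  # relocations: splice pairs of contigs into single chimeric contigs
  if (plan$relocation_count > 0) {
    if (2L * plan$relocation_count > length(contigs)) {
      stop("relocation_count exceeds available segments")
    }
    picked <- sample.int(length(contigs), 2L * plan$relocation_count)
    keep <- setdiff(seq_along(contigs), picked)
    spliced <- lapply(seq_len(plan$relocation_count), function(i) {
      a <- contigs[[picked[2L * i - 1L]]]
      b <- contigs[[picked[2L * i]]]
      rbind(a, b)
    })
    contigs <- c(contigs[keep], spliced)
  }

  # realize sequences + substitution noise, tracking noise per ref position
  contig_names <- sprintf("contig_%04d", seq_along(contigs))
  contig_seqs <- character(length(contigs))
  blocks <- list()
  noise <- list()  # per contig: data frame ref_id, ref_pos of substitutions
  for (ci in seq_along(contigs)) {
    iv <- contigs[[ci]]
    parts <- vapply(seq_len(nrow(iv)), function(i) {
      as.character(Biostrings::Views(seqs[[iv$ref_id[i]]],
                                     iv$start[i] + 1L, iv$end[i]))
    }, "")
    chars <- strsplit(paste(parts, collapse = ""), "", fixed = TRUE)[[1]]
    clen <- length(chars)
    sub_pos <- integer(0)
    if (plan$divergence_noise > 0) {
      n_sub <- stats::rbinom(1L, clen, plan$divergence_noise)
      if (n_sub > 0) {
        sub_pos <- sort(sample.int(clen, n_sub))
        chars <- substitute_bases(chars, sub_pos)
      }
    }
    contig_seqs[ci] <- paste(chars, collapse = "")
    # map contig positions back to reference positions
    seg_len <- iv$end - iv$start
    cum <- cumsum(c(0L, seg_len))
    if (length(sub_pos)) {
      seg_of <- findInterval(sub_pos - 1L, cum[-length(cum)])
      noise[[ci]] <- data.frame(
        ref_id = iv$ref_id[seg_of],
        ref_pos = iv$start[seg_of] + (sub_pos - 1L) - cum[seg_of],
        stringsAsFactors = FALSE
      )
    } else {
      noise[[ci]] <- data.frame(ref_id = character(), ref_pos = integer())
    }
    for (i in seq_len(nrow(iv))) {
      n_in_seg <- sum(noise[[ci]]$ref_id == iv$ref_id[i] &
                      noise[[ci]]$ref_pos >= iv$start[i] &
                      noise[[ci]]$ref_pos < iv$end[i])
      blocks[[length(blocks) + 1L]] <- data.frame(
        contig_id = contig_names[ci],
        contig_start = cum[i], contig_end = cum[i + 1L],
        ref_id = iv$ref_id[i], ref_start = iv$start[i], ref_end = iv$end[i],
        strand = "+",
        identity = 1 - n_in_seg / seg_len[i],
        stringsAsFactors = FALSE
      )
    }
  }
  blocks <- do.call(rbind, blocks)
  blocks <- alignment_blocks(blocks$contig_id, blocks$contig_start,
                             blocks$contig_end, blocks$ref_id,
                             blocks$ref_start, blocks$ref_end,
                             blocks$strand, blocks$identity)
  noise_all <- do.call(rbind, noise)

  # planted misassembly junctions
  mis <- list()
  for (ci in seq_along(contigs)) {
    iv <- contigs[[ci]]
    if (nrow(iv) < 2L) next
    for (i in seq_len(nrow(iv) - 1L)) {
      kind <- if (iv$ref_id[i] != iv$ref_id[i + 1L]) "translocation" else "relocation"
      mis[[length(mis) + 1L]] <- data.frame(
        contig_id = contig_names[ci], kind = kind,
        contig_pos = sum(iv$end[seq_len(i)] - iv$start[seq_len(i)]),
        ref_id = iv$ref_id[i], ref_pos = iv$end[i],
        stringsAsFactors = FALSE
      )
    }
  }

  # truth labels
  feats <- bundle_features(genome)
  truth <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    status <- "absent"; identity <- NA_real_
    covered <- 0L; full_hit <- FALSE; n_sub <- 0L
    for (ci in seq_along(contigs)) {
      iv <- contigs[[ci]]
      ov <- pmin(iv$end, f$end) - pmax(iv$start, f$start)
      ov[iv$ref_id != f$ref_id] <- 0L
      covered <- covered + sum(pmax(ov, 0L))
      hit <- which(iv$ref_id == f$ref_id & iv$start <= f$start & iv$end >= f$end)
      if (length(hit) > 0L) {
        full_hit <- TRUE
        n_sub <- sum(noise_all$ref_id == f$ref_id &
                     noise_all$ref_pos >= f$start & noise_all$ref_pos < f$end)
      }
    }
    if (full_hit) {
      if (n_sub == 0L) {
        status <- "perfect"; identity <- 1.0
      } else {
        status <- "diverged"; identity <- 1 - n_sub / (f$end - f$start)
      }
    } else if (covered > 0L) {
      status <- "broken"
    }
    data.frame(feature_id = f$feature_id, feature_type = f$feature_type,
               planted_status = status, planted_identity = identity,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth)
  truth$planted_status[truth$feature_id %in% collapsed_ids] <- "absent"
  truth$planted_identity[truth$feature_id %in% collapsed_ids] <- NA_real_

  contig_set <- Biostrings::DNAStringSet(contig_seqs)
  names(contig_set) <- contig_names
  out <- list(contigs = contig_set, blocks = blocks, truth = truth,
              misassemblies = if (length(mis)) do.call(rbind, mis) else
                data.frame(contig_id = character(), kind = character(),
                           contig_pos = integer(), ref_id = character(),
                           ref_pos = integer()),
              plan = plan)
  class(out) <- "simulated_contigs"
  out
}
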
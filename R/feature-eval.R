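#' Assess the assembly of one annotated feature
#'
#' A feature is *contained* when both of its boundary positions lie inside
#' aligned blocks of one contig's best placement (the two boundaries may sit
#' in different blocks of that chain). For contained features the feature
#' span is projected onto the contig through the covering blocks, the
#' corresponding subsequences (feature plus `flank` bases of context on each
#' side, truncated at sequence ends) are extracted, and a local alignment
#' (match +2, mismatch -3, gap opening 5, gap extension 2 — megablast-like
#' scoring) determines identity and length ratio. Both statistics are
#' evaluated over the alignment columns belonging to the feature interval,
#' with the flanks serving only to anchor the alignment at the feature
#' edges: identity is matching columns over feature columns, and the length
#' ratio is the fraction of feature reference bases covered by the
#' alignment. A feature is *perfect* when identity and length ratio both
#' equal 1, and *partial* when it is not contained but at least one boundary
#' or at least 100 bp of it is covered by some block.
#'
#' @param feature One-row data frame with `feature_id`, `feature_type`,
#'   `ref_id`, `start`, `end` (0-based half-open).
#' @param placements List of (stringently filtered) `contig_placement`
#'   objects.
#' @param ref_seqs DNAStringSet of reference scaffolds.
#' @param contig_seqs DNAStringSet of contigs.
#' @param flank Context bases on each side of the extraction windows.
#' @return One-row data frame: `feature_id`, `feature_type`, `contained`,
#'   `contig_id`, `identity`, `length_ratio`, `perfect`, `partial`,
#'   `assessable`.
#' @export
assess_feature <- function(feature, placements, ref_seqs, contig_seqs,
                           flank = 100L) {
  f <- as.list(feature)
  p1 <- f$start
  p2 <- f$end - 1L
  flen <- f$end - f$start

  covering <- function(blocks, p) {
    which(blocks$ref_id == f$ref_id & blocks$ref_start <= p &
          blocks$ref_end > p)
  }

  host <- NULL; b1 <- NULL; b2 <- NULL
  covered_bases <- 0L
  endpoint_hit <- FALSE
  for (pl in placements) {
    bl <- pl$blocks
    i1 <- covering(bl, p1)
    i2 <- covering(bl, p2)
    if (length(i1) > 0) endpoint_hit <- TRUE
    if (length(i2) > 0) endpoint_hit <- TRUE
    same <- bl$ref_id == f$ref_id
    if (any(same)) {
      ov <- pmin(bl$ref_end[same], f$end) - pmax(bl$ref_start[same], f$start)
      covered_bases <- max(covered_bases, max(c(ov, 0L)))
    }
    if (length(i1) > 0 && length(i2) > 0 &&
        (is.null(host) || pl$score > host$score ||
         (pl$score == host$score && pl$contig_id < host$contig_id))) {
      host <- pl
      b1 <- bl[i1[1], ]
      b2 <- bl[i2[1], ]
    }
  }

  res <- data.frame(
    feature_id = f$feature_id, feature_type = f$feature_type,
    contained = FALSE, contig_id = NA_character_,
    identity = NA_real_, length_ratio = NA_real_,
    perfect = FALSE, partial = FALSE, assessable = TRUE,
    stringsAsFactors = FALSE
  )
  if (is.null(host)) {
    res$partial <- endpoint_hit || covered_bases >= 100L
    return(res)
  }
  res$contained <- TRUE
  res$contig_id <- host$contig_id

  project <- function(p, b) {
    if (b$strand == "+") b$contig_start + (p - b$ref_start)
    else b$contig_end - 1L - (p - b$ref_start)
  }
  c1 <- project(p1, b1)
  c2 <- project(p2, b2)
  clen <- length(contig_seqs[[host$contig_id]])
  win_c1 <- max(0L, min(c1, c2) - flank)
  win_c2 <- min(clen, max(c1, c2) + 1L + flank)
  rlen <- length(ref_seqs[[f$ref_id]])
  win_r1 <- max(0L, f$start - flank)
  win_r2 <- min(rlen, f$end + flank)
  if (win_c2 <= win_c1 || win_r2 <= win_r1) {
    res$assessable <- FALSE
    return(res)
  }

  cs <- Biostrings::subseq(contig_seqs[[host$contig_id]], win_c1 + 1L, win_c2)
  if (b1$strand == "-") cs <- Biostrings::reverseComplement(cs)
  rs <- Biostrings::subseq(ref_seqs[[f$ref_id]], win_r1 + 1L, win_r2)

  aln <- Biostrings::pairwiseAlignment(
    rs, cs, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "",
                      fixed = TRUE)[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "",
                      fixed = TRUE)[[1]]
  if (length(p_chars) == 0L) {
    res$assessable <- FALSE
    return(res)
  }
  p_start0 <- BiocGenerics::start(Biostrings::pattern(aln)) - 1L
  # 0-based position in the reference window consumed at each column
  consumed <- cumsum(p_chars != "-")
  ref_pos <- p_start0 + consumed - 1L  # valid where p_chars != "-"
  feat1 <- f$start - win_r1
  feat2 <- feat1 + flen
  in_feat <- (p_chars != "-" & ref_pos >= feat1 & ref_pos < feat2) |
    (p_chars == "-" & p_start0 + consumed > feat1 & p_start0 + consumed < feat2)
  n_cols <- sum(in_feat)
  if (n_cols == 0L) {
    res$assessable <- FALSE
    return(res)
  }
  matches <- sum(in_feat & p_chars != "-" & s_chars != "-" &
                 p_chars == s_chars)
  ref_covered <- length(unique(ref_pos[in_feat & p_chars != "-"]))
  res$identity <- matches / n_cols
  res$length_ratio <- ref_covered / flen
  res$perfect <- res$identity == 1 && res$length_ratio == 1
  res
}

#' Assess every annotated feature of a genome against a placement set
#'
#' Applies [assess_feature()] to every gene and TE annotation and summarizes
#' the fractions contained, perfect, and at >= 99% identity over the full
#' feature length, per feature type.
#'
#' @param genome A `genome_bundle` (or a feature data frame via `features`).
#' @param placements List of stringently filtered `contig_placement`s.
#' @param contig_seqs DNAStringSet of contigs.
#' @param flank Passed to [assess_feature()].
#' @param features Optional explicit feature table overriding the bundle's.
#' @return List with `table` (per-feature assessments) and `summary` (per
#'   feature type: `n`, `fraction_contained`, `fraction_perfect`,
#'   `fraction_at_99`).
#' @export
assess_all <- function(genome, placements, contig_seqs, flank = 100L,
                       features = NULL) {
  if (is.null(features)) features <- bundle_features(genome)
  ref_seqs <- if (inherits(genome, "genome_bundle")) genome$seqs else genome
  rows <- lapply(seq_len(nrow(features)), function(i) {
    assess_feature(features[i, ], placements, ref_seqs, contig_seqs, flank)
  })
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tab, tab$feature_type), function(d) {
    data.frame(
      feature_type = d$feature_type[1],
      n = nrow(d),
      fraction_contained = mean(d$contained),
      fraction_perfect = mean(d$perfect),
      fraction_at_99 = mean(d$contained & !is.na(d$identity) &
                            d$identity >= 0.99 & d$length_ratio >= 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}
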
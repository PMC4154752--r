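#' Position-dependent read error profile
#'
#' Accumulates mismatch, insertion, and deletion events into bins of read
#' position (distance from the read 5' end in sequencing orientation) and
#' divides by the aligned bases falling in each bin. Counting conventions:
#' one event per mismatched, inserted, or deleted base; deletion events are
#' binned at the read offset immediately 5' of the deleted bases, so class
#' totals stay consistent with per-base rates.
#'
#' @param alignments Read alignment data frame (see
#'   [read_read_alignments()]).
#' @param bin_width Bin width in bases (default 100).
#' @param mapq_min Alignments with `mapq` below this are excluded.
#' @return An `error_profile` list: `bin_width`, `bins` (data frame with
#'   per-bin aligned bases, event counts and rates) and `totals`.
#' @export
profile_errors <- function(alignments, bin_width = 100L, mapq_min = 0L) {
  if (bin_width <= 0L) stop("bin_width must be positive")
  a <- alignments[alignments$mapq >= mapq_min, , drop = FALSE]
  mm_l <- list(); ins_l <- list(); del_l <- list()
  run_s <- list(); run_e <- list()
  for (ops in a$ops) {
    r <- parse_ops(ops)
    len <- r$len
    # read offset at the start of each run (I and =/X consume read bases)
    consume <- ifelse(r$op == "D", 0L, len)
    q0 <- cumsum(c(0L, consume))[seq_along(len)]
    is_aln <- r$op %in% c("=", "X")
    run_s[[length(run_s) + 1L]] <- q0[is_aln]
    run_e[[length(run_e) + 1L]] <- q0[is_aln] + len[is_aln]
    xi <- which(r$op == "X")
    if (length(xi)) {
      mm_l[[length(mm_l) + 1L]] <-
        unlist(lapply(xi, function(i) q0[i] + seq_len(len[i]) - 1L))
    }
    ii <- which(r$op == "I")
    if (length(ii)) {
      ins_l[[length(ins_l) + 1L]] <-
        unlist(lapply(ii, function(i) q0[i] + seq_len(len[i]) - 1L))
    }
    di <- which(r$op == "D")
    if (length(di)) {
      del_l[[length(del_l) + 1L]] <-
        unlist(lapply(di, function(i) rep(max(q0[i] - 1L, 0L), len[i])))
    }
  }
  mm_off <- as.integer(unlist(mm_l))
  ins_off <- as.integer(unlist(ins_l))
  del_off <- as.integer(unlist(del_l))
  aligned_runs_s <- as.integer(unlist(run_s))
  aligned_runs_e <- as.integer(unlist(run_e))
  max_off <- max(c(aligned_runs_e, mm_off + 1L, ins_off + 1L, del_off + 1L, 1L))
  n_bins <- ceiling(max_off / bin_width)
  bin_of <- function(off) pmin(off %/% bin_width, n_bins - 1L) + 1L
  count_bins <- function(off) {
    tabulate(bin_of(off), nbins = n_bins)
  }
  # aligned bases per bin: coverage of the =/X runs along the read-offset
  # axis, summed within fixed windows
  if (length(aligned_runs_s)) {
    cov <- IRanges::coverage(as_iranges0(aligned_runs_s, aligned_runs_e),
                             width = n_bins * bin_width)
    aligned <- as.numeric(IRanges::viewSums(IRanges::Views(
      cov, start = (seq_len(n_bins) - 1L) * bin_width + 1L,
      width = bin_width)))
  } else {
    aligned <- numeric(n_bins)
  }
  bins <- data.frame(
    bin = seq_len(n_bins) - 1L,
    start = (seq_len(n_bins) - 1L) * bin_width,
    aligned_bases = aligned,
    mismatches = count_bins(mm_off),
    insertions = count_bins(ins_off),
    deletions = count_bins(del_off)
  )
  bins$mismatch_rate <- ifelse(bins$aligned_bases > 0,
                               bins$mismatches / bins$aligned_bases, 0)
  bins$insertion_rate <- ifelse(bins$aligned_bases > 0,
                                bins$insertions / bins$aligned_bases, 0)
  bins$deletion_rate <- ifelse(bins$aligned_bases > 0,
                               bins$deletions / bins$aligned_bases, 0)
  total_aligned <- sum(bins$aligned_bases)
  totals <- list(
    aligned_bases = total_aligned,
    mismatches = sum(bins$mismatches),
    insertions = sum(bins$insertions),
    deletions = sum(bins$deletions),
    mismatch_rate = if (total_aligned > 0) sum(bins$mismatches) / total_aligned else 0,
    insertion_rate = if (total_aligned > 0) sum(bins$insertions) / total_aligned else 0,
    deletion_rate = if (total_aligned > 0) sum(bins$deletions) / total_aligned else 0
  )
  out <- list(bin_width = as.integer(bin_width), bins = bins, totals = totals)
  class(out) <- "error_profile"
  out
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(paste0("error_profile: %.0f aligned bases; mismatch %.4f%%, ",
                     "insertion %.4f%%, deletion %.4f%% per base\n"),
              x$totals$aligned_bases, 100 * x$totals$mismatch_rate,
              100 * x$totals$insertion_rate, 100 * x$totals$deletion_rate))
  invisible(x)
}

#' Depth of coverage per scaffold
#'
#' Coverage counts reference-consuming alignment (reads span their reference
#' interval; insertions add nothing and deletions are spanned). Returns the
#' run-length encoded per-position depth and a per-scaffold mean table.
#'
#' @param alignments Read alignment data frame with `ref_id`, `ref_start`,
#'   `ref_end`, `mapq` columns.
#' @param ref_lengths Named integer vector of scaffold lengths.
#' @param mapq_min Alignments with `mapq` below this are excluded.
#' @return List with `coverage` (RleList) and `per_scaffold` (data frame of
#'   mean depth).
#' @export
depth_of_coverage <- function(alignments, ref_lengths, mapq_min = 0L) {
  a <- alignments[alignments$mapq >= mapq_min, , drop = FALSE]
  cov <- lapply(names(ref_lengths), function(ref) {
    b <- a[a$ref_id == ref, , drop = FALSE]
    IRanges::coverage(as_iranges0(b$ref_start, b$ref_end),
                      width = ref_lengths[[ref]])
  })
  names(cov) <- names(ref_lengths)
  per_scaffold <- data.frame(
    ref_id = names(ref_lengths),
    length = as.integer(ref_lengths),
    mean_depth = vapply(cov, function(x) sum(as.numeric(x)) /
                          length(x), 0),
    stringsAsFactors = FALSE
  )
  list(coverage = methods::as(cov, "SimpleRleList"),
       per_scaffold = per_scaffold,
       mean_depth = sum(per_scaffold$mean_depth * per_scaffold$length) /
         sum(per_scaffold$length))
}

#' Heterozygosity-corrected read error rate
#'
#' Decomposes the count of reference sites with at least one observed
#' mismatch, `M`, into sequencing error and residual heterozygosity using
#' the relations `M = L * (e_site + h * pi)` and
#' `M_SNP = L * (e_site * p + h * pi)`, where `L` is the reference length,
#' `h` the residual heterozygosity of the sequenced line, `pi` the pairwise
#' diversity of the source population, and `p` the fraction of sites that
#' are known SNPs (every segregating site is assumed previously observed,
#' which makes the correction conservative). Site-level error converts to
#' the per-read-base rate by dividing by the mean depth `c`.
#'
#' Exactly one of `M_SNP` (count of mismatch sites overlapping known SNPs)
#' or `h` must be supplied: with `M_SNP`,
#' `e_site = (M - M_SNP) / (L * (1 - p))` and `h = (M/L - e_site) / pi`;
#' with `h`, `e_site = M/L - h * pi`.
#'
#' @param M Count of reference sites with >= 1 mismatch observation.
#' @param L Reference length in bases.
#' @param pi Pairwise diversity (fraction).
#' @param c Mean depth of coverage (fold).
#' @param M_SNP Count of mismatch sites overlapping known SNPs (optional).
#' @param p Fraction of sites that are known SNPs (required with `M_SNP`).
#' @param h Residual heterozygosity fraction (optional).
#' @return List with `e_site`, `e_read` and `h` (all fractions).
#' @export
solve_error_rates <- function(M, L, pi, c, M_SNP = NULL, p = NULL, h = NULL) {
  if (is.null(M_SNP) == is.null(h)) {
    stop("exactly one of M_SNP and h must be supplied")
  }
  stopifnot(M >= 0, L > 0, M <= L, pi > 0, pi < 1, c > 0)
  if (!is.null(M_SNP)) {
    stopifnot(!is.null(p), p > 0, p < 1, M_SNP >= 0, M_SNP <= M)
    e_site <- (M - M_SNP) / (L * (1 - p))
    h <- (M / L - e_site) / pi
  } else {
    stopifnot(h >= 0)
    e_site <- M / L - h * pi
  }
  if (e_site < -1e-15 || h < -1e-15) {
    stop("model inconsistent with inputs: negative error or heterozygosity")
  }
  e_site <- max(e_site, 0)
  h <- max(h, 0)
  list(e_site = e_site, e_read = e_site / c, h = h)
}

#' Count mismatch sites for the heterozygosity correction
#'
#' Tallies distinct reference sites with at least one observed mismatch from
#' a read alignment table, and optionally how many overlap a known-SNP site
#' list.
#'
#' @param alignments Read alignment data frame with `ops`.
#' @param snp_sites Optional data frame with `ref_id`, `pos` (0-based).
#' @param mapq_min Minimum MAPQ.
#' @return List with `M` and (when `snp_sites` given) `M_SNP`.
#' @export
count_mismatch_sites <- function(alignments, snp_sites = NULL, mapq_min = 0L) {
  a <- alignments[alignments$mapq >= mapq_min, , drop = FALSE]
  ref_l <- list(); pos_l <- list()
  for (i in seq_len(nrow(a))) {
    r <- parse_ops(a$ops[i])
    xi <- which(r$op == "X")
    if (length(xi) == 0L) next
    # reference bases consumed before each run, walking in read orientation
    consume <- ifelse(r$op %in% c("=", "X", "D"), r$len, 0L)
    before <- cumsum(c(0L, consume))[seq_along(consume)]
    pos <- unlist(lapply(xi, function(j) before[j] + seq_len(r$len[j]) - 1L))
    pos <- if (a$strand[i] == "-") a$ref_end[i] - 1L - pos else
      a$ref_start[i] + pos
    ref_l[[length(ref_l) + 1L]] <- rep(a$ref_id[i], length(pos))
    pos_l[[length(pos_l) + 1L]] <- pos
  }
  if (length(pos_l) == 0L) {
    return(list(M = 0L, M_SNP = if (is.null(snp_sites)) NULL else 0L))
  }
  sites <- unique(data.frame(ref_id = unlist(ref_l), pos = unlist(pos_l),
                             stringsAsFactors = FALSE))
  out <- list(M = nrow(sites))
  if (!is.null(snp_sites)) {
    key <- paste(sites$ref_id, sites$pos)
    snp_key <- paste(snp_sites$ref_id, snp_sites$pos)
    out$M_SNP <- sum(key %in% snp_key)
  }
  out
}
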
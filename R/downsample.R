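#' Down-sample reads to a target fold-coverage
#'
#' Draws reads uniformly without replacement (order randomized by `seed`)
#' until the cumulative read length reaches `target_depth * genome_size`;
#' the read that crosses the threshold is kept, so the sampled bases lie in
#' `[target, target + max read length)`.
#'
#' @param reads A `simulated_reads` object (or list with `reads` and
#'   `alignments`).
#' @param genome_size Genome length in bases.
#' @param target_depth Target fold-coverage.
#' @param seed Integer seed.
#' @return A `simulated_reads` object holding the subset.
#' @export
downsample_reads <- function(reads, genome_size, target_depth, seed = 1L) {
  stopifnot(target_depth > 0)
  lens <- Biostrings::width(reads$reads)
  total <- sum(lens)
  target <- target_depth * genome_size
  if (target > total) {
    stop(sprintf("unattainable target: %.2fx requested, %.2fx available",
                 target_depth, total / genome_size))
  }
  set.seed(as.integer(seed))
  ord <- sample.int(length(lens))
  cum <- cumsum(lens[ord])
  n_keep <- which(cum >= target)[1]
  keep <- ord[seq_len(n_keep)]
  out <- list(
    reads = reads$reads[keep],
    alignments = reads$alignments[
      match(names(reads$reads)[keep], reads$alignments$read_id), ,
      drop = FALSE],
    config = reads$config
  )
  rownames(out$alignments) <- NULL
  class(out) <- "simulated_reads"
  out
}

#' Assembly and feature-recovery metrics as a function of coverage
#'
#' Simulates reads once at the deepest target, then for each depth
#' down-samples, rebuilds the coverage-gap pseudo-assembly (the desk-scale
#' surrogate for re-assembly: the pseudo-contigs are exact reference
#' segments bounded by coverage gaps), and records NG(x) contiguity and the
#' fraction of genes and TEs recovered perfectly. Because pseudo-contigs are
#' exact reference segments, a feature is perfectly recovered exactly when
#' its interval is contained in one pseudo-contig, so recovery is computed
#' at interval level.
#'
#' @param genome A `genome_bundle`.
#' @param cfg A [read_sim_config()]; its `target_depth` must be at least
#'   `max(depths)`.
#' @param depths Ascending fold-coverage targets.
#' @param min_overlap,min_len Pseudo-assembly parameters.
#' @param seed Seed for the down-sampling draws.
#' @param ngx Percentages at which NG(x) is recorded.
#' @return A `coverage_series` list: `table` (per depth: NG50, LG50,
#'   fractions perfect) and `ng_curves` (per depth NG(x) values).
#' @export
coverage_series <- function(genome, cfg, depths,
                            min_overlap = 800L, min_len = 1000L,
                            seed = 1L, ngx = c(seq(5, 95, by = 5), 99)) {
  stopifnot(all(depths > 0))
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("depths must be strictly ascending")
  }
  if (cfg$target_depth < max(depths)) {
    stop("cfg$target_depth must cover the deepest target")
  }
  genome_size <- sum(Biostrings::width(genome$seqs))
  reads <- simulate_reads(genome, cfg)
  feats <- bundle_features(genome)

  rows <- list()
  curves <- list()
  for (d in depths) {
    sub <- if (d >= sum(Biostrings::width(reads$reads)) / genome_size) reads
      else downsample_reads(reads, genome_size, d, seed = seed)
    pc <- pseudo_assemble(sub$alignments, min_overlap = min_overlap,
                          min_len = min_len)
    recovered <- feature_recovery(feats, pc)
    ng <- vapply(ngx, function(x) {
      nx_metrics(pc$length, x, genome_size)$N
    }, 0)
    ng50 <- nx_metrics(pc$length, 50, genome_size)
    rows[[length(rows) + 1L]] <- data.frame(
      depth = d,
      n_pseudo_contigs = nrow(pc),
      total_length = sum(pc$length),
      NG50 = ng50$N, LG50 = ng50$L,
      fraction_genes_perfect = recovered["gene"],
      fraction_tes_perfect = recovered["TE"]
    )
    curves[[as.character(d)]] <- data.frame(depth = d, x = ngx, NG = ng)
  }
  out <- list(table = do.call(rbind, rows),
              ng_curves = do.call(rbind, curves))
  rownames(out$table) <- NULL
  rownames(out$ng_curves) <- NULL
  class(out) <- "coverage_series"
  out
}

# fraction of features whose interval is contained in one pseudo-contig
feature_recovery <- function(feats, pseudo_contigs) {
  ok <- vapply(seq_len(nrow(feats)), function(i) {
    any(pseudo_contigs$ref_id == feats$ref_id[i] &
        pseudo_contigs$start <= feats$start[i] &
        pseudo_contigs$end >= feats$end[i])
  }, TRUE)
  c(gene = if (any(feats$feature_type == "gene"))
      mean(ok[feats$feature_type == "gene"]) else NA_real_,
    TE = if (any(feats$feature_type == "TE"))
      mean(ok[feats$feature_type == "TE"]) else NA_real_)
}
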
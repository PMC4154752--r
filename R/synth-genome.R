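#' Describe a transposable-element family for the genome simulator
#'
#' A family is defined by its canonical (consensus) sequence length, how many
#' copies are planted, the mean divergence of copies from the canonical
#' sequence (substitutions per base), the GC content of the canonical
#' sequence, and the fraction of copies arranged as adjacent same-family
#' tandem pairs — the organizational axes along which TE assembly difficulty
#' varies.
#'
#' @param name Family label.
#' @param canonical_length Canonical sequence length in bases (>= 50).
#' @param copy_number Number of copies to plant (>= 1).
#' @param mean_divergence Mean substitutions per base of copies relative to
#'   the canonical sequence, in `[0, 0.5]`.
#' @param gc_content GC fraction of the canonical sequence, in `[0, 1]`.
#' @param tandem_fraction Fraction of copies placed as adjacent same-family
#'   pairs, in `[0, 1]`.
#' @return A `te_family` list.
#' @export
te_family <- function(name, canonical_length, copy_number, mean_divergence,
                      gc_content = 0.4, tandem_fraction = 0) {
  stopifnot(
    is.character(name), nchar(name) > 0,
    canonical_length >= 50,
    copy_number >= 1,
    mean_divergence >= 0, mean_divergence <= 0.5,
    gc_content >= 0, gc_content <= 1,
    tandem_fraction >= 0, tandem_fraction <= 1
  )
  structure(
    list(name = name,
         canonical_length = as.integer(canonical_length),
         copy_number = as.integer(copy_number),
         mean_divergence = mean_divergence,
         gc_content = gc_content,
         tandem_fraction = tandem_fraction),
    class = "te_family"
  )
}

BASES <- c("A", "C", "G", "T")

# Random sequence with a target GC fraction (chars).
random_seq_chars <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# Background with sinusoidal GC landscape: per-position GC probability
# mean + amplitude * sin(2*pi*pos/period), clamped away from 0 and 1.
background_chars <- function(n, landscape) {
  pos <- seq_len(n)
  p_gc <- landscape$mean +
    landscape$amplitude * sin(2 * pi * pos / landscape$period)
  p_gc <- pmin(pmax(p_gc, 0.02), 0.98)
  is_gc <- stats::runif(n) < p_gc
  out <- character(n)
  half <- stats::runif(n) < 0.5
  out[is_gc] <- ifelse(half[is_gc], "G", "C")
  out[!is_gc] <- ifelse(half[!is_gc], "A", "T")
  out
}

# Substitute n_sub positions of a character vector with a different base.
substitute_bases <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  chars
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[chars]))
}

#' Generate a toy annotated reference genome with planted TE families
#'
#' Builds scaffolds with a sinusoidal GC landscape, plants TE copies drawn
#' from family specifications (per-copy substitutions are binomial at the
#' family mean divergence, optional 5' truncation, random strand, and a
#' configurable fraction of copies in adjacent tandem pairs), and annotates
#' non-overlapping gene intervals. The result is the ground-truth reference
#' against which reads, contigs, and assessments are validated.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold in bases.
#' @param families List of [te_family()] specifications.
#' @param gene_density Genes per Mbp of total genome (the realized count is
#'   `round(gene_density * genome_mbp)`).
#' @param gc_landscape List with `mean`, `amplitude`, `period` of the
#'   background GC sinusoid.
#' @param seed Integer seed; identical seeds reproduce identical bundles.
#' @param gene_length_range Range gene lengths are drawn from (uniform).
#' @param truncation_prob Probability that a planted TE copy is 5'-truncated
#'   (by a uniform fraction up to half its length).
#' @param margin Feature-free bases kept at each scaffold end.
#' @param min_gap Minimum spacing between planted features.
#' @return A `genome_bundle` list with elements `seqs` (DNAStringSet),
#'   `genes` and `tes` (data frames, 0-based half-open coordinates),
#'   `families` (data frame of the specs) and `canonical` (DNAStringSet of
#'   canonical sequences).
#' @export
generate_genome <- function(n_scaffolds, scaffold_length, families,
                            gene_density = 10,
                            gc_landscape = list(mean = 0.42, amplitude = 0.08,
                                                period = 1e5),
                            seed = 1L,
                            gene_length_range = c(1000L, 3000L),
                            truncation_prob = 0,
                            margin = 200L, min_gap = 50L) {
  stopifnot(n_scaffolds >= 1, scaffold_length > 2 * margin)
  if (length(families) > 0 && !all(vapply(families, inherits, TRUE, "te_family"))) {
    stop("families must be a list of te_family() objects")
  }
  set.seed(as.integer(seed))
  genome_len <- n_scaffolds * scaffold_length

  # canonical sequences
  canonical <- lapply(families, function(f) random_seq_chars(f$canonical_length, f$gc_content))
  names(canonical) <- vapply(families, `[[`, "", "name")

  # plan placement units: tandem pairs count as one unit of two copies
  units <- list()
  for (f in families) {
    n_pairs <- floor(f$copy_number * f$tandem_fraction / 2)
    n_single <- f$copy_number - 2L * n_pairs
    if (n_pairs > 0) {
      for (i in seq_len(n_pairs)) {
        units[[length(units) + 1L]] <- list(kind = "te_pair", family = f$name)
      }
    }
    if (n_single > 0) {
      for (i in seq_len(n_single)) {
        units[[length(units) + 1L]] <- list(kind = "te", family = f$name)
      }
    }
  }
  n_genes <- round(gene_density * genome_len / 1e6)
  gene_lens <- if (n_genes > 0) {
    as.integer(round(stats::runif(n_genes, gene_length_range[1], gene_length_range[2])))
  } else integer(0)
  for (i in seq_len(n_genes)) {
    units[[length(units) + 1L]] <- list(kind = "gene", len = gene_lens[i])
  }

  # realize TE copies (lengths needed before placement)
  fam_by_name <- stats::setNames(families, vapply(families, `[[`, "", "name"))
  realize_te <- function(fam_name) {
    f <- fam_by_name[[fam_name]]
    chars <- canonical[[fam_name]]
    len <- f$canonical_length
    if (truncation_prob > 0 && stats::runif(1) < truncation_prob) {
      cut <- as.integer(floor(stats::runif(1, 0, 0.5) * len))
      if (cut > 0) chars <- chars[-seq_len(cut)]
      len <- length(chars)
    }
    n_sub <- stats::rbinom(1L, len, f$mean_divergence)
    if (n_sub > 0) {
      chars <- substitute_bases(chars, sample.int(len, n_sub))
    }
    strand <- sample(c("+", "-"), 1L)
    seq_chars <- if (strand == "-") revcomp_chars(chars) else chars
    list(family = fam_name, len = len, n_sub = n_sub, strand = strand,
         chars = seq_chars)
  }

  unit_payload <- lapply(units, function(u) {
    switch(u$kind,
      te = { r <- realize_te(u$family); r$kind <- "te"; list(r) },
      te_pair = {
        a <- realize_te(u$family); b <- realize_te(u$family)
        a$kind <- b$kind <- "te"
        list(a, b)
      },
      gene = list(list(kind = "gene", len = u$len))
    )
  })
  unit_lens <- vapply(unit_payload, function(p) sum(vapply(p, `[[`, 0L, "len")), 0L)

  if (sum(unit_lens) >= 0.8 * genome_len) {
    stop("packing error: planted features exceed 80% of genome length")
  }

  # assign units to scaffolds, then space them with random gaps >= min_gap
  order_units <- sample.int(length(unit_lens))
  scaffold_of <- integer(length(unit_lens))
  remaining <- rep(scaffold_length - 2L * margin, n_scaffolds)
  for (i in order_units) {
    need <- unit_lens[i] + min_gap
    ok <- which(remaining >= need)
    if (length(ok) == 0L) stop("packing error: features do not fit on scaffolds")
    s <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = remaining[ok])
    scaffold_of[i] <- s
    remaining[s] <- remaining[s] - need
  }

  genes <- list(); tes <- list()
  seqs <- vector("list", n_scaffolds)
  te_counter <- stats::setNames(rep(0L, length(families)), names(canonical))
  gene_counter <- 0L
  pair_counter <- 0L

  for (s in seq_len(n_scaffolds)) {
    chars <- background_chars(scaffold_length, gc_landscape)
    idx <- which(scaffold_of == s)
    if (length(idx) > 0L) {
      idx <- sample(idx)  # random order along the scaffold
      k <- length(idx)
      free <- scaffold_length - 2L * margin - sum(unit_lens[idx]) - k * min_gap
      # distribute the leftover free space across k+1 inter-unit gaps
      extra <- if (free > 0) {
        cuts <- sort(sample.int(free + k, k))
        diff(c(0L, cuts, free + k)) - 1L
      } else rep(0L, k + 1L)
      pos <- margin
      for (j in seq_along(idx)) {
        pos <- pos + extra[j]
        u <- unit_payload[[idx[j]]]
        if (length(u) == 2L) pair_counter <- pair_counter + 1L
        for (part in u) {
          if (part$kind == "gene") {
            gene_counter <- gene_counter + 1L
            genes[[length(genes) + 1L]] <- data.frame(
              feature_id = sprintf("gene_%04d", gene_counter),
              ref_id = sprintf("scaffold_%d", s),
              start = pos, end = pos + part$len,
              stringsAsFactors = FALSE
            )
          } else {
            te_counter[part$family] <- te_counter[part$family] + 1L
            chars[(pos + 1L):(pos + part$len)] <- part$chars
            tes[[length(tes) + 1L]] <- data.frame(
              feature_id = sprintf("te_%s_%04d", part$family, te_counter[part$family]),
              ref_id = sprintf("scaffold_%d", s),
              start = pos, end = pos + part$len,
              strand = part$strand,
              family = part$family,
              n_subs = part$n_sub,
              divergence = part$n_sub / part$len,
              tandem_pair = if (length(u) == 2L) pair_counter else NA_integer_,
              stringsAsFactors = FALSE
            )
          }
          pos <- pos + part$len + min_gap
        }
      }
    }
    seqs[[s]] <- paste(chars, collapse = "")
  }

  seqs <- Biostrings::DNAStringSet(unlist(seqs))
  names(seqs) <- sprintf("scaffold_%d", seq_len(n_scaffolds))

  fam_df <- do.call(rbind, lapply(families, function(f) {
    data.frame(family = f$name, canonical_length = f$canonical_length,
               copy_number = f$copy_number, mean_divergence = f$mean_divergence,
               gc_content = f$gc_content, tandem_fraction = f$tandem_fraction,
               stringsAsFactors = FALSE)
  }))
  canonical_set <- Biostrings::DNAStringSet(vapply(canonical, paste, "", collapse = ""))

  bundle <- list(
    seqs = seqs,
    genes = if (length(genes)) do.call(rbind, genes) else
      data.frame(feature_id = character(), ref_id = character(),
                 start = integer(), end = integer()),
    tes = if (length(tes)) do.call(rbind, tes) else
      data.frame(feature_id = character(), ref_id = character(),
                 start = integer(), end = integer(), strand = character(),
                 family = character(), n_subs = integer(),
                 divergence = numeric(), tandem_pair = integer()),
    families = fam_df,
    canonical = canonical_set,
    gc_landscape = gc_landscape,
    seed = as.integer(seed)
  )
  class(bundle) <- "genome_bundle"
  bundle
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle: %d scaffold(s), %s bp, %d gene(s), %d TE copie(s) in %d familie(s)\n",
              length(x$seqs), format(sum(Biostrings::width(x$seqs)), big.mark = ","),
              nrow(x$genes), nrow(x$tes),
              if (is.null(x$families)) 0L else nrow(x$families)))
  invisible(x)
}

# All annotated feature intervals of a bundle as one data frame.
bundle_features <- function(genome) {
  g <- genome$genes
  t <- genome$tes
  rbind(
    if (nrow(g)) data.frame(feature_id = g$feature_id, feature_type = "gene",
                            ref_id = g$ref_id, start = g$start, end = g$end,
                            stringsAsFactors = FALSE),
    if (nrow(t)) data.frame(feature_id = t$feature_id, feature_type = "TE",
                            ref_id = t$ref_id, start = t$start, end = t$end,
                            stringsAsFactors = FALSE)
  )
}
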
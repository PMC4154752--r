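#' Read contig-to-reference alignments from a PAF file
#'
#' The query side is taken as the contig. Identity is the ratio of matching
#' bases (column 10) to alignment block length (column 11). PAF coordinates
#' are already 0-based half-open and are preserved as-is.
#'
#' @param path Path to a PAF file (>= 12 tab-separated columns per line).
#' @return [alignment_blocks()] with one row per line. Query/target lengths
#'   are attached as attributes `contig_lengths` and `ref_lengths`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed PAF line %d: fewer than 12 columns", bad[1]))
  }
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
    if (anyNA(v)) {
      stop(sprintf("malformed PAF line %d: non-numeric column %d",
                   which(is.na(v))[1], i))
    }
    v
  }
  chr <- function(i) vapply(fields, `[[`, "", i)
  strand <- chr(5)
  if (!all(strand %in% c("+", "-"))) {
    stop(sprintf("malformed PAF line %d: bad strand",
                 which(!strand %in% c("+", "-"))[1]))
  }
  matches <- num(10); blocklen <- num(11)
  blocks <- alignment_blocks(
    contig_id = chr(1), contig_start = num(3), contig_end = num(4),
    ref_id = chr(6), ref_start = num(8), ref_end = num(9),
    strand = strand, identity = ifelse(blocklen > 0, matches / blocklen, 0)
  )
  attr(blocks, "contig_lengths") <-
    stats::setNames(as.integer(num(2)), chr(1))[!duplicated(chr(1))]
  attr(blocks, "ref_lengths") <-
    stats::setNames(as.integer(num(7)), chr(6))[!duplicated(chr(6))]
  blocks
}

#' Write alignment blocks as PAF
#'
#' @param blocks [alignment_blocks()].
#' @param path Output path.
#' @param contig_lengths,ref_lengths Named integer vectors of sequence
#'   lengths; defaults fall back to attributes on `blocks` or to the maximum
#'   end coordinate observed.
#' @export
write_paf <- function(blocks, path, contig_lengths = NULL, ref_lengths = NULL) {
  if (is.null(contig_lengths)) contig_lengths <- attr(blocks, "contig_lengths")
  if (is.null(ref_lengths)) ref_lengths <- attr(blocks, "ref_lengths")
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(blocks$contig_end, blocks$contig_id, max)
  }
  if (is.null(ref_lengths)) {
    ref_lengths <- tapply(blocks$ref_end, blocks$ref_id, max)
  }
  matches <- round(blocks$identity * blocks$aligned_length)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   blocks$contig_id,
                   as.integer(contig_lengths[blocks$contig_id]),
                   blocks$contig_start, blocks$contig_end, blocks$strand,
                   blocks$ref_id, as.integer(ref_lengths[blocks$ref_id]),
                   blocks$ref_start, blocks$ref_end,
                   as.integer(matches), blocks$aligned_length, 60L)
  writeLines(lines, path)
  invisible(path)
}

#' Read NUCmer show-coords tab output
#'
#' Consumes `show-coords -T` style rows: `S1 E1 S2 E2 LEN1 LEN2 %IDY REF QRY`
#' with 1-based inclusive coordinates (reference first, contig second).
#' Reversed intervals (start > end) are normalized to forward orientation
#' with the strand flag set to `-`.
#'
#' @param path Path to the tab-separated file (header lines starting with
#'   non-numeric fields are skipped).
#' @return [alignment_blocks()].
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_data <- vapply(fields, function(f) {
    length(f) >= 9L && !is.na(suppressWarnings(as.numeric(f[1])))
  }, TRUE)
  # tolerate the standard show-coords preamble, but a non-numeric line among
  # data lines is an error
  first_data <- which(is_data)[1]
  if (is.na(first_data)) return(empty_blocks())
  if (any(!is_data[first_data:length(is_data)])) {
    stop(sprintf("malformed coords line %d",
                 which(!is_data & seq_along(is_data) >= first_data)[1]))
  }
  fields <- fields[is_data]
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
    if (anyNA(v)) stop(sprintf("malformed coords line: non-numeric column %d", i))
    v
  }
  s1 <- num(1); e1 <- num(2); s2 <- num(3); e2 <- num(4)
  idy <- num(7)
  ref_id <- vapply(fields, `[[`, "", 8)
  contig_id <- vapply(fields, `[[`, "", 9)
  strand <- ifelse(xor(s1 > e1, s2 > e2), "-", "+")
  r <- one_to_zero_based(pmin(s1, e1), pmax(s1, e1))
  q <- one_to_zero_based(pmin(s2, e2), pmax(s2, e2))
  alignment_blocks(contig_id, q$start, q$end, ref_id, r$start, r$end,
                   strand, idy / 100)
}

# ---- SAM / tabular read alignments --------------------------------------

# Merge a CIGAR string (possibly with M runs) and an MD tag into =XID
# run-length operations covering the aligned portion of the read.
cigar_md_to_ops <- function(cigar, md) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  # tokenize MD: numbers (match runs), letters (mismatch), ^SEQ (deletion)
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  md_q <- list()
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      n <- as.integer(t)
      if (n > 0) md_q[[length(md_q) + 1L]] <- c("=", n)
    } else if (startsWith(t, "^")) {
      md_q[[length(md_q) + 1L]] <- c("D", nchar(t) - 1L)
    } else {
      md_q[[length(md_q) + 1L]] <- c("X", 1L)
    }
  }
  md_i <- 1L
  md_left <- if (length(md_q)) as.integer(md_q[[1]][2]) else 0L
  have_md <- length(md_q) > 0L
  take_md <- function(n) {
    # consume n ref bases from MD, returning =/X runs; without an MD tag the
    # CIGAR itself must already classify mismatches (=/X runs)
    if (!have_md) return(list(t = character(0), l = integer(0)))
    out_t <- character(0); out_l <- integer(0)
    while (n > 0L) {
      if (md_i > length(md_q)) stop("MD tag shorter than CIGAR")
      t <- md_q[[md_i]][1]
      use <- min(n, md_left)
      out_t <- c(out_t, t); out_l <- c(out_l, use)
      md_left <<- md_left - use
      n <- n - use
      if (md_left == 0L) {
        md_i <<- md_i + 1L
        if (md_i <= length(md_q)) md_left <<- as.integer(md_q[[md_i]][2])
      }
    }
    list(t = out_t, l = out_l)
  }
  out_t <- character(0); out_l <- integer(0)
  push <- function(t, l) {
    k <- length(out_t)
    if (k > 0L && out_t[k] == t) out_l[k] <<- out_l[k] + l
    else { out_t[k + 1L] <<- t; out_l[k + 1L] <<- l }
  }
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M")) {
      if (!have_md) stop("M CIGAR runs need an MD tag to classify mismatches")
      r <- take_md(len)
      for (j in seq_along(r$t)) if (r$l[j] > 0) push(r$t[j], r$l[j])
    } else if (op %in% c("=", "X")) {
      take_md(len)
      push(op, len)
    } else if (op == "I") {
      push("I", len)
    } else if (op == "D") {
      take_md(len)
      push("D", len)
    } else if (op %in% c("S", "H", "N", "P")) {
      # clips/skips are not part of the aligned portion
      next
    }
  }
  paste0(out_l, out_t, collapse = "")
}

parse_ops <- function(ops) {
  m <- regmatches(ops, gregexpr("\\d+[=XID]", ops))[[1]]
  data.frame(len = as.integer(sub("[=XID]$", "", m)),
             op = sub("^\\d+", "", m), stringsAsFactors = FALSE)
}

reverse_ops <- function(ops) {
  r <- parse_ops(ops)
  paste0(rev(r$len), rev(r$op), collapse = "")
}

ops_ref_span <- function(ops) {
  r <- parse_ops(ops)
  sum(r$len[r$op %in% c("=", "X", "D")])
}

#' Read per-read alignments from SAM/BAM or the simulator's tabular format
#'
#' Returns one row per mapped read with run-length `=XID` operations in read
#' orientation (5' to 3' of the read as sequenced): reverse-strand SAM
#' records have their operations reversed. Mismatches in `M` CIGAR runs are
#' classified using the MD tag; records without MD and without `=`/`X`
#' operations raise an error. Unmapped records are skipped and counted in
#' the `unmapped` attribute.
#'
#' @param path A `.sam`/`.bam` file or a tab-separated table with columns
#'   `read_id`, `ref_id`, `ref_start`, `ref_end`, `strand`, `mapq`, `ops`.
#' @return Data frame of read alignments.
#' @export
read_read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "mapq", "cigar", "flag"),
      tag = "MD"
    )
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    unmapped <- bitwAnd(x$flag, 4L) != 0L
    n_unmapped <- sum(unmapped)
    keep <- which(!unmapped)
    if (length(keep) == 0L) {
      out <- data.frame(read_id = character(), ref_id = character(),
                        ref_start = integer(), ref_end = integer(),
                        strand = character(), mapq = integer(),
                        ops = character())
      attr(out, "unmapped") <- n_unmapped
      return(out)
    }
    md <- x$tag$MD[keep]
    cigar <- x$cigar[keep]
    has_eq <- grepl("[=X]", cigar) & !grepl("M", cigar)
    if (any(is.na(md) & !has_eq)) {
      stop("cannot classify mismatches: records lack both MD tags and =/X CIGAR runs")
    }
    ops <- vapply(seq_along(keep), function(i) {
      cigar_md_to_ops(cigar[i], if (is.na(md[i])) "" else md[i])
    }, "")
    rev_strand <- bitwAnd(x$flag[keep], 16L) != 0L
    ops[rev_strand] <- vapply(ops[rev_strand], reverse_ops, "")
    spans <- vapply(ops, ops_ref_span, 0)
    out <- data.frame(
      read_id = x$qname[keep],
      ref_id = as.character(x$rname[keep]),
      ref_start = x$pos[keep] - 1L,
      ref_end = x$pos[keep] - 1L + as.integer(spans),
      strand = ifelse(rev_strand, "-", "+"),
      mapq = x$mapq[keep],
      ops = unname(ops),
      stringsAsFactors = FALSE
    )
    attr(out, "unmapped") <- n_unmapped
    out
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("read_id", "ref_id", "ref_start", "ref_end", "strand", "mapq", "ops")
    if (!all(need %in% names(out))) {
      stop("tabular alignments must have columns: ", paste(need, collapse = ", "))
    }
    attr(out, "unmapped") <- 0L
    out
  }
}

#' Write read alignments in the package's tabular format
#' @param alignments Data frame as returned by [read_read_alignments()].
#' @param path Output path.
#' @export
write_read_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- GFF3 / BED / VCF / FASTA -------------------------------------------

#' Write genome annotations as GFF3
#'
#' Genes are emitted as `gene` features, TE copies as `transposable_element`
#' features with `family=` and `divergence=` attributes. Internal 0-based
#' half-open coordinates are converted to the 1-based inclusive GFF3
#' convention.
#'
#' @param genome A `genome_bundle`.
#' @param path Output path.
#' @export
write_gff3 <- function(genome, path) {
  make_gr <- function(df, type, extra = NULL) {
    if (nrow(df) == 0L) return(NULL)
    coords <- zero_to_one_based(df$start, df$end)
    gr <- GenomicRanges::GRanges(
      df$ref_id,
      IRanges::IRanges(coords$start, coords$end),
      strand = if ("strand" %in% names(df)) df$strand else "*"
    )
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- df$feature_id
    for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
    gr
  }
  grs <- list(
    make_gr(genome$genes, "gene"),
    make_gr(genome$tes, "transposable_element",
            list(family = genome$tes$family,
                 divergence = genome$tes$divergence))
  )
  gr <- do.call(c, grs[!vapply(grs, is.null, TRUE)])
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation file into the package's feature table
#'
#' @param path GFF3 path.
#' @return Data frame with `feature_id`, `feature_type` (`gene`/`TE`),
#'   `ref_id`, `start`, `end` (0-based half-open), `strand`, and `family`,
#'   `divergence` where present.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  coords <- one_to_zero_based(BiocGenerics::start(gr), BiocGenerics::end(gr))
  data.frame(
    feature_id = if ("ID" %in% names(mc)) as.character(mc$ID) else
      sprintf("feature_%d", seq_along(gr)),
    feature_type = ifelse(as.character(mc$type) == "gene", "gene", "TE"),
    ref_id = as.character(GenomicRanges::seqnames(gr)),
    start = coords$start, end = coords$end,
    strand = as.character(BiocGenerics::strand(gr)),
    family = if ("family" %in% names(mc)) as.character(mc$family) else NA_character_,
    divergence = if ("divergence" %in% names(mc)) as.numeric(mc$divergence) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED (0-based half-open)
#' @param df Data frame with `ref_id`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$ref_id, as_iranges0(df$start, df$end))
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED intervals (returned 0-based half-open)
#' @param path BED path.
#' @return Data frame with `ref_id`, `start`, `end` and `name` if present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    ref_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) out$name <- as.character(mc$name)
  out
}

#' Write heterozygous/SNP sites as a minimal sites-only VCF
#' @param sites Data frame with `ref_id`, `pos` (0-based), `ref`, `alt`.
#' @param path Output path.
#' @export
write_vcf_sites <- function(sites, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=repeatproof",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  sites$ref_id, sites$pos + 1L, sites$ref, sites$alt)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read site positions from a sites-only VCF
#' @param path VCF path.
#' @return Data frame with `ref_id`, `pos` (0-based), `ref`, `alt`.
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- if (is.matrix(fx)) fx else matrix(fx, nrow = 1,
                                          dimnames = list(NULL, names(fx)))
  data.frame(
    ref_id = as.character(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]) - 1L,
    ref = as.character(fx[, "REF"]),
    alt = as.character(fx[, "ALT"]),
    stringsAsFactors = FALSE
  )
}

#' Write all outputs of the synthetic-data generator to a directory
#'
#' Emits `genome.fa`, `annotations.gff3`, `canonical.fa` and `families.tsv`
#' for the genome; `reads.fa` plus `read_alignments.tsv` when reads are
#' given; `contigs.fa`, `contig_placements.paf`, `truth.tsv` and
#' `gap_truth.bed` when contigs are given; `het_sites.vcf` when sites are
#' given.
#'
#' @param genome A `genome_bundle`.
#' @param dir Output directory (created if needed).
#' @param reads Optional `simulated_reads`.
#' @param contigs Optional `simulated_contigs`.
#' @param het_sites Optional het-site data frame.
#' @export
write_simulation <- function(genome, dir, reads = NULL, contigs = NULL,
                             het_sites = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$seqs, file.path(dir, "genome.fa"))
  write_gff3(genome, file.path(dir, "annotations.gff3"))
  if (length(genome$canonical) > 0) {
    Biostrings::writeXStringSet(genome$canonical, file.path(dir, "canonical.fa"))
  }
  if (!is.null(genome$families) && nrow(genome$families) > 0) {
    utils::write.table(genome$families, file.path(dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(reads)) {
    Biostrings::writeXStringSet(reads$reads, file.path(dir, "reads.fa"))
    write_read_alignments(reads$alignments,
                          file.path(dir, "read_alignments.tsv"))
  }
  if (!is.null(contigs)) {
    Biostrings::writeXStringSet(contigs$contigs, file.path(dir, "contigs.fa"))
    write_paf(contigs$blocks, file.path(dir, "contig_placements.paf"),
              contig_lengths = stats::setNames(Biostrings::width(contigs$contigs),
                                               names(contigs$contigs)),
              ref_lengths = stats::setNames(Biostrings::width(genome$seqs),
                                            names(genome$seqs)))
    utils::write.table(contigs$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gaps <- contigs$plan$gap_intervals
    if (!is.null(gaps) && nrow(gaps) > 0) {
      write_bed(gaps, file.path(dir, "gap_truth.bed"))
    }
  }
  if (!is.null(het_sites) && nrow(het_sites) > 0) {
    write_vcf_sites(het_sites, file.path(dir, "het_sites.vcf"))
  }
  invisible(dir)
}
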
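test_that("nx_metrics matches hand-computed N50/L50 cases", {
  # total 15, half 7.5: 5+4 = 9 >= 7.5 at the second contig
  m <- nx_metrics(c(5, 4, 3, 2, 1), x = 50)
  expect_equal(m$N, 4)
  expect_equal(m$L, 2L)
  expect_true(m$reached)
  # NG50 against genome_size 20: target 10, 5+4+3 = 12 at the third
  g <- nx_metrics(c(5, 4, 3, 2, 1), x = 50, genome_size = 20)
  expect_equal(g$N, 3)
  expect_equal(g$L, 3L)
  # unreachable target: N = 0, L = contig count, flagged
  u <- nx_metrics(c(5, 4), x = 50, genome_size = 100)
  expect_equal(u$N, 0)
  expect_equal(u$L, 2L)
  expect_false(u$reached)
  # input order must not matter
  expect_equal(nx_metrics(c(1, 3, 5, 2, 4)), nx_metrics(c(5, 4, 3, 2, 1)))
  expect_error(nx_metrics(numeric(0)))
  expect_error(nx_metrics(c(1, 0)))
  expect_error(nx_metrics(c(1, 2), x = 0))
})

test_that("nx_metrics matches the cumulative-scan oracle on 1000 cases", {
  set.seed(88)
  for (case in 1:1000) {
    n <- sample(1:50, 1)
    lengths <- sample.int(10000L, n, replace = TRUE)
    x <- sample(c(10, 50, 90, 100), 1)
    gs <- if (stats::runif(1) < 0.5) NULL else
      round(stats::runif(1, 0.2, 2) * sum(lengths))
    got <- nx_metrics(lengths, x, genome_size = gs)
    want <- nx_oracle(lengths, x, genome_size = gs)
    expect_equal(got$N, want$N, label = sprintf("case %d N", case))
    expect_equal(got$L, want$L, label = sprintf("case %d L", case))
    expect_equal(got$reached, want$reached)
  }
})

test_that("assembly_metrics summarizes sizes and GC", {
  contigs <- Biostrings::DNAStringSet(c(c1 = strrep("AT", 50),
                                        c2 = strrep("GC", 100)))
  m <- assembly_metrics(contigs, genome_size = 400)
  expect_equal(m$n_contigs, 2L)
  expect_equal(m$total_size, 300)
  expect_equal(m$longest, 200)
  expect_equal(m$shortest, 100)
  expect_equal(m$gc_content, 200 / 300)
  expect_equal(m$N50, 200)
  expect_equal(m$L50, 1L)
  expect_equal(m$NG50, 200)  # target 200; first contig reaches it
  # numeric-lengths input skips GC
  m2 <- assembly_metrics(c(100, 200))
  expect_true(is.na(m2$gc_content))
  expect_equal(m2$N50, 200)
})

test_that("detect_misassemblies classifies junction types", {
  mk <- function(ref, strand, rs, re, cs, ce) {
    alignment_blocks("c1", cs, ce, ref, rs, re, strand, 1)
  }
  pl <- function(b) {
    out <- list(contig_id = "c1", blocks = b,
                score = sum(b$identity * b$aligned_length))
    class(out) <- "contig_placement"
    out
  }
  # translocation: blocks on different references
  b1 <- rbind(mk("r1", "+", 0L, 1000L, 0L, 1000L),
              mk("r2", "+", 0L, 1000L, 1000L, 2000L))
  d1 <- detect_misassemblies(pl(b1))
  expect_equal(d1$events$kind, "translocation")
  expect_equal(d1$broken_lengths, c(1000, 1000))
  # inversion: same reference, opposite strands
  b2 <- rbind(mk("r1", "+", 0L, 1000L, 0L, 1000L),
              mk("r1", "-", 2000L, 3000L, 1000L, 2000L))
  d2 <- detect_misassemblies(pl(b2))
  expect_equal(d2$events$kind, "inversion")
  # relocation: gap inconsistency above the threshold
  b3 <- rbind(mk("r1", "+", 0L, 1000L, 0L, 1000L),
              mk("r1", "+", 2500L, 3500L, 1000L, 2000L))
  d3 <- detect_misassemblies(pl(b3))  # ref gap 1500, contig gap 0
  expect_equal(d3$events$kind, "relocation")
  expect_equal(d3$events$inconsistency, 1500)
  # inconsistency exactly at the threshold is tolerated
  b4 <- rbind(mk("r1", "+", 0L, 1000L, 0L, 1000L),
              mk("r1", "+", 2000L, 3000L, 1000L, 2000L))
  d4 <- detect_misassemblies(pl(b4), inconsistency_threshold = 1000L)
  expect_equal(nrow(d4$events), 0L)
  expect_equal(d4$broken_lengths, 2000)
  # reverse strand pair, consistent spacing: no event
  b5 <- rbind(mk("r1", "-", 2000L, 3000L, 0L, 1000L),
              mk("r1", "-", 900L, 1900L, 1000L, 2000L))
  d5 <- detect_misassemblies(pl(b5))
  expect_equal(nrow(d5$events), 0L)
})

test_that("na_metrics never exceeds N50 of the unbroken chains", {
  g <- tiny_genome(seed = 60, scaffold_length = 1e5, n_scaffolds = 1L)
  sim <- simulate_contigs(g, list(
    gap_intervals = data.frame(ref_id = names(g$seqs)[1],
                               start = 40000L, end = 42000L),
    relocation_count = 1L, seed = 3L))
  pl <- best_placements(sim$blocks)
  na <- na_metrics(pl)
  whole <- nx_metrics(vapply(pl, function(p) sum(p$blocks$aligned_length), 0))
  expect_lte(na$N, whole$N)
  expect_true(na$reached)
  # planted relocation shows up as an event
  expect_true("relocation" %in% na$events$kind)
})

test_that("per100kbp_errors counts planted substitutions exactly", {
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  ref <- paste(sample(bases, 50000, replace = TRUE), collapse = "")
  contig <- strsplit(ref, "", fixed = TRUE)[[1]]
  pos <- sample(50000L, 25L)
  for (p in pos) contig[p] <- setdiff(bases, contig[p])[1]
  ref_seqs <- Biostrings::DNAStringSet(c(r1 = ref))
  contig_seqs <- Biostrings::DNAStringSet(c(c1 = paste(contig, collapse = "")))
  pl <- best_placements(alignment_blocks("c1", 0L, 50000L, "r1", 0L, 50000L,
                                         "+", 1 - 25 / 50000))
  e <- per100kbp_errors(pl, contig_seqs, ref_seqs)
  expect_equal(e$mismatches, 25L)
  expect_equal(e$mismatches_per_100kbp, 1e5 * 25 / 50000)
  expect_equal(e$short_indels, 0L)
  expect_equal(e$long_indels, 0L)
})

test_that("per100kbp_errors counts indel events through realignment", {
  set.seed(62)
  ref <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
               collapse = "")
  # delete 3 bases at one locus and 20 at another: one short + one long event
  contig <- paste0(substr(ref, 1, 1000), substr(ref, 1004, 2500),
                   substr(ref, 2521, 4000))
  ref_seqs <- Biostrings::DNAStringSet(c(r1 = ref))
  contig_seqs <- Biostrings::DNAStringSet(c(c1 = contig))
  pl <- best_placements(alignment_blocks("c1", 0L, nchar(contig), "r1", 0L,
                                         4000L, "+", 0.99))
  e <- per100kbp_errors(pl, contig_seqs, ref_seqs, short_indel_max = 5L)
  expect_equal(e$short_indels, 1L)
  expect_equal(e$long_indels, 1L)
  expect_equal(e$mismatches, 0L)
  # reverse-strand blocks are reverse-complemented before comparison
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref)))
  pl2 <- best_placements(alignment_blocks("c2", 0L, 4000L, "r1", 0L, 4000L,
                                          "-", 1))
  e2 <- per100kbp_errors(pl2, Biostrings::DNAStringSet(c(c2 = rc)),
                         ref_seqs)
  expect_equal(e2$mismatches, 0L)
})

test_that("per100kbp_errors validates block coordinates", {
  ref_seqs <- Biostrings::DNAStringSet(c(r1 = strrep("A", 100)))
  contig_seqs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100)))
  bad <- best_placements(alignment_blocks("c1", 0L, 200L, "r1", 0L, 200L,
                                          "+", 1))
  expect_error(per100kbp_errors(bad, contig_seqs, ref_seqs), "inconsistent")
})

test_that("merge_end_overlaps joins exact suffix-prefix overlaps", {
  set.seed(63)
  genome <- paste(sample(c("A", "C", "G", "T"), 7800 + 2400,
                         replace = TRUE), collapse = "")
  # c1 = [1,5000], c2 = [3801,7800]: 1200 bp exact overlap
  contigs <- Biostrings::DNAStringSet(c(
    c1 = substr(genome, 1, 5000),
    c2 = substr(genome, 3801, 7800)
  ))
  m <- merge_end_overlaps(contigs, min_overlap = 1000L)
  expect_equal(length(m$contigs), 1L)
  expect_equal(length(m$contigs[[1]]), 5000 + 4000 - 1200)
  expect_equal(as.character(m$contigs[[1]]), substr(genome, 1, 7800))
  expect_equal(m$log$overlap, 1200L)
  expect_equal(m$log$orientation, "+")
  # overlap below the threshold: nothing merges
  short <- Biostrings::DNAStringSet(c(
    c1 = substr(genome, 1, 5000),
    c2 = substr(genome, 4102, 9000)  # 899 bp overlap
  ))
  m2 <- merge_end_overlaps(short, min_overlap = 1000L)
  expect_equal(length(m2$contigs), 2L)
  expect_equal(nrow(m2$log), 0L)
})

test_that("merge_end_overlaps handles reverse-complement overlaps and conserves bases", {
  set.seed(64)
  genome <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                  collapse = "")
  c2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome, 3801, 8000))))
  contigs <- Biostrings::DNAStringSet(c(
    c1 = substr(genome, 1, 5000), c2 = c2rc))
  m <- merge_end_overlaps(contigs, min_overlap = 1000L)
  expect_equal(length(m$contigs), 1L)
  expect_equal(m$log$orientation, "-")
  expect_equal(as.character(m$contigs[[1]]), substr(genome, 1, 8000))
  # base conservation: merged length = inputs minus one overlap copy
  expect_equal(sum(Biostrings::width(m$contigs)),
               5000 + 4200 - m$log$overlap)
})
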
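test_that("te_family enforces its invariants", {
  f <- te_family("roo", canonical_length = 5000, copy_number = 10,
                 mean_divergence = 0.05)
  expect_s3_class(f, "te_family")
  expect_error(te_family("x", canonical_length = 10, copy_number = 1,
                         mean_divergence = 0))
  expect_error(te_family("x", canonical_length = 100, copy_number = 0,
                         mean_divergence = 0))
  expect_error(te_family("x", canonical_length = 100, copy_number = 1,
                         mean_divergence = 0.6))
  expect_error(te_family("x", canonical_length = 100, copy_number = 1,
                         mean_divergence = 0, gc_content = 1.2))
})

test_that("zero-divergence copies are exact substrings of the canonical", {
  fams <- list(te_family("zero", canonical_length = 1000, copy_number = 10,
                         mean_divergence = 0))
  g <- generate_genome(1, 1e5, fams, gene_density = 5, seed = 11)
  canon <- as.character(g$canonical[["zero"]])
  for (i in seq_len(nrow(g$tes))) {
    te <- g$tes[i, ]
    planted <- as.character(Biostrings::subseq(g$seqs[[te$ref_id]],
                                               te$start + 1L, te$end))
    if (te$strand == "-") {
      planted <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(planted)))
    }
    expect_identical(planted, canon)
    expect_identical(te$n_subs, 0L)
  }
})

test_that("realized substitutions match the binomial expectation", {
  # copy_number 50, length 1000, divergence 0.01 -> mean substitutions
  # within 3 standard errors of 10 (SE = sqrt(1000 * 0.01 * 0.99 / 50))
  fams <- list(te_family("div", canonical_length = 1000, copy_number = 50,
                         mean_divergence = 0.01))
  g <- generate_genome(2, 2e5, fams, gene_density = 2, seed = 13)
  expect_equal(nrow(g$tes), 50L)
  se <- sqrt(1000 * 0.01 * 0.99 / 50)
  expect_lt(abs(mean(g$tes$n_subs) - 10), 3 * se)
  expect_equal(g$tes$divergence, g$tes$n_subs / (g$tes$end - g$tes$start))
})

test_that("gene_density gives the exact gene count, genes never overlap TEs", {
  g <- tiny_genome(seed = 3, scaffold_length = 1e6, n_scaffolds = 2,
                   gene_density = 10)
  expect_equal(nrow(g$genes), 20L)  # 10 genes/Mbp * 2 Mbp
  for (i in seq_len(nrow(g$genes))) {
    for (j in seq_len(nrow(g$tes))) {
      if (g$genes$ref_id[i] == g$tes$ref_id[j]) {
        expect_lte(min(g$genes$end[i], g$tes$end[j]) -
                     max(g$genes$start[i], g$tes$start[j]), 0)
      }
    }
  }
})

test_that("tandem pairs are adjacent same-family copies", {
  g <- tiny_genome(seed = 5)
  pairs <- split(g$tes[!is.na(g$tes$tandem_pair), ],
                 g$tes$tandem_pair[!is.na(g$tes$tandem_pair)])
  expect_gt(length(pairs), 0)
  for (p in pairs) {
    expect_equal(nrow(p), 2L)
    expect_equal(p$family[1], p$family[2])
    expect_equal(p$ref_id[1], p$ref_id[2])
    gap <- max(p$start) - min(p$end)
    expect_lte(gap, 60)  # adjacent up to the generator's minimum spacing
  }
})

test_that("infeasible packing raises an explicit error", {
  fams <- list(te_family("huge", canonical_length = 10000, copy_number = 50,
                         mean_divergence = 0))
  expect_error(generate_genome(1, 5e5, fams, gene_density = 5, seed = 1),
               "packing|fit|exceed")
})

test_that("generation is deterministic per seed", {
  g1 <- tiny_genome(seed = 7)
  g2 <- tiny_genome(seed = 7)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  expect_identical(g1$tes, g2$tes)
  expect_identical(g1$genes, g2$genes)
  g3 <- tiny_genome(seed = 8)
  expect_false(identical(as.character(g1$seqs), as.character(g3$seqs)))
})

test_that("error-free reads are exact genome substrings", {
  g <- tiny_genome(seed = 2, scaffold_length = 1e5, n_scaffolds = 1)
  cfg <- read_sim_config(mismatch_rate = 0, insertion_rate = 0,
                         deletion_rate = 0, target_depth = 2, seed = 4)
  r <- simulate_reads(g, cfg)
  expect_gt(length(r$reads), 5)
  for (i in seq_len(min(50L, length(r$reads)))) {
    a <- r$alignments[i, ]
    src <- Biostrings::subseq(g$seqs[[a$ref_id]], a$ref_start + 1L, a$ref_end)
    if (a$strand == "-") src <- Biostrings::reverseComplement(src)
    expect_identical(as.character(r$reads[[i]]), as.character(src))
    expect_match(a$ops, "^[0-9]+=$")
  }
})

test_that("no simulated read is shorter than min_length", {
  g <- tiny_genome(seed = 2, scaffold_length = 1e5, n_scaffolds = 1)
  r <- simulate_reads(g, read_sim_config(target_depth = 5, seed = 21))
  expect_gte(min(Biostrings::width(r$reads)), 1500L)
})

test_that("realized mismatch count is within 3 Poisson SE of expectation", {
  g <- tiny_genome(seed = 9, scaffold_length = 3e5, n_scaffolds = 1,
                   gene_density = 5)
  cfg <- read_sim_config(mismatch_rate = 0.001, insertion_rate = 0,
                         deletion_rate = 0, target_depth = 10, seed = 10)
  r <- simulate_reads(g, cfg)
  total_bases <- sum(Biostrings::width(r$reads))
  n_x <- sum(vapply(r$alignments$ops, function(o) {
    runs <- regmatches(o, gregexpr("[0-9]+X", o))[[1]]
    sum(as.integer(sub("X", "", runs)))
  }, 0))
  expected <- total_bases * 0.001
  expect_lt(abs(n_x - expected), 3 * sqrt(expected))
})

test_that("read length equals the drawn length despite indels", {
  g <- tiny_genome(seed = 2, scaffold_length = 1e5, n_scaffolds = 1)
  cfg <- read_sim_config(insertion_rate = 0.005, deletion_rate = 0.005,
                         target_depth = 3, seed = 6)
  r <- simulate_reads(g, cfg)
  # ops consume: = X I on the read; D on the reference only
  for (i in seq_len(min(100L, nrow(r$alignments)))) {
    a <- r$alignments[i, ]
    lens <- as.integer(regmatches(a$ops, gregexpr("[0-9]+", a$ops))[[1]])
    types <- regmatches(a$ops, gregexpr("[=XID]", a$ops))[[1]]
    read_len <- sum(lens[types %in% c("=", "X", "I")])
    ref_len <- sum(lens[types %in% c("=", "X", "D")])
    expect_equal(read_len, Biostrings::width(r$reads)[i])
    expect_equal(ref_len, a$ref_end - a$ref_start)
  }
})

test_that("het sites appear in about half the overlapping reads", {
  g <- tiny_genome(seed = 2, scaffold_length = 2e5, n_scaffolds = 1)
  hs <- plant_het_sites(g, 50, seed = 3)
  cfg <- read_sim_config(mismatch_rate = 0, insertion_rate = 0,
                         deletion_rate = 0, target_depth = 10, seed = 5)
  r <- simulate_reads(g, cfg, het_sites = hs)
  # with zero error rates every X event is a planted het allele
  prof <- profile_errors(r$alignments)
  n_x <- prof$totals$mismatches
  depth <- depth_of_coverage(r$alignments, ref_lengths_of(g))
  exp_cover <- sum(vapply(seq_len(nrow(hs)), function(i) {
    as.numeric(depth$coverage[[hs$ref_id[i]]][hs$pos[i] + 1L])
  }, 0))
  expect_gt(exp_cover, 200)
  expect_lt(abs(n_x - 0.5 * exp_cover), 3 * sqrt(0.25 * exp_cover))
})

test_that("unattainable read length raises an error", {
  fams <- list(te_family("f", canonical_length = 100, copy_number = 1,
                         mean_divergence = 0))
  g <- generate_genome(1, 1200, fams, gene_density = 0, seed = 1)
  expect_error(simulate_reads(g, read_sim_config(target_depth = 2, seed = 1)),
               "unattainable")
})

test_that("empty failure plan yields one perfect contig per scaffold", {
  g <- tiny_genome(seed = 15)
  sc <- simulate_contigs(g, list(seed = 2))
  expect_equal(length(sc$contigs), 2L)
  expect_identical(sort(unname(as.character(sc$contigs))),
                   sort(unname(as.character(g$seqs))))
  expect_true(all(sc$truth$planted_status == "perfect"))
  expect_true(all(sc$truth$planted_identity == 1))
  expect_equal(nrow(sc$misassemblies), 0L)
})

test_that("a gap bisecting a gene labels it broken", {
  g <- tiny_genome(seed = 16)
  gene <- g$genes[1, ]
  mid <- (gene$start + gene$end) %/% 2
  plan <- list(gap_intervals = data.frame(ref_id = gene$ref_id,
                                          start = mid - 50L, end = mid + 50L),
               seed = 3)
  sc <- simulate_contigs(g, plan)
  lab <- sc$truth[sc$truth$feature_id == gene$feature_id, ]
  expect_equal(lab$planted_status, "broken")
  # both flanking contigs carry alignments into the gene
  b <- sc$blocks
  left <- any(b$ref_id == gene$ref_id & b$ref_start <= gene$start &
                b$ref_end > gene$start)
  right <- any(b$ref_id == gene$ref_id & b$ref_start < gene$end &
                 b$ref_end >= gene$end)
  expect_true(left && right)
})

test_that("collapse_tandems labels victims absent and partners perfect", {
  g <- tiny_genome(seed = 17)
  pairs <- g$tes[!is.na(g$tes$tandem_pair), ]
  expect_gt(nrow(pairs), 0)
  sc <- simulate_contigs(g, list(collapse_tandems = TRUE, seed = 4))
  for (pid in unique(pairs$tandem_pair)) {
    p <- pairs[pairs$tandem_pair == pid, ]
    victim <- p$feature_id[which.max(p$start)]
    partner <- p$feature_id[which.min(p$start)]
    expect_equal(
      sc$truth$planted_status[sc$truth$feature_id == victim], "absent")
    expect_equal(
      sc$truth$planted_status[sc$truth$feature_id == partner], "perfect")
  }
})

test_that("contig plus gap lengths conserve the genome length", {
  g <- tiny_genome(seed = 18)
  gaps <- data.frame(ref_id = names(g$seqs)[c(1, 1, 2)],
                     start = c(10000L, 50000L, 30000L),
                     end = c(13000L, 54000L, 36000L))
  sc <- simulate_contigs(g, list(gap_intervals = gaps, seed = 5))
  expect_equal(sum(Biostrings::width(sc$contigs)) + sum(gaps$end - gaps$start),
               sum(Biostrings::width(g$seqs)))
})

test_that("excessive relocation_count raises an error", {
  g <- tiny_genome(seed = 19)
  expect_error(simulate_contigs(g, list(relocation_count = 5, seed = 1)),
               "relocation")
})

test_that("written simulation outputs are byte-identical per seed", {
  g <- tiny_genome(seed = 20, scaffold_length = 5e4, n_scaffolds = 1,
                   gene_density = 20)
  r <- simulate_reads(g, read_sim_config(target_depth = 1, seed = 2))
  sc <- simulate_contigs(g, list(seed = 3))
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(g, d1, reads = r, contigs = sc)
  write_simulation(g, d2, reads = r, contigs = sc)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
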
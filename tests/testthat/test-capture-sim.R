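test_that("make_genome is seeded, reproducible and composition-controlled", {
  g1 <- make_genome(5000, seed = 7)
  g2 <- make_genome(5000, seed = 7)
  expect_identical(g1$seq, g2$seq)
  g3 <- make_genome(5000, seed = 8)
  expect_false(identical(g1$seq, g3$seq))

  g <- make_genome(100000, seed = 9, gc_bias = 0.5)
  expect_lt(abs(gc_content(g$seq[["chr1"]]) - 50), 1)  # binomial bound
  g_rich <- make_genome(100000, seed = 9, gc_bias = 0.65)
  expect_lt(abs(gc_content(g_rich$seq[["chr1"]]) - 65), 1)
  expect_error(make_genome(500), ">= 1000")
})

test_that("apply_deletion removes exactly the specified bases", {
  g <- make_genome(100000, seed = 13)
  del <- apply_deletion(g, "chr1", 45000, 31)
  expect_equal(nchar(del$seq[["chr1"]]), 99969)
  expect_equal(substring(del$seq[["chr1"]], 1, 44999),
               substring(g$seq[["chr1"]], 1, 44999))
  expect_equal(substring(del$seq[["chr1"]], 45000, 99969),
               substring(g$seq[["chr1"]], 45031, 100000))
  expect_error(apply_deletion(g, "chr1", 45000, 0), "positive")
  expect_error(apply_deletion(g, "chr1", 99990, 31), "beyond")
})

test_that("simulated reads are exact substrings with faithful truth records", {
  g <- make_genome(20000, seed = 17)
  cfg <- sim_config(target = rse_interval("chr1", 5001, 10000),
                    n_reads = 500, enrichment = 2, read_len = 36, seed = 21)
  sim <- simulate_capture_reads(g, cfg)
  expect_length(sim$reads, 500)
  for (i in seq_len(100)) {
    tr <- sim$truth[i, ]
    src <- substring(g$seq[[tr$chrom]], tr$start, tr$start + 35)
    want <- if (tr$strand == "+") src else rsecapture:::revcomp(src)
    expect_identical(unname(sim$reads[[tr$read_id]]), want)
  }
  # byte-identical under a fixed seed
  sim2 <- simulate_capture_reads(g, cfg)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("null enrichment gives an on-target fraction near L/G", {
  g <- make_genome(50000, seed = 23)
  cfg <- sim_config(target = rse_interval("chr1", 10001, 20000),
                    n_reads = 20000, enrichment = 1, seed = 29)
  sim <- simulate_capture_reads(g, cfg)
  p <- 10000 / 50000
  expect_lt(abs(sim$n_on_target / 20000 - p), 0.01)
})

test_that("an unattainable enrichment is rejected", {
  g <- make_genome(20000, seed = 31)
  cfg <- sim_config(target = rse_interval("chr1", 1, 10000),
                    n_reads = 100, enrichment = 3, seed = 1)
  expect_error(simulate_capture_reads(g, cfg), "probability")
})

test_that("align_exact recovers truth positions and flags ambiguity", {
  g <- make_genome(30000, seed = 37)
  cfg <- sim_config(target = rse_interval("chr1", 1, 30000),
                    n_reads = 400, enrichment = 1, seed = 41)
  sim <- simulate_capture_reads(g, cfg)
  al <- align_exact(sim$reads, g)
  expect_equal(al$unmapped + al$ambiguous, 0L)
  m <- merge(al$alignments, sim$truth, by = "read_id",
             suffixes = c("", ".truth"))
  expect_equal(nrow(m), 400L)
  expect_equal(m$start, m$start.truth)
  expect_equal(m$strand, m$strand.truth)

  # a read duplicated in the reference is ambiguous
  dupseq <- paste0(g$seq[["chr1"]],
                   substring(g$seq[["chr1"]], 101, 136))
  g_dup <- rse_genome(c(chr1 = dupseq))
  probe <- sim$reads[1]
  names(probe) <- "probe"
  probe[] <- substring(g$seq[["chr1"]], 101, 136)
  al2 <- align_exact(probe, g_dup)
  expect_equal(al2$ambiguous, 1L)
})

test_that("align_exact agrees with brute-force substring search", {
  g <- make_genome(5000, seed = 43)
  cfg <- sim_config(target = rse_interval("chr1", 1, 5000),
                    n_reads = 50, enrichment = 1, seed = 47)
  sim <- simulate_capture_reads(g, cfg)
  al <- align_exact(sim$reads, g)
  for (i in seq_len(nrow(al$alignments))) {
    a <- al$alignments[i, ]
    fwd_hits <- oracle_occurrence_count(unname(sim$reads[[a$read_id]]),
                                        g$seq)
    expect_equal(fwd_hits, 1L)
    src <- substring(g$seq[["chr1"]], a$start, a$start + 35)
    want <- if (a$strand == "+") src else rsecapture:::revcomp(src)
    expect_identical(unname(sim$reads[[a$read_id]]), want)
  }
})

test_that("reads spanning a deletion junction fail to map to the reference", {
  ref <- make_genome(20000, seed = 53)
  allele <- apply_deletion(ref, "chr1", 9000, 31)
  # reads straddling the junction at allele position 9000
  junction_reads <- vapply(0:9, function(k) {
    substring(allele$seq[["chr1"]], 8980 - k, 8980 - k + 35)
  }, "")
  names(junction_reads) <- paste0("j", 0:9)
  al <- align_exact(junction_reads, ref)
  expect_equal(al$unmapped, 10L)
})

test_that("find_deletion_site skips junctions with flank micro-homology", {
  g <- rse_genome(c(c = paste0(strrep("A", 20), "CGTGCTAGCTAAGCTTCCAG")))
  ch <- strsplit(g$seq[["c"]], "", fixed = TRUE)[[1]]
  pos <- find_deletion_site(g, "c", 5, 3)
  # inside the poly-A run every junction is homologous; the first
  # admissible site must satisfy both junction conditions
  expect_gt(pos, 16)
  expect_true(ch[pos - 1] != ch[pos + 2])
  expect_true(ch[pos + 3] != ch[pos])
  expect_error(find_deletion_site(
    rse_genome(c(c = strrep("A", 2000))), "c", 10, 5, max_scan = 100),
    "no unambiguous")
})

test_that("a planted deletion is recovered as a zero-coverage gap", {
  # 200x mean depth: a base flanking the deletion is reachable only by
  # reads starting at one exact position, so flank coverage per side is
  # Poisson(depth/read_len) and exact-length recovery needs deep sampling
  ref <- make_genome(12000, seed = 59)
  del_pos <- find_deletion_site(ref, "chr1", 6000, 31)
  allele <- apply_deletion(ref, "chr1", del_pos, 31)
  n_reads <- ceiling(nchar(allele$seq[["chr1"]]) * 200 / 36)
  cfg <- sim_config(target = rse_interval("chr1", 1, 11969),
                    n_reads = n_reads, enrichment = 1, seed = 61)
  sim <- simulate_capture_reads(allele, cfg)
  al <- align_exact(sim$reads, ref)
  prof <- depth_profile(al$alignments, rse_interval("chr1", 3001, 9000))
  gaps <- find_gaps(prof)
  expect_equal(max(gaps$length), 31)
  best <- gaps[which.max(gaps$length), ]
  expect_equal(c(best$start, best$end), c(del_pos, del_pos + 30))
  # flanking bases retain coverage (maximality of the gap)
  d <- prof$depth
  expect_gt(d[del_pos - 1 - 3001 + 1], 0)
  expect_gt(d[del_pos + 31 - 3001 + 1], 0)
})

test_that("simulated enrichment is recovered by the evaluation stage", {
  g <- make_genome(60000, seed = 67)
  tgt <- rse_interval("chr1", 20001, 30000)
  cfg <- sim_config(target = tgt, n_reads = 30000, enrichment = 40,
                    seed = 71, genome_bp = 1e6)
  sim <- simulate_capture_reads(g, cfg)
  rep <- enrichment_report(sim$truth, cfg$n_reads, tgt, genome_bp = 1e6,
                           overlap = "within")
  expect_lt(abs(rep$fold_enrichment - 40) / 40, 0.05)
})
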
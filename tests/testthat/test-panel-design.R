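test_that("window parsing reproduces the published panel geometry", {
  # 319,757 bp at 8 kb spacing with a terminal anchor site = 41 design
  # sites, the size of the published first-capture panel
  w <- parse_windows(rse_interval("chr19", 32557347, 32877103))
  expect_equal(nrow(w), 41L)
  expect_equal(sum(!w$terminal), 40L)
  expect_equal(w$anchor[41], 32877103 - 27 + 1)
})

test_that("a region smaller than the spacing yields a single window", {
  cfg <- design_config(anchor_end = FALSE)
  w <- parse_windows(rse_interval("c", 1001, 6000), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(1001, 6000))
})

test_that("non-terminal windows partition the region exactly and evenly", {
  set.seed(31)
  for (i in 1:20) {
    start <- sample.int(1e5, 1)
    len <- sample(500:60000, 1)
    region <- rse_interval("c", start, start + len - 1)
    w <- parse_windows(region, design_config(anchor_end = (i %% 2 == 0)))
    base <- w[!w$terminal, ]
    expect_equal(base$start[1], region$start)
    expect_equal(base$end[nrow(base)], region$end)
    if (nrow(base) > 1) {
      expect_equal(base$start[-1], base$end[-nrow(base)] + 1)  # disjoint
      expect_lte(diff(range(base$end - base$start + 1)), 1)    # equal +-1
    }
    expect_equal(sum(base$end - base$start + 1), len)
  }
})

test_that("oversized regions are rejected with advice to split", {
  expect_error(parse_windows(rse_interval("c", 1, 1000001)), "split")
})

test_that("candidate enumeration counts and ordering are correct", {
  set.seed(41)
  g <- rse_genome(c(c = random_dna(200)))
  w <- data.frame(chrom = "c", start = 51, end = 150, anchor = 51)
  cands <- enumerate_candidates(w, g)
  # closed form: sum over k of (100 - k + 1), k = 22..27
  expect_equal(nrow(cands), sum(100 - (22:27) + 1))  # 459
  expect_true(all(diff(cands$dist) >= 0))
  first <- cands[cands$dist == 0, ]
  expect_equal(first$length, sort(first$length, decreasing = TRUE))
  expect_equal(cands$sequence[1], substring(g$seq[["c"]], 51, 77))
})

test_that("masked bases exclude candidates spanning them", {
  set.seed(43)
  g <- rse_genome(c(c = random_dna(200)))
  g$mask$c[100] <- TRUE  # single masked base at the window center
  w <- data.frame(chrom = "c", start = 51, end = 150, anchor = 51)
  cands <- enumerate_candidates(w, g)
  expect_true(all(cands$end < 100 | cands$start > 100))
  # brute-force enumeration oracle
  want <- oracle_candidates(g$seq[["c"]], g$mask$c, 51, 150, 22, 27)
  expect_equal(nrow(cands), length(want))
  got_keys <- sort(paste(cands$start, cands$length))
  want_keys <- sort(vapply(want, function(x) paste(x[1], x[2]), ""))
  expect_equal(got_keys, want_keys)

  g$mask$c[] <- TRUE
  expect_equal(nrow(enumerate_candidates(w, g)), 0L)
})

test_that("uniqueness_check counts exact occurrences on both strands", {
  set.seed(53)
  core <- random_dna(5000)
  probe <- substring(core, 1001, 1025)
  g_unique <- rse_genome(c(c = core))
  expect_true(uniqueness_check(probe, g_unique))

  g_dup <- rse_genome(c(c = paste0(core, "TTTT", probe)))
  expect_false(uniqueness_check(probe, g_dup))

  g_rc <- rse_genome(c(c = paste0(core, "TTTT",
                                  rsecapture:::revcomp(probe))))
  expect_false(uniqueness_check(probe, g_rc))

  expect_error(uniqueness_check("ACGTACGT", g_unique), "seed")
})

test_that("uniqueness_check agrees with a brute-force substring counter", {
  set.seed(59)
  g <- rse_genome(c(a = random_dna(30000), b = random_dna(20000)))
  cfg <- design_config()
  for (i in 1:50) {
    chrom <- sample(c("a", "b"), 1)
    s0 <- sample.int(nchar(g$seq[[chrom]]) - 24, 1)
    probe <- substring(g$seq[[chrom]], s0, s0 + 24)
    want <- oracle_occurrence_count(probe, g$seq) == cfg$uniqueness_max_hits
    expect_identical(uniqueness_check(probe, g, cfg), want)
  }
})

test_that("selection takes the first passing candidate by anchor distance", {
  set.seed(61)
  g <- rse_genome(c(c = random_dna(3000)))
  w <- data.frame(chrom = "c", start = 1001, end = 2000, anchor = 1001)
  cands <- enumerate_candidates(w, g)
  # permissive screens isolate the ordering rule
  dcfg <- design_config(gc_min = 0, gc_max = 100, tm_min = -100, tm_max = 200)
  tcfg <- thermo_config(hairpin_min_stem = 50, dimer_max_run = 50,
                        dimer_3prime_max_run = 50)
  sel <- select_for_window(cands, g, dcfg, tcfg, chrom = "c")
  expect_equal(sel$start, 1001)
  expect_equal(sel$length, 27L)  # distance tie broken by longer oligo
  expect_equal(sel$sequence, substring(g$seq[["c"]], 1001, 1027))
})

test_that("select_for_window reports an unfillable window as NULL", {
  set.seed(67)
  g <- rse_genome(c(c = random_dna(3000)))
  w <- data.frame(chrom = "c", start = 1001, end = 2000, anchor = 1001)
  cands <- enumerate_candidates(w, g)
  dcfg <- design_config(gc_min = 99, gc_max = 100)  # nothing passes
  expect_null(select_for_window(cands, g, dcfg, thermo_config(),
                                chrom = "c"))
})

test_that("design_panel fills a clean synthetic region deterministically", {
  g <- make_genome(100000, seed = 71)
  region <- rse_interval("chr1", 1, 100000)
  panel <- design_panel(region, g)
  # round(100000/8000) = 12 windows + 1 terminal anchor site
  expect_equal(nrow(panel$oligos) + nrow(panel$unfilled), 13L)
  expect_gte(nrow(panel$oligos), 12L)

  # every emitted oligo is the genome substring at its coordinates and
  # re-passes every configured filter post hoc
  dcfg <- panel$design_config
  tcfg <- panel$thermo_config
  for (i in seq_len(nrow(panel$oligos))) {
    o <- panel$oligos[i, ]
    expect_equal(o$sequence,
                 substring(g$seq[[o$chrom]], o$start, o$end))
    gc <- gc_content(o$sequence)
    tm <- melting_temperature(o$sequence, tcfg)
    expect_true(gc >= dcfg$gc_min && gc <= dcfg$gc_max)
    expect_true(tm >= dcfg$tm_min && tm <= dcfg$tm_max)
    expect_false(hairpin_check(o$sequence, tcfg))
    expect_false(dimer_check(o$sequence, o$sequence, tcfg))
    expect_true(uniqueness_check(o$sequence, g, dcfg))
  }
  # oligos sorted, non-overlapping, pairwise dimer-compatible
  expect_true(all(diff(panel$oligos$start) > 0))
  expect_true(all(panel$oligos$start[-1] >
                    panel$oligos$end[-nrow(panel$oligos)]))
  n <- nrow(panel$oligos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_false(dimer_check(panel$oligos$sequence[i],
                               panel$oligos$sequence[j], tcfg))
    }
  }

  # byte-identical panel TSV on a rerun with identical inputs
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(panel, f1)
  write_panel_tsv(design_panel(region, g), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a fully masked window is reported unfilled without side effects", {
  g <- make_genome(50000, seed = 73)
  region <- rse_interval("chr1", 1, 50000)
  w <- parse_windows(region)  # 6 windows + terminal
  panel_clean <- design_panel(region, g)

  g2 <- g
  g2$mask$chr1[w$start[3]:w$end[3]] <- TRUE
  panel_masked <- design_panel(region, g2)
  expect_true(any(panel_masked$unfilled$start == w$start[3]))
  other_clean <- panel_clean$oligos[panel_clean$oligos$window_index != 2, ]
  other_masked <- panel_masked$oligos[panel_masked$oligos$window_index != 2, ]
  expect_equal(other_masked$sequence, other_clean$sequence)
})

test_that("overlapping input regions are rejected", {
  g <- make_genome(20000, seed = 79)
  expect_error(design_panel(list(rse_interval("chr1", 1, 9000),
                                 rse_interval("chr1", 8500, 18000)), g),
               "overlapping")
})
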
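# Independent brute-force oracles. Deliberately written with naive explicit
# loops and a different decomposition than the package implementations.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.comp1 <- c(A = "T", C = "G", G = "C", T = "A")

# hairpin: enumerate every placement of a min_stem-long perfect stem
# (left half starting at i, right half starting at j) and check the loop.
# A stem longer than min_stem exists iff a min_stem-long one does.
oracle_hairpin <- function(seq, min_stem, min_loop) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  for (i in seq_len(n)) {
    if (i + min_stem - 1 > n) break
    j_lo <- i + min_stem + min_loop
    if (j_lo + min_stem - 1 > n) next
    for (j in j_lo:(n - min_stem + 1)) {
      ok <- TRUE
      for (k in 0:(min_stem - 1)) {
        if (ch[i + k] != .comp1[[ch[j + min_stem - 1 - k]]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# dimer: slide b (3'->5') along a and walk every column explicitly,
# tracking run lengths and whether a run touches either 3' terminus
oracle_dimer <- function(a, b, max_run, run3) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av)
  nb <- length(bv)
  for (off in -(nb - 1):(na - 1)) {
    run <- 0L
    run_start_y <- NA_integer_
    for (y in seq_len(nb)) {
      x <- y + off
      if (x < 1 || x > na) next
      # column y of the reversed bottom strand carries b[nb - y + 1]
      pair <- av[x] == .comp1[[bv[nb - y + 1]]]
      if (pair) {
        if (run == 0L) run_start_y <- y
        run <- run + 1L
        if (run >= max_run) return(TRUE)
        a3 <- x == na             # a's 3'-terminal base in the run
        b3 <- run_start_y == 1L   # run started at b's 3'-terminal base
        if (run >= run3 && (a3 || b3)) return(TRUE)
      } else {
        run <- 0L
      }
    }
  }
  FALSE
}

# two-strand exact substring counter (overlap-aware)
oracle_occurrence_count <- function(pattern, genome_seqs) {
  cnt <- 0L
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", pattern), "",
                           fixed = TRUE)[[1]]), collapse = "")
  for (s in genome_seqs) {
    n <- nchar(s)
    k <- nchar(pattern)
    if (n < k) next
    subs <- substring(s, 1:(n - k + 1), k:n)
    cnt <- cnt + sum(subs == pattern) + sum(subs == rc)
  }
  cnt
}

# per-base depth by explicit per-alignment incrementing
oracle_depth <- function(alignments, chrom, start, end) {
  d <- integer(end - start + 1)
  for (i in seq_len(nrow(alignments))) {
    if (alignments$chrom[i] != chrom) next
    a <- max(alignments$start[i], start)
    b <- min(alignments$start[i] + alignments$aligned_length[i] - 1, end)
    if (a <= b) d[(a - start + 1):(b - start + 1)] <-
        d[(a - start + 1):(b - start + 1)] + 1L
  }
  d
}

# zero runs by explicit scan
oracle_gaps <- function(depth) {
  gaps <- list()
  in_gap <- FALSE
  g0 <- 0L
  for (i in seq_along(depth)) {
    if (depth[i] == 0L && !in_gap) {
      in_gap <- TRUE
      g0 <- i
    } else if (depth[i] != 0L && in_gap) {
      in_gap <- FALSE
      gaps[[length(gaps) + 1]] <- c(g0, i - 1L)
    }
  }
  if (in_gap) gaps[[length(gaps) + 1]] <- c(g0, length(depth))
  gaps
}

# candidate enumeration by checking every substring against the mask
oracle_candidates <- function(seq, mask, wstart, wend, len_min, len_max) {
  out <- list()
  for (k in len_min:len_max) {
    if (wend - wstart + 1 < k) next
    for (s in wstart:(wend - k + 1)) {
      if (!any(mask[s:(s + k - 1)])) {
        out[[length(out) + 1]] <- c(s, k)
      }
    }
  }
  out
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_file <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
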
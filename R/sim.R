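#' Capture-read simulation configuration
#'
#' Parameters for the error-free capture-read simulator. Each read is drawn
#' on-target with probability `p = enrichment * L / genome_bp` where `L` is
#' the target length, so that measuring fold enrichment on the simulated
#' read set recovers the configured value; `p` must be a probability, which
#' bounds the achievable enrichment at `genome_bp / L`. On-target reads are
#' fully contained in the target (that stratification is what makes `p`
#' exact rather than approximate at the boundaries).
#'
#' `genome_bp` defaults to the physical genome length but may be set larger
#' (e.g. the 1.6e9 zebrafish genome estimate while simulating from a few
#' hundred kb of physical sequence): the on-target probability then uses the
#' configured size while read sequences are drawn from the physical target
#' and flank sequence, which acts as a stand-in for the rest of the genome.
#'
#' @param target On-target [rse_interval()] (coordinates on the simulated
#'   genome).
#' @param n_reads Number of reads to draw.
#' @param enrichment Intended fold enrichment `E` (1 = uniform).
#' @param read_len Read length in bases (default 36, an early-generation
#'   short-read length).
#' @param seed RNG seed; fixed seed gives byte-identical read sets.
#' @param genome_bp Modeled genome size; `NULL` = physical length.
#' @return A list of class `rse_sim_config`.
#' @export
sim_config <- function(target, n_reads, enrichment = 1, read_len = 36L,
                       seed = 1L, genome_bp = NULL) {
  stopifnot(inherits(target, "rse_interval"), enrichment > 0)
  n_reads <- assert_count(n_reads, "n_reads", positive = TRUE)
  read_len <- assert_count(read_len, "read_len", positive = TRUE)
  if (read_len < 20) stop("read_len must be >= 20", call. = FALSE)
  seed <- assert_count(seed, "seed")
  structure(list(target = target, n_reads = n_reads, enrichment = enrichment,
                 read_len = as.integer(read_len), seed = as.integer(seed),
                 genome_bp = genome_bp),
            class = "rse_sim_config")
}

#' Generate a seeded random genome
#'
#' I.i.d. bases with G+C probability `gc_bias`; identical seeds give
#' identical genomes.
#'
#' @param genome_bp Genome size (>= 1000).
#' @param seed RNG seed.
#' @param gc_bias Probability that a base is G or C (default 0.5, uniform).
#' @param name Sequence name.
#' @return An [rse_genome()] with a single unmasked sequence.
#' @export
make_genome <- function(genome_bp, seed = 1L, gc_bias = 0.5, name = "chr1") {
  genome_bp <- assert_count(genome_bp, "genome_bp", positive = TRUE)
  if (genome_bp < 1000) stop("genome_bp must be >= 1000", call. = FALSE)
  stopifnot(gc_bias > 0, gc_bias < 1)
  set.seed(seed)
  p <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  s <- paste(sample(.DNA_BASES, genome_bp, replace = TRUE, prob = p),
             collapse = "")
  g <- list(s)
  names(g) <- name
  rse_genome(unlist(g))
}

#' Apply a deletion to a genome
#'
#' Removes `deletion_length` bases starting at `position` (1-based), e.g. to
#' build a mutant allele carrying a known deletion whose zero-coverage
#' signature the evaluation stage should recover.
#'
#' @param genome An [rse_genome()].
#' @param chrom Sequence name.
#' @param position 1-based first deleted base.
#' @param deletion_length Number of bases to remove (>= 1).
#' @return A new [rse_genome()]; the named sequence is shorter by
#'   `deletion_length`, flanking sequence unchanged.
#' @export
apply_deletion <- function(genome, chrom, position, deletion_length) {
  stopifnot(inherits(genome, "rse_genome"))
  position <- assert_count(position, "position", positive = TRUE)
  deletion_length <- assert_count(deletion_length, "deletion_length",
                                  positive = TRUE)
  if (!chrom %in% names(genome$seq)) {
    stop(sprintf("unknown sequence '%s'", chrom), call. = FALSE)
  }
  n <- nchar(genome$seq[[chrom]])
  if (position + deletion_length - 1 > n) {
    stop("deletion extends beyond sequence end", call. = FALSE)
  }
  seqs <- genome$seq
  mask <- genome$mask
  left <- substring(seqs[[chrom]], 1, position - 1)
  right <- substring(seqs[[chrom]], position + deletion_length, n)
  seqs[[chrom]] <- paste0(left, right)
  mask[[chrom]] <- mask[[chrom]][-(position:(position + deletion_length - 1))]
  rse_genome(seqs, mask = mask)
}

#' Find a deletion site with unambiguous alignment representation
#'
#' A deletion whose first (last) base equals the first (last) base of its
#' right (left) flank has micro-homology with the flank: the same allele is
#' produced by deleting a shifted window, and error-free reads crossing the
#' junction by one base still match the undeleted reference exactly, so the
#' zero-coverage signature shrinks below the nominal deletion length. This
#' helper scans forward from `near` for the first start position where
#' neither junction has single-base homology, which makes the deletion
#' coordinates (and its zero-coverage gap) well-defined.
#'
#' @param genome An [rse_genome()].
#' @param chrom Sequence name.
#' @param near 1-based position to start the scan at.
#' @param deletion_length Deletion size in bases.
#' @param max_scan How far to scan before giving up.
#' @return The first admissible 1-based deletion start position.
#' @export
find_deletion_site <- function(genome, chrom, near, deletion_length,
                               max_scan = 1000L) {
  stopifnot(inherits(genome, "rse_genome"))
  ch <- strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1]]
  for (pos in near:(near + max_scan)) {
    if (pos < 2 || pos + deletion_length > length(ch)) break
    left_ok <- ch[pos - 1] != ch[pos + deletion_length - 1]
    right_ok <- ch[pos + deletion_length] != ch[pos]
    if (left_ok && right_ok) return(pos)
  }
  stop("no unambiguous deletion site found in scan range", call. = FALSE)
}

#' Simulate capture-enriched reads with known truth
#'
#' Draws `n_reads` error-free reads from the genome: each read is on-target
#' (fully contained in `config$target`) with probability
#' `p = enrichment * L / genome_bp`, with a uniform start within its
#' stratum; strand is chosen uniformly and minus-strand reads are
#' reverse-complemented. Returns the reads together with their true source
#' alignments for oracle use.
#'
#' @param genome An [rse_genome()] (single or multiple sequences; the target
#'   must lie on one of them).
#' @param config An [sim_config()].
#' @return List with `reads` (named character vector of read sequences),
#'   `truth` (data.frame `read_id`, `chrom`, `start`, `aligned_length`,
#'   `strand` on the source genome), `n_on_target`, and `config`.
#' @export
simulate_capture_reads <- function(genome, config) {
  stopifnot(inherits(genome, "rse_genome"), inherits(config, "rse_sim_config"))
  tgt <- config$target
  rl <- config$read_len
  lens <- seq_lengths(genome)
  if (!tgt$chrom %in% names(lens)) {
    stop(sprintf("target on unknown sequence '%s'", tgt$chrom), call. = FALSE)
  }
  if (tgt$end > lens[[tgt$chrom]]) {
    stop("target outside genome", call. = FALSE)
  }
  L <- interval_length(tgt)
  if (L < rl) stop("target shorter than read length", call. = FALSE)
  G <- if (is.null(config$genome_bp)) sum(lens) else config$genome_bp
  p <- config$enrichment * L / G
  if (p > 1) {
    stop(sprintf("enrichment %.3g with L/G = %.3g gives on-target probability > 1",
                 config$enrichment, L / G), call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_reads
  on_target <- runif(n) < p
  # start positions admissible per stratum: on-target reads fully contained
  # in the target; off-target reads anywhere else (read fits the sequence)
  on_starts <- tgt$start:(tgt$end - rl + 1)
  off <- list()
  for (nm in names(lens)) {
    s_all <- 1:(lens[[nm]] - rl + 1)
    if (nm == tgt$chrom) {
      s_all <- s_all[s_all < tgt$start | s_all > tgt$end - rl + 1]
    }
    if (length(s_all)) off[[nm]] <- s_all
  }
  if (any(!on_target) && sum(lengths(off)) == 0L) {
    stop("no off-target sequence to draw from", call. = FALSE)
  }
  off_chrom_sizes <- lengths(off)
  chrom <- character(n)
  start <- numeric(n)
  chrom[on_target] <- tgt$chrom
  start[on_target] <- on_starts[sample.int(length(on_starts),
                                           sum(on_target), replace = TRUE)]
  n_off <- sum(!on_target)
  if (n_off > 0) {
    ci <- sample.int(length(off), n_off, replace = TRUE,
                     prob = off_chrom_sizes / sum(off_chrom_sizes))
    chrom[!on_target] <- names(off)[ci]
    off_start <- numeric(n_off)
    for (i in seq_along(off)) {
      sel <- ci == i
      if (any(sel)) {
        off_start[sel] <- off[[i]][sample.int(length(off[[i]]), sum(sel),
                                              replace = TRUE)]
      }
    }
    start[!on_target] <- off_start
  }
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  seqs <- character(n)
  for (nm in unique(chrom)) {
    idx <- chrom == nm
    seqs[idx] <- substring(genome$seq[[nm]], start[idx], start[idx] + rl - 1)
  }
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  ids <- sprintf("read_%06d", seq_len(n))
  names(seqs) <- ids
  list(reads = seqs,
       truth = data.frame(read_id = ids, chrom = chrom, start = start,
                          aligned_length = rl, strand = strand,
                          stringsAsFactors = FALSE),
       n_on_target = sum(on_target),
       config = config)
}

#' Exact-match read alignment
#'
#' Places each read at its unique exact match in the reference, searching
#' both strands. Reads with zero exact matches (e.g. reads spanning a
#' deletion junction, whose sequence does not exist in the undeleted
#' reference) or with multiple matches are reported unmapped/ambiguous and
#' excluded from the alignment table — sufficient machinery for
#' zero-coverage gap detection, which is what the evaluation stage needs.
#'
#' @param reads Character vector of equal-length A/C/G/T reads (as from
#'   [simulate_capture_reads()]).
#' @param genome Reference [rse_genome()].
#' @param chunk_size Reads matched per dictionary batch (memory control).
#' @return List with `alignments` (data.frame `read_id`, `chrom`, `start`,
#'   `aligned_length`, `strand`), `total_reads`, `unmapped` (no exact
#'   match), and `ambiguous` (multiple matches).
#' @export
align_exact <- function(reads, genome, chunk_size = 100000L) {
  stopifnot(inherits(genome, "rse_genome"), is.character(reads),
            length(reads) > 0)
  if (length(unique(nchar(reads))) != 1L) {
    stop("align_exact requires equal-length reads", call. = FALSE)
  }
  rl <- nchar(reads[1])
  ids <- if (is.null(names(reads))) {
    sprintf("read_%06d", seq_along(reads))
  } else {
    names(reads)
  }
  subjects <- lapply(genome$seq, Biostrings::DNAString)
  rc_subjects <- lapply(subjects, Biostrings::reverseComplement)
  nhits <- integer(length(reads))
  hit_chrom <- character(length(reads))
  hit_start <- numeric(length(reads))
  hit_strand <- character(length(reads))
  for (lo in seq(1L, length(reads), by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, length(reads))
    idx <- lo:hi
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(reads[idx])))
    for (nm in names(genome$seq)) {
      for (str in c("+", "-")) {
        s <- if (str == "+") subjects[[nm]] else rc_subjects[[nm]]
        mi <- Biostrings::matchPDict(pd, s)
        st <- Biostrings::startIndex(mi)  # list, NULL where no hit
        cnt <- lengths(st)
        has <- cnt > 0L
        first <- rep(NA_real_, length(idx))
        first[has] <- vapply(st[has], `[[`, 0L, 1L)
        if (str == "-") {
          # position on the forward strand of the reference
          first <- nchar(genome$seq[[nm]]) - (first + rl - 1) + 1
        }
        newly <- has & nhits[idx] == 0L
        hit_chrom[idx][newly] <- nm
        hit_start[idx][newly] <- first[newly]
        hit_strand[idx][newly] <- str
        nhits[idx] <- nhits[idx] + cnt
      }
    }
  }
  ok <- nhits == 1L
  list(alignments = data.frame(read_id = ids[ok], chrom = hit_chrom[ok],
                               start = hit_start[ok],
                               aligned_length = rep(rl, sum(ok)),
                               strand = hit_strand[ok],
                               stringsAsFactors = FALSE),
       total_reads = length(reads),
       unmapped = sum(nhits == 0L),
       ambiguous = sum(nhits > 1L))
}
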
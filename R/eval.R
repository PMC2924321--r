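#' Fold enrichment of a targeted-capture experiment
#'
#' `(reads_on_target / total_reads) / (interval_bp / genome_bp)`: the
#' fraction of reads mapping to the examined region divided by the fraction
#' of the genome that region occupies. 1 means no enrichment; the maximum is
#' `genome_bp / interval_bp`, attained when every read is on target. The
#' exact ratio is returned; reports round it half-up to an integer (see
#' [enrichment_report()]).
#'
#' @param reads_on_target Reads mapping to the examined interval.
#' @param total_reads Total reads in the experiment (mapped + unmapped).
#' @param interval_bp Size of the examined interval in bases.
#' @param genome_bp Genome size in bases; default the 1.6 Gb zebrafish
#'   genome estimate.
#' @return Exact fold-enrichment ratio.
#' @examples
#' round(fold_enrichment(280884, 5861492, 315606))  # 243
#' @export
fold_enrichment <- function(reads_on_target, total_reads, interval_bp,
                            genome_bp = 1.6e9) {
  reads_on_target <- assert_count(reads_on_target, "reads_on_target")
  total_reads <- assert_count(total_reads, "total_reads", positive = TRUE)
  if (interval_bp <= 0) stop("interval_bp must be positive", call. = FALSE)
  if (genome_bp < interval_bp) {
    stop("genome_bp must be at least interval_bp", call. = FALSE)
  }
  if (reads_on_target > total_reads) {
    stop("reads_on_target cannot exceed total_reads", call. = FALSE)
  }
  (reads_on_target / total_reads) / (interval_bp / genome_bp)
}

#' Per-base read-depth profile over an interval
#'
#' `depth[i]` is the number of alignments overlapping base `i` of the
#' interval; an alignment partially overlapping the interval contributes
#' only its overlapping bases.
#'
#' @param alignments Data.frame with columns `chrom`, `start`,
#'   `aligned_length` (as from [read_alignments()] or [align_exact()]).
#' @param interval An [rse_interval()].
#' @return Object of class `rse_depth_profile`: list with `interval` and
#'   integer vector `depth` of length `interval_length(interval)`.
#' @export
depth_profile <- function(alignments, interval) {
  stopifnot(inherits(interval, "rse_interval"), is.data.frame(alignments))
  len <- interval_length(interval)
  al <- alignments[alignments$chrom == interval$chrom, , drop = FALSE]
  depth <- if (nrow(al) == 0L) {
    integer(len)
  } else {
    ir <- IRanges::IRanges(start = al$start, width = al$aligned_length)
    # shift interval start to 1 and clip coverage to the interval
    as.integer(IRanges::coverage(ir, shift = 1 - interval$start, width = len))
  }
  structure(list(interval = interval, depth = depth),
            class = "rse_depth_profile")
}

#' @export
print.rse_depth_profile <- function(x, ...) {
  cat(sprintf("<rse_depth_profile> %s:%d-%d  mean depth %.2f, %.2f%% covered\n",
              x$interval$chrom, x$interval$start, x$interval$end,
              mean(x$depth), coverage_fraction(x)))
  invisible(x)
}

#' Fraction of interval bases at or above a depth threshold
#'
#' @param profile An [depth_profile()].
#' @param min_depth Minimum depth to count a base as covered (>= 1).
#' @return Percentage in `[0, 100]`.
#' @export
coverage_fraction <- function(profile, min_depth = 1L) {
  stopifnot(inherits(profile, "rse_depth_profile"), min_depth >= 1)
  100 * sum(profile$depth >= min_depth) / length(profile$depth)
}

#' Zero-coverage gaps in a depth profile
#'
#' Maximal runs of zero depth, the signature by which genomic deletions show
#' up when mutant reads are aligned to an undeleted reference (a planted or
#' real deletion of `d` bases leaves exactly `d` reference bases that no
#' error-free read can cover). Gaps are reported 1-based inclusive in genome
#' coordinates, sorted by position.
#'
#' @param profile An [depth_profile()].
#' @param min_len,max_len Optional length filter for triaging small gaps.
#' @return Data.frame with columns `chrom`, `start`, `end`, `length`.
#' @export
find_gaps <- function(profile, min_len = 1L, max_len = Inf) {
  stopifnot(inherits(profile, "rse_depth_profile"))
  r <- rle(profile$depth == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len & r$lengths <= max_len
  data.frame(chrom = rep(profile$interval$chrom, sum(keep)),
             start = profile$interval$start + starts[keep] - 1,
             end = profile$interval$start + ends[keep] - 1,
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Write gaps as a BED file (0-based half-open)
#'
#' @param gaps Data.frame from [find_gaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaps_bed <- function(gaps, path) {
  gaps$name <- sprintf("gap_%dbp", gaps$length)
  write_bed(gaps, path)
}

#' Recombination distance in centimorgans
#'
#' `100 * recombinants / meioses`. The reported value is truncated (not
#' rounded) at one decimal, the convention under which 27 recombinants in
#' 976 meioses print as 2.7 cM; set `truncate = FALSE` for the exact value.
#'
#' @param recombinants Recombination events observed.
#' @param meioses Meioses scored (> 0).
#' @param truncate Truncate to one decimal (default).
#' @return Distance in cM.
#' @examples
#' recombination_distance(27, 976)  # 2.7
#' @export
recombination_distance <- function(recombinants, meioses, truncate = TRUE) {
  recombinants <- assert_count(recombinants, "recombinants")
  meioses <- assert_count(meioses, "meioses", positive = TRUE)
  if (recombinants > meioses) {
    stop("recombinants cannot exceed meioses", call. = FALSE)
  }
  cm <- 100 * recombinants / meioses
  if (truncate) trunc_decimal(cm, 1) else cm
}

#' Full enrichment report for a capture experiment
#'
#' Counts on-target reads (overlap of at least one base by default, or full
#' containment with `overlap = "within"`), computes fold enrichment (exact
#' and rounded half-up to integer, the convention in which the worked
#' examples print as 243, 72 and 43), mean depth, and coverage fraction over
#' the interval.
#'
#' @param alignments Data.frame of mapped reads (`chrom`, `start`,
#'   `aligned_length`).
#' @param total_reads Total read count including unmapped reads.
#' @param interval Examined [rse_interval()].
#' @param genome_bp Genome size (default 1.6e9).
#' @param min_depth Depth threshold for the coverage fraction.
#' @param overlap `"any"` (>= 1 base) or `"within"` (fully contained).
#' @return Object of class `rse_enrichment_report`: list with
#'   `reads_on_target`, `total_reads`, `interval_bp`, `genome_bp`,
#'   `fold_enrichment` (exact), `fold_enrichment_rounded`, `mean_depth`,
#'   `coverage_fraction_pct`.
#' @export
enrichment_report <- function(alignments, total_reads, interval,
                              genome_bp = 1.6e9, min_depth = 1L,
                              overlap = c("any", "within")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(interval, "rse_interval"))
  ends <- alignments$start + alignments$aligned_length - 1
  on_chrom <- alignments$chrom == interval$chrom
  on_target <- if (overlap == "any") {
    on_chrom & alignments$start <= interval$end & ends >= interval$start
  } else {
    on_chrom & alignments$start >= interval$start & ends <= interval$end
  }
  prof <- depth_profile(alignments, interval)
  fe <- fold_enrichment(sum(on_target), total_reads,
                        interval_length(interval), genome_bp)
  structure(list(reads_on_target = sum(on_target),
                 total_reads = total_reads,
                 interval_bp = interval_length(interval),
                 genome_bp = genome_bp,
                 fold_enrichment = fe,
                 fold_enrichment_rounded = round_half_up(fe),
                 mean_depth = mean(prof$depth),
                 coverage_fraction_pct = coverage_fraction(prof, min_depth)),
            class = "rse_enrichment_report")
}

#' @export
print.rse_enrichment_report <- function(x, ...) {
  cat(sprintf(paste0("<rse_enrichment_report> %d/%d reads on a %s bp target",
                     " (genome %s bp)\n  fold enrichment %.2f (reported %d);",
                     " mean depth %.2f; %.2f%% covered\n"),
              x$reads_on_target, x$total_reads,
              format(x$interval_bp, big.mark = ","),
              format(x$genome_bp, big.mark = ",", scientific = FALSE),
              x$fold_enrichment, x$fold_enrichment_rounded, x$mean_depth,
              x$coverage_fraction_pct))
  invisible(x)
}
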
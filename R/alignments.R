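#' Read aligned-read records
#'
#' Reads a minimal SAM subset (header lines skipped; RNAME, POS, FLAG and the
#' SEQ field length are used; CIGAR is ignored) or a 4+-column BED of aligned
#' read intervals. Records flagged unmapped (SAM FLAG bit 0x4, or RNAME
#' `"*"`) are excluded from the alignment table but counted in `total_reads`:
#' the fold-enrichment denominator is the total number of reads, mapped or
#' not.
#'
#' @param path Path to the alignment file.
#' @param format `"sam_minimal"` or `"bed"`.
#' @param genome Optional [rse_genome()]; if supplied, records are validated
#'   against its sequence names and lengths.
#' @return A list with elements `alignments` (data.frame with columns
#'   `read_id`, `chrom`, `start` (1-based leftmost), `aligned_length`,
#'   `strand`), `total_reads`, and `unmapped`.
#' @export
read_alignments <- function(path, format = c("sam_minimal", "bed"),
                            genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "bed") {
    df <- read_bed(path)
    al <- data.frame(read_id = df$name, chrom = df$chrom, start = df$start,
                     aligned_length = df$end - df$start + 1,
                     strand = "+", stringsAsFactors = FALSE)
    out <- list(alignments = al, total_reads = nrow(al), unmapped = 0L)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0L) {
      return(list(alignments = data.frame(read_id = character(),
                                          chrom = character(),
                                          start = numeric(),
                                          aligned_length = numeric(),
                                          strand = character(),
                                          stringsAsFactors = FALSE),
                  total_reads = 0L, unmapped = 0L))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 0L) < 11L
    if (any(short)) {
      stop(sprintf("SAM record with fewer than 11 fields at line %d",
                   which(short)[1]), call. = FALSE)
    }
    flag <- as.integer(vapply(fields, `[[`, "", 2L))
    rname <- vapply(fields, `[[`, "", 3L)
    pos <- as.numeric(vapply(fields, `[[`, "", 4L))
    seqf <- vapply(fields, `[[`, "", 10L)
    if (any(pos < 0, na.rm = TRUE)) stop("negative position in SAM",
                                         call. = FALSE)
    unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
    al <- data.frame(read_id = vapply(fields, `[[`, "", 1L)[!unmapped],
                     chrom = rname[!unmapped],
                     start = pos[!unmapped],
                     aligned_length = nchar(seqf[!unmapped]),
                     strand = ifelse(bitwAnd(flag[!unmapped], 16L) != 0L,
                                     "-", "+"),
                     stringsAsFactors = FALSE)
    out <- list(alignments = al, total_reads = length(lines),
                unmapped = sum(unmapped))
  }
  if (!is.null(genome)) validate_alignments(out$alignments, genome)
  out
}

# check AlignmentRecord invariants against a genome
validate_alignments <- function(alignments, genome) {
  lens <- seq_lengths(genome)
  bad <- !alignments$chrom %in% names(lens)
  if (any(bad)) {
    stop(sprintf("alignment on unknown sequence '%s'",
                 alignments$chrom[bad][1]), call. = FALSE)
  }
  ends <- alignments$start + alignments$aligned_length - 1
  over <- ends > lens[alignments$chrom]
  if (any(alignments$start < 1) || any(over)) {
    stop("alignment extends beyond sequence bounds", call. = FALSE)
  }
  if (any(alignments$aligned_length < 1)) {
    stop("aligned_length must be positive", call. = FALSE)
  }
  invisible(alignments)
}

# write alignments as a 6-column BED (0-based half-open)
write_alignments_bed <- function(alignments, path) {
  df <- data.frame(chrom = alignments$chrom,
                   start = alignments$start,
                   end = alignments$start + alignments$aligned_length - 1,
                   name = alignments$read_id)
  bed <- data.frame(df$chrom,
                    format(df$start - 1, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$name, 0L, alignments$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
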
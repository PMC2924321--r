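#' Genome with per-base design mask
#'
#' A genome is a set of named uppercase DNA sequences (A/C/G/T/N) together
#' with one logical mask vector per sequence; `TRUE` marks a base excluded
#' from oligo design (repeat-/SNP-masked positions, plus every `N`, which can
#' never be a capture point).
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   sequences. Lowercase is accepted and uppercased; it does NOT set mask
#'   flags here (see [read_fasta()] for soft-mask handling).
#' @param mask Optional named list of logical vectors, one per sequence, the
#'   same length as the sequence. `N` bases are masked regardless.
#' @return An object of class `rse_genome` with fields `seq` (named character
#'   vector, uppercase) and `mask` (named list of logical vectors).
#' @export
rse_genome <- function(sequences, mask = NULL) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences))
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop(sprintf("duplicate sequence name: %s",
                 names(sequences)[duplicated(names(sequences))][1]),
         call. = FALSE)
  }
  seqs <- toupper(sequences)
  assert_dna(seqs, allow_n = TRUE, what = "genome sequence")
  msk <- lapply(names(seqs), function(nm) {
    n <- nchar(seqs[[nm]])
    m <- if (is.null(mask)) rep(FALSE, n) else mask[[nm]]
    if (is.null(m)) m <- rep(FALSE, n)
    if (length(m) != n) {
      stop(sprintf("mask length %d != sequence length %d for '%s'",
                   length(m), n, nm), call. = FALSE)
    }
    # N can never be a capture point
    m | (strsplit(seqs[[nm]], "", fixed = TRUE)[[1]] == "N")
  })
  names(msk) <- names(seqs)
  structure(list(seq = seqs, mask = msk), class = "rse_genome")
}

#' @export
print.rse_genome <- function(x, ...) {
  cat(sprintf("<rse_genome> %d sequence(s), %s bp total, %s bp masked\n",
              length(x$seq),
              format(sum(nchar(x$seq)), big.mark = ","),
              format(sum(vapply(x$mask, sum, 0)), big.mark = ",")))
  invisible(x)
}

#' Lengths of genome sequences
#' @param genome An [rse_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "rse_genome"))
  nchar(genome$seq)
}

# extract the forward-strand substring for an interval
genome_subseq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "rse_genome"))
  if (!chrom %in% names(genome$seq)) {
    stop(sprintf("unknown sequence '%s'", chrom), call. = FALSE)
  }
  n <- nchar(genome$seq[[chrom]])
  if (start < 1 || end > n || start > end) {
    stop(sprintf("interval %s:%d-%d out of bounds (length %d)",
                 chrom, start, end, n), call. = FALSE)
  }
  substring(genome$seq[[chrom]], start, end)
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased for storage. With `mask_mode = "softmask"`,
#' bases that are lowercase in the file (the soft-mask convention for
#' repeat- and SNP-masked positions) are flagged as masked, i.e. excluded
#' as capture points. `N` bases are always masked.
#'
#' @param path Path to a FASTA file.
#' @param mask_mode `"softmask"` to convert lowercase to mask flags, or
#'   `"none"` to start with an all-FALSE mask.
#' @return An [rse_genome()].
#' @export
read_fasta <- function(path, mask_mode = c("softmask", "none")) {
  mask_mode <- match.arg(mask_mode)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  # BStringSet preserves case, which DNAStringSet would normalize away
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (length(set) == 0L) stop(sprintf("empty FASTA: %s", path), call. = FALSE)
  # FASTA headers: name = first whitespace-delimited token
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate sequence name in %s: %s", path,
                 nms[duplicated(nms)][1]), call. = FALSE)
  }
  raw <- as.character(set)
  names(raw) <- nms
  mask <- NULL
  if (mask_mode == "softmask") {
    mask <- lapply(raw, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch %in% c("a", "c", "g", "t", "n")
    })
  }
  rse_genome(raw, mask = mask)
}

#' Write a genome to FASTA
#'
#' Masked bases are written lowercase (soft-masked), so
#' `read_fasta(write_fasta(g), "softmask")` round-trips both the sequence
#' and the mask.
#'
#' @param genome An [rse_genome()].
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "rse_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    ch <- strsplit(genome$seq[[nm]], "", fixed = TRUE)[[1]]
    m <- genome$mask[[nm]]
    ch[m] <- tolower(ch[m])
    s <- paste(ch, collapse = "")
    writeLines(paste0(">", nm), con)
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Mask genome positions from a BED file
#'
#' BED intervals (0-based half-open, the standard convention) are converted
#' to 1-based inclusive coordinates and OR-ed into the existing mask.
#'
#' @param genome An [rse_genome()].
#' @param bed_path Path to a BED file of intervals to exclude from design.
#' @return A new [rse_genome()] with the union mask.
#' @export
apply_mask_bed <- function(genome, bed_path) {
  stopifnot(inherits(genome, "rse_genome"))
  df <- read_bed(bed_path)
  if (nrow(df) == 0L) return(genome)
  lens <- seq_lengths(genome)
  mask <- genome$mask
  for (i in seq_len(nrow(df))) {
    chrom <- df$chrom[i]
    if (!chrom %in% names(lens)) {
      stop(sprintf("BED interval on unknown sequence '%s'", chrom),
           call. = FALSE)
    }
    if (df$end[i] > lens[[chrom]]) {
      stop(sprintf("BED interval %s:%d-%d beyond sequence end (%d)",
                   chrom, df$start[i], df$end[i], lens[[chrom]]),
           call. = FALSE)
    }
    mask[[chrom]][df$start[i]:df$end[i]] <- TRUE
  }
  out <- genome
  out$mask <- mask
  out
}
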
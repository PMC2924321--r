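#' Genomic interval (1-based, inclusive)
#'
#' All user-facing coordinates in this package are 1-based and inclusive at
#' both ends, matching the convention in which targeted regions and oligo
#' start positions are printed (e.g. `chr19:32,557,347-32,877,103`). BED
#' input/output converts to/from the 0-based half-open BED convention at the
#' boundary.
#'
#' @param chrom Sequence (chromosome) name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return An object of class `rse_interval` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' iv <- rse_interval("chr19", 32557347, 32877103)
#' interval_length(iv)  # 319757
#' @export
rse_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- assert_count(start, "start", positive = TRUE)
  end <- assert_count(end, "end", positive = TRUE)
  if (start > end) {
    stop(sprintf("invalid interval %s:%d-%d (start > end)", chrom, start, end),
         call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "rse_interval")
}

#' @export
print.rse_interval <- function(x, ...) {
  cat(sprintf("<rse_interval> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of an interval in bases
#'
#' @param interval An [rse_interval()].
#' @return `end - start + 1`.
#' @export
interval_length <- function(interval) {
  stopifnot(inherits(interval, "rse_interval"))
  interval$end - interval$start + 1
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators
#' (`"chr19:32,557,347-32,877,103"`).
#'
#' @param x Region string.
#' @return An [rse_interval()].
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x2 <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x2, regexec("^(.+):([0-9]+)-([0-9]+)$", x2))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse region '%s' (expected chrom:start-end)", x),
         call. = FALSE)
  }
  rse_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

# read a BED file (0-based half-open) into a data.frame with 1-based
# inclusive columns chrom/start/end (+ name if present)
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]) + 1,  # 0-based -> 1-based
                    end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("BED interval with start >= end required",
                                     call. = FALSE)
  out$name <- if (ncol(df) >= 4L) as.character(df[[4]]) else
    paste0("iv", seq_len(nrow(out)))
  out
}

# write 1-based inclusive intervals (data.frame chrom/start/end[/name]) as BED
write_bed <- function(df, path) {
  bed <- data.frame(df$chrom, format(df$start - 1, scientific = FALSE,
                                     trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name)) bed[[4]] <- df$name
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read target intervals from a BED file
#'
#' @param path Path to a BED file (0-based half-open).
#' @return A list of [rse_interval()] objects, in file order.
#' @export
read_targets_bed <- function(path) {
  df <- read_bed(path)
  lapply(seq_len(nrow(df)),
         function(i) rse_interval(df$chrom[i], df$start[i], df$end[i]))
}
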
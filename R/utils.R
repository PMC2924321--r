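#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats runif
#' @importFrom utils read.table write.table packageVersion
NULL

# round half away from zero (base round() is half-to-even); the convention
# used for reported fold-enrichment values
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# truncate (floor) at `digits` decimals; used for cM reporting
trunc_decimal <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m) / m
}

.DNA_BASES <- c("A", "C", "G", "T")

# scalar/vector reverse complement on plain character strings
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

assert_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s: %s", what,
                 if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                 x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (positive) 1 else 0) {
    stop(sprintf("'%s' must be a single %s integer", what,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.numeric(x))
}
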
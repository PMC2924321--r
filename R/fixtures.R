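#' Load the packaged capture-oligo tables
#'
#' The package ships the published capture panels for the zebrafish *macf1*
#' locus (Zv7/danRer5 chromosome 19) as a plain-text table: the 41-oligo set
#' used for the first (319.8 kb) capture and the 36 additional oligos used
#' to extend it to the 613.9 kb second capture (77 oligos in all). Start
#' positions are 1-based reference coordinates; sequences are stored as
#' printed, including one record with a stray internal space, which is
#' stripped before validation.
#'
#' Every record is validated on load: after whitespace stripping the
#' sequence must be A/C/G/T only and 22-27 nt long.
#'
#' @param set `"first"` (41 records), `"additional"` (36), or `"all"` (77).
#' @param path Path to the fixture TSV; defaults to the packaged copy.
#' @return A data.frame with columns `start_position`, `sequence` (stripped),
#'   `set_label`, `length`.
#' @examples
#' oligos <- load_fixture_oligos("first")
#' nrow(oligos)  # 41
#' @export
load_fixture_oligos <- function(set = c("all", "first", "additional"),
                                path = NULL) {
  set <- match.arg(set)
  if (is.null(path)) {
    path <- system.file("extdata", "capture_oligos.tsv",
                        package = "rsecapture", mustWork = TRUE)
  }
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("numeric", "character", "character"))
  df$sequence <- gsub("[[:space:]]+", "", df$sequence)
  assert_dna(df$sequence, what = "fixture oligo sequence")
  df$length <- nchar(df$sequence)
  bad <- df$length < 22L | df$length > 27L
  if (any(bad)) {
    stop(sprintf("fixture oligo at %d has invalid length %d (must be 22-27)",
                 df$start_position[bad][1], df$length[bad][1]), call. = FALSE)
  }
  if (set != "all") df <- df[df$set_label == set, , drop = FALSE]
  rownames(df) <- NULL
  df
}
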
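#' Panel design configuration
#'
#' Numeric criteria for capture-oligo panel design: one oligo per window at
#' approximately `spacing_bp` intervals (default 8 kb), oligo length 22-27
#' nt, GC content 48-52% (inclusive at both bounds), Tm 57-61 degrees C, and
#' genome-wide uniqueness. Regions of up to `max_region_bp` (default 1 Mb)
#' are accepted.
#'
#' @param spacing_bp Target inter-oligo spacing in bases.
#' @param len_min,len_max Oligo length bounds.
#' @param gc_min,gc_max GC bounds in percent, inclusive.
#' @param tm_min,tm_max Tm bounds in degrees C, inclusive.
#' @param anchor_end Add a terminal design site at the region end, so the
#'   last oligo sits at the far boundary of the region.
#' @param max_region_bp Largest accepted input region.
#' @param uniqueness_seed_len Minimum queryable length for the uniqueness
#'   check.
#' @param uniqueness_max_hits Allowed genome-wide exact-match count (the
#'   design site itself; default 1).
#' @return A list of class `rse_design_config`.
#' @export
design_config <- function(spacing_bp = 8000L, len_min = 22L, len_max = 27L,
                          gc_min = 48, gc_max = 52, tm_min = 57, tm_max = 61,
                          anchor_end = TRUE, max_region_bp = 1000000L,
                          uniqueness_seed_len = 16L,
                          uniqueness_max_hits = 1L) {
  stopifnot(len_min > 0, len_min <= len_max, gc_min <= gc_max,
            tm_min <= tm_max, spacing_bp > len_max, max_region_bp > 0,
            uniqueness_seed_len > 0, uniqueness_max_hits >= 1,
            is.logical(anchor_end), length(anchor_end) == 1L)
  structure(list(spacing_bp = as.numeric(spacing_bp),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 anchor_end = anchor_end,
                 max_region_bp = as.numeric(max_region_bp),
                 uniqueness_seed_len = as.integer(uniqueness_seed_len),
                 uniqueness_max_hits = as.integer(uniqueness_max_hits)),
            class = "rse_design_config")
}

#' Parse a region into design windows
#'
#' The region is split into `n = max(1, round(length / spacing_bp))` windows
#' of equal size (within one base); the window start is the preferred design
#' position (anchor). With `anchor_end`, an extra terminal design site
#' anchored at `region_end - len_max + 1` is appended so the panel also
#' covers the far boundary; its lookback window overlaps the last base
#' window and is flagged `terminal`.
#'
#' @param region An [rse_interval()].
#' @param config An [design_config()].
#' @return A data.frame with columns `index` (0-based), `chrom`, `start`,
#'   `end`, `anchor`, `terminal`. The non-terminal windows are disjoint and
#'   their union is exactly the region.
#' @examples
#' w <- parse_windows(rse_interval("chr19", 32557347, 32877103))
#' nrow(w)  # 41 design sites for the 319,757 bp region at 8 kb spacing
#' @export
parse_windows <- function(region, config = design_config()) {
  stopifnot(inherits(region, "rse_interval"))
  len <- interval_length(region)
  if (len > config$max_region_bp) {
    stop(sprintf(paste0("region %s:%d-%d is %d bp, larger than max_region_bp",
                        " = %d; split it into smaller regions"),
                 region$chrom, region$start, region$end, len,
                 config$max_region_bp), call. = FALSE)
  }
  n <- max(1, round(len / config$spacing_bp))
  bounds <- region$start + round((0:n) * len / n)  # length n+1
  starts <- bounds[1:n]
  ends <- bounds[2:(n + 1)] - 1
  ends[n] <- region$end
  out <- data.frame(index = 0:(n - 1), chrom = region$chrom,
                    start = starts, end = ends, anchor = starts,
                    terminal = FALSE, stringsAsFactors = FALSE)
  if (config$anchor_end && len >= config$len_max) {
    term_start <- max(region$start, region$end - config$spacing_bp + 1)
    out <- rbind(out, data.frame(index = n, chrom = region$chrom,
                                 start = term_start, end = region$end,
                                 anchor = region$end - config$len_max + 1,
                                 terminal = TRUE, stringsAsFactors = FALSE))
  }
  out
}

#' Enumerate candidate oligos in a window
#'
#' All substrings with length in `[len_min, len_max]` lying fully inside the
#' window and containing no masked base (repeat-/SNP-masked positions and
#' every `N` are excluded as capture points). Candidates are ordered by
#' distance of their start from the window anchor, ties broken by longer
#' oligo then lexicographically smaller sequence, so selection is fully
#' deterministic.
#'
#' @param window A one-row data.frame as returned by [parse_windows()] (or a
#'   list with `chrom`, `start`, `end`, `anchor`).
#' @param genome An [rse_genome()].
#' @param config An [design_config()].
#' @return A data.frame with columns `start`, `end`, `length`, `sequence`,
#'   `dist`, ordered as described; zero rows if the window is fully masked.
#' @export
enumerate_candidates <- function(window, genome, config = design_config()) {
  stopifnot(inherits(genome, "rse_genome"))
  chrom <- window$chrom[1]
  wstart <- window$start[1]
  wend <- window$end[1]
  anchor <- window$anchor[1]
  if (!chrom %in% names(genome$seq)) {
    stop(sprintf("unknown sequence '%s'", chrom), call. = FALSE)
  }
  if (wstart < 1 || wend > nchar(genome$seq[[chrom]])) {
    stop("window outside genome bounds", call. = FALSE)
  }
  mask <- genome$mask[[chrom]]
  cm <- c(0, cumsum(mask))  # cm[i+1] = masked bases in 1..i
  starts <- integer(0)
  lens <- integer(0)
  for (k in config$len_min:config$len_max) {
    if (wend - wstart + 1 < k) next
    s <- wstart:(wend - k + 1)
    nmasked <- cm[s + k] - cm[s]
    keep <- s[nmasked == 0]
    starts <- c(starts, keep)
    lens <- c(lens, rep(k, length(keep)))
  }
  if (length(starts) == 0L) {
    return(data.frame(start = numeric(), end = numeric(), length = integer(),
                      sequence = character(), dist = numeric(),
                      stringsAsFactors = FALSE))
  }
  seqs <- substring(genome$seq[[chrom]], starts, starts + lens - 1)
  out <- data.frame(start = starts, end = starts + lens - 1, length = lens,
                    sequence = seqs, dist = abs(starts - anchor),
                    stringsAsFactors = FALSE)
  out <- out[order(out$dist, -out$length, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide uniqueness check
#'
#' `TRUE` iff the number of exact occurrences of the sequence in the genome,
#' counting both strands, equals `uniqueness_max_hits` (the design site
#' itself, by default). This is the deterministic exact-match analogue of
#' screening candidate oligos against a local alignment server to ensure
#' they match only one region.
#'
#' @param sequence A/C/G/T string, at least `uniqueness_seed_len` long.
#' @param genome An [rse_genome()].
#' @param config An [design_config()].
#' @return Logical.
#' @export
uniqueness_check <- function(sequence, genome, config = design_config()) {
  stopifnot(inherits(genome, "rse_genome"))
  assert_dna(sequence, what = "sequence")
  if (nchar(sequence) < config$uniqueness_seed_len) {
    stop(sprintf("sequence shorter than uniqueness_seed_len (%d)",
                 config$uniqueness_seed_len), call. = FALSE)
  }
  subject <- Biostrings::DNAStringSet(genome$seq)
  hits <- sum(Biostrings::vcountPattern(sequence, subject)) +
    sum(Biostrings::vcountPattern(revcomp(sequence), subject))
  hits == config$uniqueness_max_hits
}

# per-candidate filter battery, cheap tests first; `accepted` is a
# data.frame of already-accepted oligos (cross-reactivity + overlap checks)
.candidate_passes <- function(cand, genome, design_cfg, thermo_cfg,
                              accepted = NULL) {
  gc <- gc_content(cand$sequence)
  if (gc < design_cfg$gc_min || gc > design_cfg$gc_max) return(NULL)
  tm <- melting_temperature(cand$sequence, thermo_cfg)
  if (tm < design_cfg$tm_min || tm > design_cfg$tm_max) return(NULL)
  if (hairpin_check(cand$sequence, thermo_cfg)) return(NULL)
  if (dimer_check(cand$sequence, cand$sequence, thermo_cfg)) return(NULL)
  if (!uniqueness_check(cand$sequence, genome, design_cfg)) return(NULL)
  if (!is.null(accepted) && nrow(accepted) > 0) {
    same <- accepted$chrom == cand$chrom
    if (any(same & accepted$start <= cand$end & accepted$end >= cand$start)) {
      return(NULL)  # overlap with an already-placed oligo
    }
    for (s in accepted$sequence) {
      if (dimer_check(s, cand$sequence, thermo_cfg)) return(NULL)
    }
  }
  data.frame(cand, gc_pct = gc, tm_c = tm, hairpin_fail = FALSE,
             selfdimer_fail = FALSE, unique = TRUE,
             stringsAsFactors = FALSE)
}

#' Select the oligo for one window
#'
#' Walks the anchor-ordered candidate list and returns the first candidate
#' passing the GC range, Tm range, hairpin, self-dimer, and uniqueness
#' screens (plus, when `accepted` is given, non-overlap and cross-dimer
#' compatibility with already-accepted oligos). An unfilled window is a
#' result, not an error: `NULL` is returned so the caller can report it for
#' redesign with relaxed per-window settings.
#'
#' @param candidates Data.frame from [enumerate_candidates()].
#' @param genome An [rse_genome()].
#' @param design_cfg An [design_config()].
#' @param thermo_cfg An [thermo_config()].
#' @param chrom Sequence name of the candidates.
#' @param accepted Optional data.frame of already-accepted oligos
#'   (columns `chrom`, `start`, `end`, `sequence`).
#' @return A one-row data.frame with position, sequence and metrics, or
#'   `NULL` if no candidate passes.
#' @export
select_for_window <- function(candidates, genome,
                              design_cfg = design_config(),
                              thermo_cfg = thermo_config(),
                              chrom = NULL, accepted = NULL) {
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    cand$chrom <- if (is.null(chrom)) cand$chrom else chrom
    hit <- .candidate_passes(cand, genome, design_cfg, thermo_cfg, accepted)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Design a capture-oligo panel
#'
#' The full design pipeline: each region is parsed into ~`spacing_bp`
#' windows ([parse_windows()]); candidates are enumerated from unmasked
#' sequence ([enumerate_candidates()]); the candidate nearest each anchor
#' that passes every per-oligo screen is selected; and the multiplexed set
#' is cross-screened as it grows: a candidate must also pass [dimer_check()]
#' against every earlier-placed oligo, so on a cross-reactivity conflict the
#' earlier oligo is kept and the later window falls through to its next
#' candidate. Windows with no passing candidate are reported as unfilled.
#'
#' @param regions An [rse_interval()] or list of them (non-overlapping).
#' @param genome An [rse_genome()].
#' @param design_cfg An [design_config()].
#' @param thermo_cfg An [thermo_config()].
#' @return An object of class `rse_panel`: list with `oligos` (data.frame:
#'   `name`, `chrom`, `start`, `end`, `strand`, `sequence`, `length`,
#'   `gc_pct`, `tm_c`, `window_index`, `unique`, `flags`), `unfilled`
#'   (data.frame of window coordinates), `regions`, `design_config`,
#'   `thermo_config`.
#' @export
design_panel <- function(regions, genome, design_cfg = design_config(),
                         thermo_cfg = thermo_config()) {
  if (inherits(regions, "rse_interval")) regions <- list(regions)
  stopifnot(length(regions) >= 1,
            all(vapply(regions, inherits, TRUE, "rse_interval")))
  # reject overlapping input regions
  if (length(regions) > 1) {
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i < j && regions[[i]]$chrom == regions[[j]]$chrom &&
            regions[[i]]$start <= regions[[j]]$end &&
            regions[[i]]$end >= regions[[j]]$start) {
          stop(sprintf("overlapping regions: %s:%d-%d and %s:%d-%d",
                       regions[[i]]$chrom, regions[[i]]$start,
                       regions[[i]]$end, regions[[j]]$chrom,
                       regions[[j]]$start, regions[[j]]$end), call. = FALSE)
        }
      }
    }
  }
  accepted <- NULL
  unfilled <- list()
  for (ri in seq_along(regions)) {
    windows <- parse_windows(regions[[ri]], design_cfg)
    for (wi in seq_len(nrow(windows))) {
      w <- windows[wi, , drop = FALSE]
      cands <- enumerate_candidates(w, genome, design_cfg)
      sel <- select_for_window(cands, genome, design_cfg, thermo_cfg,
                               chrom = w$chrom, accepted = accepted)
      if (is.null(sel)) {
        unfilled[[length(unfilled) + 1]] <-
          data.frame(chrom = w$chrom, start = w$start, end = w$end,
                     name = sprintf("region%d_window%d", ri, w$index),
                     stringsAsFactors = FALSE)
      } else {
        sel$window_index <- w$index
        sel$region <- ri
        accepted <- rbind(accepted, sel)
      }
    }
  }
  oligos <- if (is.null(accepted)) {
    data.frame(name = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), sequence = character(),
               length = integer(), gc_pct = numeric(), tm_c = numeric(),
               window_index = integer(), unique = logical(),
               flags = character(), stringsAsFactors = FALSE)
  } else {
    accepted <- accepted[order(accepted$chrom, accepted$start), , drop = FALSE]
    data.frame(name = sprintf("oligo_%03d", seq_len(nrow(accepted))),
               chrom = accepted$chrom, start = accepted$start,
               end = accepted$end, strand = "+",
               sequence = accepted$sequence, length = accepted$length,
               gc_pct = accepted$gc_pct, tm_c = accepted$tm_c,
               window_index = accepted$window_index, unique = accepted$unique,
               flags = "pass", stringsAsFactors = FALSE)
  }
  unfilled <- if (length(unfilled)) do.call(rbind, unfilled) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), stringsAsFactors = FALSE)
  structure(list(oligos = oligos, unfilled = unfilled, regions = regions,
                 design_config = design_cfg, thermo_config = thermo_cfg),
            class = "rse_panel")
}

#' @export
print.rse_panel <- function(x, ...) {
  cat(sprintf("<rse_panel> %d oligo(s) over %d region(s); %d unfilled window(s)\n",
              nrow(x$oligos), length(x$regions), nrow(x$unfilled)))
  invisible(x)
}

#' Write a panel as TSV (plus unfilled windows as BED)
#'
#' Column formats are fixed (GC to one decimal, Tm to two), so identical
#' inputs and configuration produce byte-identical files.
#'
#' @param panel An `rse_panel` from [design_panel()].
#' @param path Output TSV path.
#' @param unfilled_path Optional BED path for unfilled windows; defaults to
#'   `<path>` with the extension replaced by `.unfilled.bed`.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path, unfilled_path = NULL) {
  stopifnot(inherits(panel, "rse_panel"))
  o <- panel$oligos
  out <- data.frame(name = o$name, chrom = o$chrom,
                    start_1based = format(o$start, scientific = FALSE,
                                          trim = TRUE),
                    end_1based = format(o$end, scientific = FALSE,
                                        trim = TRUE),
                    strand = o$strand, sequence = o$sequence,
                    length = o$length, gc_pct = sprintf("%.1f", o$gc_pct),
                    tm_c = sprintf("%.2f", o$tm_c),
                    window_index = o$window_index,
                    unique = tolower(as.character(o$unique)),
                    flags = o$flags, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  if (is.null(unfilled_path)) {
    unfilled_path <- paste0(sub("\\.[^.]*$", "", path), ".unfilled.bed")
  }
  write_bed(panel$unfilled, unfilled_path)
  invisible(path)
}
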
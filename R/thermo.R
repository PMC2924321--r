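#' Thermodynamic screening configuration
#'
#' Parameters for the per-oligo and cross-oligo screens. The melting
#' temperature uses the unified nearest-neighbor parameter set of
#' SantaLucia (1998) with the entropic salt correction
#' `0.368 * (N-1) * ln[Na+]`; defaults of 50 mM monovalent cation and
#' 0.25 uM oligo are typical hybridization-assay conditions and place
#' well-behaved 22-27mers of 48-52% GC in the high-50s degrees C.
#'
#' Hairpin and dimer screening is run-length based: a candidate fails if a
#' perfect inverted repeat (stem at least `hairpin_min_stem` bp enclosing a
#' loop of at least `hairpin_min_loop` nt) exists, or if any ungapped
#' antiparallel alignment of two oligos contains a complementary run of at
#' least `dimer_max_run` bp anywhere, or at least `dimer_3prime_max_run` bp
#' anchored at either 3' end (3'-anchored duplexes are extendable by
#' polymerase, hence the stricter cutoff).
#'
#' @param na_mM Monovalent cation concentration, mM.
#' @param oligo_uM Total oligo concentration, uM.
#' @param hairpin_min_stem Minimum self-complementary stem length, bp.
#' @param hairpin_min_loop Minimum loop length, nt.
#' @param dimer_max_run Complementary run length failing anywhere, bp.
#' @param dimer_3prime_max_run Complementary run length failing at a 3' end.
#' @return A list of class `rse_thermo_config`.
#' @export
thermo_config <- function(na_mM = 50, oligo_uM = 0.25,
                          hairpin_min_stem = 6L, hairpin_min_loop = 3L,
                          dimer_max_run = 8L, dimer_3prime_max_run = 5L) {
  stopifnot(na_mM > 0, oligo_uM > 0)
  for (v in c(hairpin_min_stem, hairpin_min_loop, dimer_max_run,
              dimer_3prime_max_run)) {
    assert_count(v, "thermo threshold", positive = TRUE)
  }
  structure(list(na_mM = na_mM, oligo_uM = oligo_uM,
                 hairpin_min_stem = as.integer(hairpin_min_stem),
                 hairpin_min_loop = as.integer(hairpin_min_loop),
                 dimer_max_run = as.integer(dimer_max_run),
                 dimer_3prime_max_run = as.integer(dimer_3prime_max_run)),
            class = "rse_thermo_config")
}

#' GC content in percent
#'
#' Exact value `100 * (#G + #C) / length`; vectorized over sequences.
#'
#' @param sequence Character vector of A/C/G/T sequences.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' gc_content("GAGTGCGTTTGGTTTCTGACGAAGA")  # 48
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), all(nzchar(sequence)))
  assert_dna(sequence, what = "sequence")
  gc <- nchar(gsub("[AT]", "", sequence))
  100 * gc / nchar(sequence)
}

# SantaLucia 1998 unified NN parameters: dH kcal/mol, dS cal/(mol K)
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Duplex melting temperature (nearest-neighbor)
#'
#' Two-state nearest-neighbor model with the unified SantaLucia (1998)
#' parameter set: `Tm = 1000*dH / (dS_salt + R*ln(CT_eff)) - 273.15` with
#' `R = 1.987 cal/(mol K)`, terminal A/T and G/C initiation penalties,
#' entropic salt correction `dS + 0.368*(N-1)*ln[Na+]`, and effective
#' concentration `CT/4` (or `CT` for a self-complementary duplex, which also
#' receives the symmetry entropy term). The result is symmetric under
#' reverse complement, as a duplex Tm must be.
#'
#' @param sequence A/C/G/T string, length >= 8.
#' @param config An [thermo_config()].
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(sequence, config = thermo_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  assert_dna(sequence, what = "sequence")
  n <- nchar(sequence)
  if (n < 8L) stop("sequence too short for NN Tm (need >= 8 nt)",
                   call. = FALSE)
  dinucs <- substring(sequence, 1:(n - 1), 2:n)
  dH <- sum(.NN_DH[dinucs])
  dS <- sum(.NN_DS[dinucs])
  ends <- substring(sequence, c(1, n), c(1, n))
  for (b in ends) {
    if (b %in% c("A", "T")) {
      dH <- dH + 2.3; dS <- dS + 4.1
    } else {
      dH <- dH + 0.1; dS <- dS - 2.8
    }
  }
  ct <- config$oligo_uM * 1e-6
  if (identical(sequence, revcomp(sequence))) {
    dS <- dS - 1.4          # symmetry correction
    ct_eff <- ct
  } else {
    ct_eff <- ct / 4
  }
  dS <- dS + 0.368 * (n - 1) * log(config$na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(ct_eff)) - 273.15
}

#' Hairpin screen
#'
#' Flags a sequence that can fold back on itself: returns `TRUE` iff there
#' is an inverted complementary repeat with a perfect stem of at least
#' `hairpin_min_stem` bp enclosing a loop of at least `hairpin_min_loop` nt.
#'
#' @param sequence A/C/G/T string.
#' @param config An [thermo_config()].
#' @return Logical fail flag.
#' @export
hairpin_check <- function(sequence, config = thermo_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  assert_dna(sequence, what = "sequence")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", sequence)
  cc <- strsplit(comp, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ms <- config$hairpin_min_stem
  ml <- config$hairpin_min_loop
  if (n < 2 * ms + ml) return(FALSE)
  # positions i < j pair iff ch[i] == complement(ch[j]); a stem walks the
  # anti-diagonal d = i + j, so scan each anti-diagonal for pairing runs
  for (d in (2 * ms + ml + 1):(2 * n - 2 * ms - ml + 1)) {
    i_lo <- max(1L, d - n)
    i_hi <- (d - 1L) %/% 2L
    if (i_hi - i_lo + 1L < ms) next
    iv <- i_lo:i_hi
    m <- ch[iv] == cc[d - iv]
    r <- rle(m)
    pos <- i_lo
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= ms) {
        # outermost placement of a ms-long stem gives the largest loop
        loop <- d - 2 * (pos + ms - 1) - 1
        if (loop >= ml) return(TRUE)
      }
      pos <- pos + r$lengths[k]
    }
  }
  FALSE
}

#' Homo-/hetero-dimer screen
#'
#' Returns `TRUE` iff some ungapped antiparallel alignment of `seq_a`
#' against `seq_b` contains a perfectly complementary run of at least
#' `dimer_max_run` bp, or a run of at least `dimer_3prime_max_run` bp that
#' includes the 3'-terminal base of either oligo. Calling with
#' `seq_a == seq_b` screens homodimerization. The screen is symmetric:
#' `dimer_check(a, b) == dimer_check(b, a)`.
#'
#' @param seq_a,seq_b A/C/G/T strings.
#' @param config An [thermo_config()].
#' @return Logical fail flag.
#' @export
dimer_check <- function(seq_a, seq_b, config = thermo_config()) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  assert_dna(seq_a, what = "seq_a")
  assert_dna(seq_b, what = "seq_b")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  # write b 3'->5' under a and complement it: position y of d pairs column-
  # wise with a; d[1] carries b's 3'-terminal base
  d <- strsplit(revcomp(seq_b), "", fixed = TRUE)[[1]]
  na <- length(a)
  nd <- length(d)
  maxrun <- config$dimer_max_run
  run3 <- config$dimer_3prime_max_run
  for (off in -(nd - 1):(na - 1)) {
    y <- max(1L, 1L - off):min(nd, na - off)
    x <- y + off
    m <- a[x] == d[y]
    r <- rle(m)
    if (any(r$values & r$lengths >= maxrun)) return(TRUE)
    # 3'-anchored runs: a's 3' end is column x == na (tail of overlap when
    # x[last] == na); b's 3' end is column y == 1 (head of overlap when
    # y[1] == 1)
    k <- length(r$lengths)
    if (r$values[k] && x[length(x)] == na && r$lengths[k] >= run3) {
      return(TRUE)
    }
    if (r$values[1] && y[1] == 1L && r$lengths[1] >= run3) return(TRUE)
  }
  FALSE
}

#' All per-oligo screen metrics
#'
#' @param sequence A/C/G/T string.
#' @param config An [thermo_config()].
#' @return A one-row data.frame with `gc_pct`, `tm_c`, `hairpin_fail`,
#'   `selfdimer_fail`.
#' @export
oligo_metrics <- function(sequence, config = thermo_config()) {
  data.frame(gc_pct = gc_content(sequence),
             tm_c = melting_temperature(sequence, config),
             hairpin_fail = hairpin_check(sequence, config),
             selfdimer_fail = dimer_check(sequence, sequence, config))
}
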
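---
title: "Capture-oligo design and enrichment evaluation: models and methods"
author: "rsecapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture-oligo design and enrichment evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsecapture)
```

This vignette documents the models, numerical conventions and design
choices behind the package: how capture-oligo panels for region-specific
extraction (RSE) are designed, how capture-sequencing experiments are
evaluated, and what the built-in simulator does and does not emulate.

## Coordinates and input formats

All user-facing coordinates are **1-based and inclusive** at both ends,
the convention in which genomic intervals and oligo start positions are
printed in the genetics literature (`chr19:32,557,347–32,877,103` spans
`32877103 − 32557347 + 1 = 319,757` bases, i.e. 319.8 kb). BED input and
output (masks, targets, gap reports, truth alignments) converts to and
from the 0-based half-open BED convention only at the file boundary.
FASTA is read case-preservingly: with `mask_mode = "softmask"`, lowercase
bases — the standard encoding for repeat- and SNP-masked positions — are
flagged as excluded from design. `N` bases are always masked: an
ambiguous base can never be a capture point. Alignments come in as a
minimal SAM subset (RNAME, POS, FLAG, and the SEQ length; CIGAR is
deliberately ignored) or as a 4+-column BED; unmapped records are
excluded from the alignment table but kept in the total read count,
because the enrichment denominator is the *total* number of reads.

## Panel design

### Window parsing

A target region of length $L$ is split into
$n = \max(1, \mathrm{round}(L / s))$ equal-size (±1 base) windows at the
target spacing $s$ (default 8000 bp), each window's start being its
preferred design position (anchor). With `anchor_end = TRUE` (default)
an extra terminal design site anchored at $\mathrm{end} - 27 + 1$ is
appended so the panel also covers the far boundary of the region. This
rule reproduces the published panel geometry: a 319,757 bp region at 8 kb
spacing gives 40 windows plus the terminal site — 41 design sites, the
size of the published 41-oligo panel. Rounding uses R's round-half-even;
e.g. a 100 kb region gives $\mathrm{round}(12.5) = 12$ windows plus the
terminal site.

### Candidate enumeration and screening

Within each window, every substring of length 22–27 containing no masked
base is a candidate, ordered by the distance of its start from the
anchor (ties: longer oligo first, then lexicographically smaller
sequence — a total order, so design output is byte-reproducible). The
first candidate passing all screens is selected:

* **GC content**: exact rational percent, inclusive bounds 48–52% (the
  packaged published panel sits exactly on both bounds, so inclusivity
  matters).
* **Melting temperature**: 57–61 °C under the unified nearest-neighbor
  model (below).
* **Hairpin**: fails if a perfect inverted repeat exists with stem ≥ 6 bp
  and loop ≥ 3 nt.
* **Self-dimer** and, during the multiplex pass, **cross-dimer**: fails
  if any ungapped antiparallel alignment of the pair contains a perfectly
  complementary run ≥ 8 bp anywhere, or ≥ 5 bp anchored at either 3′ end
  (3′-anchored duplexes are polymerase-extendable, hence the stricter
  cutoff).
* **Uniqueness**: the sequence must occur exactly once in the genome,
  counting both strands, by exact matching. This is the deterministic
  analogue of checking candidates against a local alignment server to
  ensure they match only one region; near-match (mismatch-tolerant)
  screening is out of scope.

The run-length formulation of the structure screens was chosen because
the design goal ("minimal dimerization and hairpin formation") fixes no
thermodynamic cutoffs, and run-length rules admit exhaustive brute-force
oracles against which the implementations are tested on thousands of
seeded random oligos. Free-energy folding would add model parameters
without a verifiable contract.

Cross-reactivity is resolved incrementally in genomic order: each
window's selection must also pass `dimer_check` against every
already-accepted oligo (and must not overlap one), so on a conflict the
earlier-placed oligo is kept and the later window falls through to its
next candidate. Given the sorted window order this is deterministic. A
window with no passing candidate is a first-class result — reported in
the panel's `unfilled` table and as a BED file — mirroring the
interactive "redesign this sub-region" step of panel design practice;
per-window overrides can then relax bounds explicitly.

### Melting temperature model

Tm uses the unified nearest-neighbor parameter set of SantaLucia (1998):

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N{-}1)\ln[\mathrm{Na}^+] + R \ln C_T^{\mathrm{eff}}} - 273.15$$

with $\Delta H$, $\Delta S$ summed over dinucleotide stacks plus terminal
A/T (+2.3 kcal/mol, +4.1 cal/mol·K) and G/C (+0.1, −2.8) initiation
penalties, $R = 1.987$ cal/mol·K, and
$C_T^{\mathrm{eff}} = C_T/4$ for non-self-complementary duplexes
($C_T$, with an additional −1.4 cal/mol·K symmetry entropy, for
self-complementary ones). Defaults are 50 mM Na⁺ and 0.25 µM oligo,
typical hybridization-assay conditions. Under these defaults the 41
packaged published oligos compute to 57.2–61.1 °C — the published
"57–61 °C" range — which is the consistency check behind the default
choice; the published model, salt and concentration are not stated, so
the Tm range is treated as a filter bound, not as an exactly
reproducible quantity. The implementation is verified to 0.01 °C against
an independent implementation of the same parameter table.

## Capture evaluation

**Fold enrichment** is
$E = (r/t)\,/\,(L/G)$ for $r$ on-target of $t$ total reads over an
examined interval of $L$ bp in a genome of $G$ bp (default
$G = 1.6 \times 10^9$, the zebrafish genome estimate). "On target" means
overlapping the interval by at least one base (configurable to full
containment). The exact ratio is always carried; the reporting layer
rounds half-up to an integer, the convention under which the published
worked examples print as 243, 72 and 43.

**Depth profiles** count, per interval base, the alignments overlapping
that base (partial overlaps contribute only their overlap);
**coverage fraction** is the percent of bases at or above a depth
threshold; **gaps** are maximal runs of zero depth, reported 1-based
inclusive with a length filter for triage. Mean depth is computed over
all profile bases; restricting to unmasked ("unique") sequence is
available by masking the genome first, since the mappability filter
behind published "average depth for unique sequence" figures is not
fully specified.

**Recombination distance** is $100 \cdot r/m$ cM for $r$ recombinants in
$m$ meioses, truncated (not rounded) at one decimal: 27/976 = 2.766% is
reported as 2.7 cM, matching the printed mapping-cross convention; the
exact value is available with `truncate = FALSE`.

## The simulator

`make_genome` draws i.i.d. bases at a configurable GC fraction;
`apply_deletion` builds a mutant allele; `simulate_capture_reads` draws
each read on-target with probability $p = E \cdot L / G$ (uniform start
within its stratum, uniform strand, error-free sequence copied from the
source genome) and returns reads plus truth alignments;
`align_exact` places each read at its unique exact match over both
strands, reporting zero-match reads as unmapped and multi-match reads as
ambiguous.

Deliberate simplifications, and what they imply about test evidence:
reads are error-free and alignment is exact full-length match, so
passing tests demonstrate the *arithmetic* of enrichment and the *logic*
of gap detection, not robustness to sequencing error, indel-aware
alignment, repeat structure, or capture chemistry biases (fragment-length
effects, GC bias, off-target hybridization), none of which the i.i.d.
genome contains. Published figures measured on real fish data (31× mean
depth, 99.9% coverage) are therefore not reproduction targets; the
enrichment worked examples, panel statistics and geometry are.

Two modeling choices deserve explanation:

* **On-target stratum = fully contained reads.** This makes
  $p = E L / G$ exact rather than approximate at the target boundaries,
  so measured enrichment converges to the configured $E$
  ($\pm 5\%$ at $10^5$ reads for the published first-capture geometry
  $E = 243$, $L = 315{,}606$, $G = 1.6 \times 10^9$, where the binomial
  standard deviation of the estimate is ≈ 3.4).
* **Modeled vs physical genome size.** `genome_bp` may exceed the
  physical simulated sequence: $p$ uses the configured $G$ while read
  sequences are drawn from the physical target and flank sequence, which
  stands in for the rest of the genome. This is what makes the 1.6 Gb
  geometry testable on a 400 kb physical sequence.

### Depth required for exact deletion recovery

A deletion of $d$ bases leaves $d$ reference bases that no error-free
read from the mutant allele can cover — but the bases *adjacent* to the
deletion are special: a read covering the last flank base without
crossing the junction must *end exactly at the junction*, i.e. start at
one particular position. Under uniform sampling the read count at a
single start position is Poisson with mean $\lambda = D/\ell$ for mean
depth $D$ and read length $\ell$. At $D = 50\times$, $\ell = 36$:
$\lambda = 1.39$ and each flank base is uncovered with probability
$e^{-1.39} = 0.25$, so the observed gap exceeds $d$ almost half the
time. The package's deletion-recovery simulations therefore run at
$200\times$ ($\lambda = 5.6$, flank-miss probability $0.4\%$), which
satisfies the "at least 50×" study condition and makes exact-length
recovery the ≥ 99% event the design intends.

A second subtlety is **junction micro-homology**: if the deleted
segment's terminal base equals the adjacent flank base, the same allele
is produced by deleting a shifted window, and junction reads with a
one-base overhang still match the undeleted reference exactly — the
zero-coverage run is genuinely shorter than the nominal deletion. This
is the familiar left/right-alignment ambiguity of indel representation.
`find_deletion_site` scans for a site where both junctions are
non-homologous, making the planted deletion's coordinates and gap length
well-defined; at a random site the gap would undershoot with probability
$1-(3/4)^2 = 44\%$.

## Determinism and problem sizes

Panel design uses no randomness: identical genome, mask and
configuration give byte-identical panel TSVs (fixed column formats: GC
one decimal, Tm two). All simulation entry points take explicit seeds
and are byte-reproducible. The CLI writes a manifest (command, config,
input checksums, version, seed) next to every output.

The test suite and the acceptance script run at desk scale by design:
oracle comparisons use thousands of 22–27mers, uniqueness genomes of
20–40 kb, depth/gap oracles on ≤ 10 kb intervals, panel design on
30–100 kb genomes, enrichment recovery at $10^5$ reads over a 400 kb
physical sequence, and deletion recovery on a 100 kb genome at 200×
(≈ 5.6 × 10⁵ reads). These sizes were chosen as the smallest at which
the binomial/Poisson arguments above give comfortable margins.

## Known limitations

* Uniqueness is exact-match only; a candidate unique in exact terms may
  still cross-hybridize to near-identical repeats. The published
  workflow's alignment-server check is mismatch-tolerant.
* Structure screens are run-length rules, not ΔG folding; borderline
  secondary structure near the thresholds is not scored
  thermodynamically.
* The strand of published panel oligos relative to the reference is not
  stated in the source tables; fixtures store sequences as printed and
  the designer emits forward-strand oligos.
* Published flank-panel oligo placement (the 36 additional oligos) does
  not follow the uniform spacing rule — interactive redesign evidently
  intervened — so the designer does not promise to reproduce that
  placement, only panels satisfying the same published criteria.
* The simulator has no sequencing error, quality scores, paired ends,
  PCR duplicates or amplification bias; see above for what that limits.
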
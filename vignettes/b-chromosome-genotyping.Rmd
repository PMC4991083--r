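---
title: "Coverage-ratio detection, multiplex marker design and qPCR dose genotyping of B chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-ratio detection, multiplex marker design and qPCR dose genotyping of B chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bchromr)
```

`bchromr` genotypes B chromosomes — dispensable supernumerary chromosomes
present in 0, 1 or 2 copies per individual — from sequencing coverage,
allele-specific multiplex PCR and qPCR gene dose. This vignette is the
package's account of the underlying models, the parameters that matter, the
synthetic data the test suite runs on, and the design decisions taken where
the method leaves room.

## The coverage-ratio model

B chromosomes accumulate duplicated blocks of the A complement. When reads
from a B-carrying individual are aligned to a reference genome that lacks
the B, reads from those duplicated blocks map back to their A-complement
source locus and inflate its depth. With `a` copies of a locus in the A
complement (2 for an ordinary diploid locus) and `c` extra copies per B, a
genotype with `nB` Bs carries `a + nB·c` copies, and block depth scales
accordingly.

`window_depth()` counts primary mapped reads into fixed windows by the
leftmost-aligned-base rule (each read increments exactly one window, so
window counts always sum to the library size). `normalize_depth()` rescales
to reads per million, because 0B/1B/2B libraries can differ several-fold in
size. `ratio_track()` then forms, per window,

```
r1 = (nd1B + alpha) / (nd0B + alpha),   r2 = (nd2B + alpha) / (nd0B + alpha)
```

with a pseudocount `alpha` that keeps empty windows at a neutral ratio of 1.
`detect_blocks()` calls a window enriched when **both** `r1 >= theta` and
`r2 >= theta` — enrichment must show in every B-positive sample for a block
to count as B-derived — merges passing windows across gaps of at most
`max_gap` windows, and keeps runs with at least `min_windows` passing
windows.

Two quantitative points that matter when interpreting ratios:

* **Library-size normalization leaves a pool-size factor.** Under
  reads-per-million, the expected block ratio is not `(a + nB·c)/a` but
  `((a + nB·c)/a) · (P0/PnB)`, where `Pg` is the total template pool of
  genotype `g` (the B content itself enlarges the library). On a real
  genome the B is a small fraction of the pool and the factor is ~1; on the
  desk-scale genomes the test suite simulates (tens of kilobases) it is
  substantial, and the tests assert the full closed form. Background
  (non-B) windows sit at `P0/PnB < 1` rather than exactly 1 for the same
  reason; detection is unaffected because thresholds apply to enrichment
  well above that baseline.
* **Dose consistency.** For a block following the linear dose model,
  `r2 - 1 = 2 (r1 - 1)` (up to the factors above), so
  `D = |(mean_r2 - 1) - 2 (mean_r1 - 1)|` is near 0 for well-behaved
  blocks. `rank_blocks()` sorts by ascending `D`, then ascending
  within-block coefficient of variation of `r2`, then descending `mean_r2`
  — the in-silico analogue of discarding candidate regions whose signal is
  erratic — with genomic coordinates as the final tie-break so ranking is
  deterministic.

Defaults: window 1,000 bp (resolves blocks from a few hundred bp to tens of
kb), `alpha = 0.5`, `theta = 1.5`, `min_windows = 3`, `max_gap = 1`. All are
configurable; `theta` trades sensitivity at low `c` against background false
positives.

The built-in mapper (`map_reads_exact()`) places a read at the unique best
position whose exact k-prefix seed matches and whose full-length Hamming
distance is at most `max_mismatches` (default 2); ties are discarded as
ambiguous. It is deliberately minimal — substitution-only, forward-strand,
matching the simulator's read model — so the coverage stages are testable
without an external aligner, and its equivalence with an exhaustive
Hamming scan is itself under test. Real alignments enter through
`read_alignments()` (SAM/BAM via Rsamtools; primary, mapped, non-duplicate
records; SAM's 1-based positions converted to the package-wide 0-based
half-open convention).

## Marker design

The presence/absence marker is a three-primer multiplex anchored on a
B-diagnostic substitution:

1. `build_consensus()` takes two or more **pre-aligned, equal-length**
   reference sequences (the simulator's ortholog panels are
   substitution-only, hence trivially aligned; externally aligned panels
   work the same way) and records the column-majority consensus plus a
   conserved mask (true only where all sequences agree; ties become IUPAC
   codes and are non-conserved).
2. `align_contig()` aligns a B-derived contig to the region by exact k-mer
   seeding plus an affine-gap Smith–Waterman pass (match +1, mismatch −2,
   gap open −4, gap extend −1 per base; a gap of length L costs
   `4 + L`). Both orientations are tried; with no seed the result is a
   "no alignment" object, not an error. On small instances the score is
   tested equal to a full Smith–Waterman oracle.
3. `call_diagnostic_variants()` keeps contig/consensus substitutions at
   conserved columns with at least `min_flank` (default 20 bp) conserved
   columns on both sides — enough room for primer bodies that must bind B
   and non-B templates alike.
4. `design_allele_specific_primer()` builds the ARMS forward primer ending
   exactly on the variant with the B allele as its 3'-terminal base,
   choosing the length (18–40 nt, the range spanned by the shipped primer
   panel) whose nearest-neighbor Tm lands closest to the middle of the
   target window (55–65 °C by default; shorter wins ties).
5. `design_control_pair()` places the control forward and the shared
   reverse entirely within conserved columns, downstream of the variant
   (45–150 bp by default) so one reverse primer closes both products and
   the two bands differ enough to resolve on agarose. When the caller
   supplies the contig's aligned interval and its mismatch columns (as the
   pipeline does), the search is restricted to sequence whose conservation
   is verified on the B side too — control primers then match both
   templates exactly by construction.
6. `assemble_multiplex()` computes the expected control and B product
   lengths from primer footprints and rejects gel-unresolvable size gaps
   (`delta_gel`, default 40 bp on 1% agarose), Tm spans above 5 °C, and
   3'-terminal cross-complementarity runs of 5 nt or more (primer-dimer
   risk).

Melting temperatures use unified nearest-neighbor duplex parameters with an
entropy salt correction at 50 mM monovalent cation and 0.25 µM total
strands; `mode = "wallace"` gives the 2AT+4GC rule. The Wallace rule is
defined for any length (its classic examples are 4-mers); the
nearest-neighbor mode requires at least 8 nt. An independent thermodynamic
implementation serves as the test oracle (agreement within 2 °C).

`in_silico_pcr()` predicts the gel: a primer site primes only if its
3'-terminal base matches exactly, at most one mismatch falls in the
3'-terminal 5 nt, and at most `m_internal` (default 3) elsewhere — the
standard ARMS assumption that a single 3' mismatch abolishes extension.
IUPAC codes in the template count as mismatches (conservative). Every
plus/minus site pair with `0 < product <= max_product` (default 1,000 bp)
is reported; `call_presence()` then applies the gel logic: control band
required (else `invalid`), B band present → `B_positive`, absent →
`B_negative`.

## qPCR gene-dose genotyping

The dose model is direct `2^-dCt` with an HPRT reference and amplification
efficiency fixed at 2.0 per cycle — no efficiency correction and no
calibrator-sample ΔΔCt, matching how the gene-dose-ratio readout is used in
practice. For a marker with `a` copies in the A complement and `c` added
per B, and an `a_ref`-copy reference gene,

```
GDR(nB) = (a + nB·c) / a_ref,       GDR(2B)/GDR(1B) = (a + 2c) / (a + c)
```

which approaches 2 as `c/a` grows — the two-fold signal expected of a
B-amplified block (`a = 2`, `c = 100` gives 202/102 ≈ 1.98).

`aggregate_ct()` means triplicates and flags replicate SDs above 0.5 cycles
(no outlier pruning — replicates either pass or get flagged);
`dose_estimates()` propagates the combined SD into a GDR interval
`2^-(dCt ± sd)`. `calibrate()` computes per-genotype GDR means and log2
centers from known 0B/1B/2B controls and **fails loudly** if the centers
are not strictly ordered 0B < 1B < 2B, since that invalidates dose
discrimination. `call_copies()` assigns the nearest center in log2 space —
dosage is multiplicative, so log space makes the 1B/2B midpoint symmetric —
and flags calls whose two nearest centers differ by less than
`epsilon = 0.25` log2 units in distance. Separability requires `c > a`
(with `c >> a` the 1B/2B centers sit a full log2 unit apart);
`a = 0` is the B-exclusive limit in the closed form above, while the
simulator itself requires `a >= 1` so every genotype yields finite Ct.
`cohort_fold_change()` reports the 2B/1B ratio of mean GDRs with a seeded
bootstrap percentile interval (default 1,000 resamples).

## The synthetic cohort

`truth_spec()` fixes the simulated study conditions; the defaults are the
conditions under which the pipeline is tested:

| parameter | default | why |
|---|---|---|
| scaffolds | 20 kb + 15 kb | desk-scale genome; one scan runs in seconds |
| B block | 5 kb, 10 copies on the B | mid-range of the selected-region sizes (0.7–13.7 kb); 10-fold duplication gives unambiguous ratios at modest depth |
| `snv_rate_in_blocks` | 0.01 /bp | ~1 diagnostic substitution per 100 bp, enough variants that assay design has choices |
| `a_complement_copies` | 2 | ordinary diploid locus; the A complement carries the blocks at low copy number |
| read length / depth | 100 bp, 20× per haploid copy | short-read scale; 20× bounds the ratio noise (~1/√depth per window) |
| `read_error_rate` | 0.001 /bp | typical short-read substitution error |
| Ct model | `C0 = 30`, noise 0.2 cycles, triplicates | a template at k copies crosses threshold at `C0 − log2(k)`; 0.2 cycles is a realistic replicate SD, and triplicates mirror qPCR practice |
| qPCR marker dose | `a = 2`, `c = 100`, `a_ref = 2` | `c` is a free parameter of the system (the true per-B copy number of a real marker region is not knowable from the method itself); 100 makes 0B/1B/2B centers 1/51/101, cleanly separable at 0.2-cycle noise |

One global integer seed drives everything; each stage derives its own
stream from the seed plus a stage label (`derive_seed()`), so regenerating
one stage never perturbs another and identical specs give byte-identical
FASTA/FASTQ/CSV output.

What the generator emulates: block duplication with shared diagnostic
substitutions across copies, read depth proportional to `a + nB·c`,
microdissection-style contigs as exact B-sequence substrings (lengths
truncated-normal around 372 bp), and Ct values following the log2 copy
model. What it does **not** emulate: GC or positional coverage bias,
indels, paired-end structure, platform error profiles, chimeric contigs or
assembly errors, qPCR efficiency drift or plate effects, and tissue
mosaicism. Passing tests therefore demonstrate the correctness of the
computational method under its own model assumptions, not robustness to
every artefact of real libraries; with real data the alignment and qPCR QC
steps carry that burden.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere; interval size is
  `end − start`, and BED round-trips unchanged. SAM positions convert on
  read.
* Ranking, primer search and ambiguity handling all have deterministic
  tie-breaks (coordinates, then shorter length), so identical inputs give
  identical outputs.
* The control-pair search scores candidates by Tm distance from the window
  midpoint plus a small product-length term (1/1000 weight), so Tm
  compatibility dominates and product size only breaks near-ties.
* Reads that straddle two copies of a block on the B have no reference
  match and go unmapped; the expected mappable fraction `1 − (L−1)/len`
  enters the closed-form ratio tests.
* Degenerate inputs fail fast with named errors: empty libraries,
  mismatched windowing, missing assays (named sample), unknown config keys,
  non-positive Ct, calibration-order violations.
* `map_reads_exact()` discards multi-best-position reads as ambiguous
  rather than picking one — depth conservation applies to placed reads.

## Scope and limitations

Alignment of real read sets is delegated to external aligners (the package
consumes SAM/BAM); the built-in mapper exists for self-contained synthetic
work. Segmentation is threshold-and-merge, not an HMM or CBS — adequate for
high-contrast duplications, not for subtle copy-number changes. The
multiplex model is three primers with one shared reverse; the in-silico PCR
does not fold secondary structure. The dose model assumes the HPRT
reference is copy-stable across genotypes and a common amplification
efficiency of 2.0; violations shift all GDRs multiplicatively and would
surface as a calibration-order failure only in extreme cases. Per-tissue
samples are treated as independent (no mosaicism model).

The test suite and acceptance script run on the desk-scale sizes above
(10–35 kb genomes, 10–70 k reads per genotype, 20–40 contigs, 9 controls +
9–30 unknowns per Ct table), chosen so the full pipeline, 10-seed recovery
sweeps and 20-cohort design round-trips complete in a few minutes.
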
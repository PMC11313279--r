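---
title: "Genotyping the CFTR poly-T/TG tract: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping the CFTR poly-T/TG tract: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytg)
```

## The problem

Intron 9 of *CFTR* carries a polymorphic low-complexity sequence: a TG
dinucleotide repeat followed directly by a poly-T run, written `(TG)mTn`.
The poly-T run sits in the splice acceptor of exon 10, and the combination
of a short poly-T with a long TG repeat - notably `(TG)12T5` and
`(TG)13T5` - promotes exon 10 skipping and is clinically significant,
whereas `T7`, `T9` and `(TG)11T5` are benign. Laboratories are therefore
expected to report the TG repeat size whenever a `T5` allele is seen.

Sanger sequencing is the economical assay for this region, but both repeat
counts vary between the two alleles of one individual. When the two
alleles differ in total length, every peak downstream of the shorter
allele's end is a superposition of two out-of-register sequences, and
reading the genotype off the chromatogram becomes slow, expert work. This
package automates the call from a pair of forward/reverse `.ab1` files and
produces a ranked genotype table, diagnostics and plots; a chromatogram
simulator makes the whole pipeline testable without clinical material.

## From traces to observations

An ABIF file provides, per called base, a peak location into the four
analyzed fluorescence traces. At each peak we sample the four channels and
divide by their sum, giving per-position **relative intensities** that are
invariant to scanner gain. Two thresholds govern interpretation:

* `min_total_signal` (default 50, analyzed-trace units): positions whose
  four-channel total falls below it are *uninformative* - they are masked
  out of all comparisons but still count as detected tract positions. The
  default is deliberately conservative for analyzed traces; it is exposed
  on the command line because the right value depends on instrument and
  template quality.
* `presence_fraction` (default 0.10): a base is *present* at a position
  when its relative intensity is at least this fraction (inclusive). A
  relative threshold keeps the predicate meaningful across instruments: a
  50/50 heterozygous peak (about 0.5) is robustly present, while typical
  spectral bleed-through (under 10 percent) stays absent.

The reverse read is normalized into genomic-forward orientation (positions
reversed, channels complemented A with T and C with G) before any
downstream step, so one coordinate frame serves both directions.

## Locating the tract

The tract is anchored on its 15 bp flanking sequences, which balances
uniqueness against compatibility with arbitrary primer designs. The
anchor is matched by Hamming distance over the profile's argmax bases
(uninformative positions count as matches), tolerating up to
`max_mismatch = 2` miscalls; the best window must be unique, otherwise the
sample fails with an ambiguity error.

* **Forward**: the tract starts immediately after the upstream anchor and
  is scanned 3'-ward. A literal "until thymine disappears" rule cannot
  work because clean guanine positions inside the TG repeat carry no
  thymine, so the scan continues while thymine is present at the position
  *or the next one*, and terminates at the first two consecutive
  thymine-free positions. The reference flank begins with two non-T bases,
  so termination lands exactly on the tract boundary. A terminator must be
  confirmed by two in-read positions; if the read (or the 60-position scan
  cap) ends first, the window is truncated and flagged as partial.
* **Reverse** (in oriented coordinates): the tract ends immediately before
  the downstream anchor and is scanned 5'-ward while tract signal (T or G)
  is present, stopping at the first position free of both - in the
  reference this is the adenine immediately 5' of the TG repeat. We phrase
  the stop in terms of tract signal rather than "first adenine" because in
  a right-aligned heterozygote the shorter allele's shifted flank
  superposes an adenine *inside* the longer allele's tract at half
  intensity; stopping on that adenine would truncate the window at the
  shorter allele's length, which contradicts what the overlapped peaks
  plainly show.

With these rules, a noiseless homozygote yields a window of exactly
`2m + n` in both directions, and a heterozygote yields the longer allele's
length. Uninformative gaps never terminate a scan.

Each direction's flank is also screened for heterozygous indel
interference: if more than 3 of the 15 anchor positions carry a second
present nucleotide, the two amplicon copies are out of register across the
flank (an insertion, duplication or deletion elsewhere in the amplicon)
and the report warns that results are unreliable. Such samples need
manual review; the tract model cannot resolve them.

## Candidate genotypes and expected patterns

All unordered allele pairs over a rectangular search space are enumerated
(defaults T3-T11 by (TG)8-(TG)16, 81 alleles, 3321 genotypes, covering all
known alleles). For each genotype the two allele sequences are superposed
with **dual alignment**: left-aligned at the tract 5' end for the forward
read and right-aligned at the 3' end for the reverse read, because each
read is in register with its own primer-proximal flank. Dual alignment is
what makes unequal-length heterozygotes identifiable: a genotype that
mimics the observation in one frame comes apart in the other.

Expected relative T and G intensities are **allele-dosage fractions**:
each allele contributes 0.5 to the channel of the base it places at a
position. Positions covered by both alleles give the familiar values - 1/0
for a shared base, 0.5/0.5 where one allele has T and the other G - and a
position past the shorter allele's end gives 0.5 for the longer allele's
base, matching the dilution actually observed there. The naive alternative
(expected intensity 1 beyond the shorter allele) makes every candidate's
cost at such positions identically 0.25 regardless of its prediction,
which collapses the margins between allele-swapped genotypes; with dosage
fractions the true genotype's expectation equals the noiseless observation
exactly, and the test suite's exhaustive recovery checks rest on that
margin.

## Elimination and ranking

A genotype is **eliminated** when its expectations contradict the
observation in either direction:

* some informative observed position inside the expected tract expects a
  single base (T only or G only) whose signal is absent; or
* its expected tract is longer than the observed window - the scan
  terminated precisely because tract signal was absent past the window, so
  signal the genotype requires was certified unobserved.

Elimination is deliberately one-directional. Observed-but-unexpected
signal never eliminates; it only worsens the score. Positions expecting
both T and G never eliminate. A consequence of the length rule worth
knowing: when a tract is only partially detected (flagged in the report),
genotypes longer than the truncated window are unavailable, which biases
the call toward shorter alleles - one more reason partial-detection
results should be discarded.

Survivors are ranked by the normalized difference score

$$D = \frac{\sum_{i=1}^{n_F+n_R} (O_{G,i}-E_{G,i})^2 + (O_{T,i}-E_{T,i})^2}
          {2\,(n_F+n_R)}
    + \frac{100 - m_F - m_R}{10^5}$$

where \(n_F, n_R\) are observed window lengths, \(m_F, m_R\) expected
pattern lengths (equal for the two directions), and O/E observed and
expected relative intensities. Observed positions beyond the expected
length take expected intensities of zero, so spurious tail peaks are
penalized; uninformative positions contribute nothing to the sum but stay
in the denominators, which are defined purely by the detected window.
The final term is a small tie-break favoring longer expected tracts; for a
perfect noiseless match the score reduces to \((100 - 2L)/10^5\), e.g.
0.00042 for a `(TG)11T7` homozygote. Ties are broken by canonical label so
ranking is deterministic.

Positions at which surviving genotypes expect different base sets
(including "no base" where patterns differ in length) are the
*informative positions* - shaded in the plots, they are where a reviewer
should look to discriminate among the remaining candidates. They are
computed over survivors only: a position that separates candidates already
eliminated carries no remaining information.

## The simulator

`simulate_read()` renders each allele's template (5' context + tract + 3'
context) as Gaussian peaks at uniform spacing (12 trace points per base,
sigma 3) with half amplitude per allele, sums the two allele traces
anchored at the read's 5' end - so unequal allele lengths drift out of
register downstream of the tract, reproducing the overlapping-peak
phenomenology - then adds optional channel bleed-through (each channel
leaking a fraction into its spectral neighbor: T to G, G to T, A to C,
C to A), additive Gaussian noise, clipping and integerization. Base calls
are the per-peak argmax channel. Output is deterministic given the spec's
seed, with separate substreams per direction. An optional superposed
tandem duplication on one allele copy reproduces the heterozygous-indel
failure class for QC tests.

Numerical detail: each peak is rendered on a support of one base cell
(within one spacing of its center), so a noiseless peak-center sample sees
only its own base's signal and relative intensities are exactly the
allele-dosage ratios; this is what lets tests assert the closed-form score
to machine precision. Peak height defaults to 1000 analyzer units summed
over both alleles; the noise level used in robustness tests is 50 (5
percent).

What the simulator does *not* model: dye mobility shifts, polymerase
slippage/stutter, dye blobs, quality decay along the read, or non-uniform
peak spacing. Passing tests therefore demonstrate the correctness of the
inference machinery under controlled dosage arithmetic, not performance on
degraded clinical traces - for real data the signal thresholds exist
precisely because those artifacts occur.

## The bundled reference

`inst/extdata/synthetic_cftr_amplicon.fa` is a **synthetic stand-in** for
the amplified *CFTR* intron 9-exon 10 junction region: its primer sites
(the published assay primer pair), its 427 bp product size and its
`(TG)11T7` reference tract follow published constants, but the remaining
flanking sequence is invented. It was designed so the detection rules are
exact over the whole default search space: the 15 bp anchors plus 12
further bases on the tract-facing side are A/C-only (upstream) and T/G-free
(downstream), so superposed out-of-register flanks never mimic tract
signal, and each anchor occurs uniquely with at least four mismatches of
slack. The frozen anchor constants in the package come from this sequence.
**Analyzing real chromatograms requires re-freezing the two 15 bp anchors
from the genuine GRCh38 flanks** (and being aware that a real downstream
flank contains bases that the expected-pattern model deliberately ignores).

## Degenerate inputs and failure contract

The two clinically meaningful failures are report statuses, not errors:
`tract_not_detected` (an anchor is missing or ambiguous; exit code 2 on
the command line) and `no_matching_genotype` (every candidate eliminated;
exit code 3). Partial tract detection and suspected indel interference
are warnings on an otherwise ordinary report. Empty observations, invalid
search spaces, malformed ABIF files and out-of-range plot indices raise
classed errors.

## Problem sizes used by the test suite

The exhaustive recovery checks run a 210-genotype subgrid (T5-T9 by
(TG)10-(TG)13) noiselessly and across five seeds at 5 percent noise; the
independent brute-force oracle is compared on 50 simulated samples spanning
the full default space with mixed noise and bleed-through; closed-form
score checks cover all 81 homozygotes. These sizes exercise every allele
of the default space in some test while keeping the default suite quick.

## Known limitations

* Heterozygous insertions/duplications/deletions in the amplicon are
  flagged, not resolved.
* Alleles with interrupted repeats (non-TG bases inside the TG run) are
  outside the model.
* Ranking is by raw score; no calibrated posterior probability is
  attached to a call.
* The bundled reference is synthetic (see above); real-data use needs the
  genuine flanks.
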
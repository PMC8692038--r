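---
title: "silkforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{silkforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkforge)
```

## The problem

Spidroins — spider silk proteins — share a three-part architecture: a
conserved N-terminal domain (NTD), a long highly repetitive domain built
from tandem repeat units, and a conserved C-terminal domain (CTD). The
repetitive domain is what matters mechanically (poly-alanine blocks form
β-sheet crystals; glycine/proline-rich motifs form the elastic matrix), and
it is also exactly the part that defeats conventional short-read assembly:
near-identical tandem copies collapse into a single cycle of the de Bruijn
graph, so assembled contigs stop at the repeat array from both sides.

silkforge implements the curation strategy used for spidroin catalogues in
orb-weaving spiders as a reusable toolkit: reconstruct the unique terminal
regions from short reads by targeted seed-and-extend, then confirm the
full-length architecture — in particular the number of repeat units — with
single long reads spanning the whole locus, and finally classify the gene
into a spidroin family from the repeat-motif content of its units. Around
that core sit the standard companions of such a study: an NTD phylogeny,
expression (TPM) and proteome-share profiling, and the two silk fibre
measurements (tensile mechanics, WAXS crystallinity).

Everything is exercisable on synthetic data: the generator module is
first-class, tested code, and every downstream stage is validated against
the generator's ground truth.

## The synthetic generator and what it emulates

`build_gene()` assembles a gene as NTD + n tandem repeat units + CTD from a
family *motif grammar* (`spidroin_grammars()`): each unit carries at least
one family core motif (e.g. GPGPQ for MaSp4, GGLGGSG/GSGGR for MaSp5,
SGGRGGY for MaSp3) and the family's tail rule (poly-A, poly-GA, a
neutral-residue poly-X block such as VSVVSTTVS, or no tail). Spacer
residues are drawn from a glycine/serine-rich alphabet that excludes
alanine, so poly-A runs occur only where the grammar puts them, and units
are rejection-sampled so no other family's core motif appears by chance —
that makes the generate-then-classify round trip exact and the
classification test meaningful.

Two generator choices deserve emphasis:

* **Repeat homogeneity.** One unit is sampled per gene and its coding
  sequence tandem-duplicated (`repeat_divergence = 0` by default). This is
  the defining property of real spidroin repeat arrays at the scale that
  matters here: it is what makes the array collapse in the de Bruijn graph
  and what lets a single consensus unit tile the long reads. A divergence
  knob exists for less idealised arrays, but the reference conditions use
  exact copies.
* **Terminal domains.** The real terminal-domain sequences are not
  redistributed; `make_terminal_domains()` deterministically builds a
  synthetic reference set (150 aa NTDs, 100 aa CTDs; labelled `synthetic`
  in the packaged FASTA) with a clade structure — MaSp2 and MaSp4 share a
  clade, the three MiSp subfamilies share a clade — at roughly 80% within-
  clade and 30% between-clade identity. This reproduces the *topology* of
  the real NTD phylogeny (MaSp4 inside the MaSp2 clade) without claiming
  sequence fidelity.

Reads: short reads are fixed-length, uniformly placed, strand-symmetric,
with i.i.d. substitutions; long reads draw lengths from a gamma (shape 2,
mean `mean_len`) truncated at the source length, with errors split 60/20/20
between substitutions, insertions and deletions — a generic Nanopore-like
profile. Paired short reads use a normal insert (sd = 10% of the mean);
none of the quality-by-position structure, chimeras or PCR duplicates of
real libraries is modelled, so passing tests say nothing about those
failure modes. All generators are deterministic under a seed, record the
origin interval of every read (0-based half-open, strand `+`/`-`), and the
study conditions are frozen in `run_config()`: a 12-unit gene
(450 nt NTD + 12 × 120 nt units + 300 nt CTD) with 300 nt genomic flanks,
50× 150 bp short reads, 15× long reads (mean 5 kb) at 8% error.

## Seed-and-extend reconstruction

`build_debruijn()` counts canonical k-mers (k odd, default 31, so no k-mer
equals its own reverse complement) and links them through (k+1)-mers into a
bidirected graph; `extract_unitigs()` walks maximal non-branching paths.
The node-count cutoff `min_count` defaults to 2, but accepts `"auto"`,
which places the cutoff at the first valley of the k-mer count histogram —
the standard spectrum-based separation of error k-mers from true coverage.
At 50× with 1% substitution error the fixed cutoff of 2 retains doubled
error k-mers that fragment the graph, while the valley rule (cutoff ≈ 5–6)
keeps the four expected unitigs; the pipeline therefore uses `"auto"`.

`find_terminal_seeds()` six-frame-translates each contig and aligns every
frame locally (BLOSUM62, gap open 10 / extend 1) against the terminal-domain
reference set; hits above `min_score` (default 150 bits-like, far above the
empirical null of random contigs, far below domain self-scores of ~800)
become seeds with coordinates on the contig's forward strand.

`extend_seed()` is the core loop: take the terminal `anchor_k`-mer of the
consensus (default 51 — large enough that a single anchor is effectively
unique in a gene-scale locus), collect all reads containing it exactly in
either orientation, stack the bases beyond the anchor into position-weight-
matrix columns, and append a column's majority base while depth ≥
`min_depth` (5) and majority frequency ≥ `min_frac` (0.8). Ties between two
bases halt the walk rather than guess — curation favours precision. The
walk re-anchors after each batch and stops with one of three recorded
reasons: `no_support` (thresholds failed — e.g. a coverage gap),
`max_length`, or `repeat_boundary`.

Repeat boundaries are detected by lagged self-match: within a trailing
window (default 300 nt), if some period q ≤ `period_max` (150) has base(i)
= base(i+q) for ≥ 90% of window positions, the consensus has entered a
tandem array. `detect_repeat_boundary()` then reports the smallest such
window start as the boundary, with the best period attached. The window
must be at least twice the maximum period so that a genuine tandem signal
(at least two copies) is required; purely random sequence never reaches the
0.9 threshold in practice (tested over 50 seeded 2 kb sequences). Because
boundary checks run between extension batches, the consensus may overrun
the boundary by up to one batch; the reported boundary position comes from
the full scan and is used to trim candidates before long-read mapping.

The N-side candidate extends the NTD seed 3′ into the gene; the C-side
candidate works on the reverse complement (so its growth is also left to
right) and is flipped back for reporting. On error-free 50× reads both
candidates reproduce the source exactly (identity 1.0) up to a point inside
the first repeat units; at 1% error the PWM consensus is still exact in
practice because a wrong call needs a majority of erroneous reads at one
column.

## Long-read confirmation

Long reads at 8% error cannot be matched exactly, so confirmation works in
three steps. (1) An optional, deliberately minimal correction stage
(`correct_long_reads()`): a base covered by any k-mer absent from the
trusted short-read spectrum is repaired only when exactly one substitution
restores *all* covering k-mers — ambiguity leaves the base untouched, and
indels are not corrected. (2) `map_candidate()` anchors each
(repeat-trimmed) candidate on each read by shared 15-mers, filters them to
a consistent diagonal band, and bridges the span with one global-local
alignment; identity is computed over aligned non-gap columns. A read
mapping both the N- and C-side candidates on one strand in gene order is a
*full-length* support (`flag_full_length()`). (3) `count_repeat_units()`
tiles the inter-terminal segment of each full-length read greedily left to
right with the repeat-unit consensus at `min_identity` 0.7 (low enough for
8% read error over a 120 nt unit, high enough to reject random sequence,
whose identities sit near 0.55). The *modal* count over full-length reads
is the reported architecture — an automatic stand-in for the by-eye
curation of mapped long reads that such screens traditionally end with.

The repeat-unit consensus itself comes from the N-side candidate's periodic
tail: the detected period (120 nt here) is cut at the boundary, shifted to
the reading frame implied by the NTD hit, and rotated codon-wise to the
rotation that maximises grammar-motif hits (+2 for a recognisable tail) —
tandem arrays are rotation-invariant, but motif scanning is not, so the
rotation with the tail at the unit end is the canonical representative.

## Cataloguing and classification

`decompose_repeats()` estimates the dominant period of a protein by
maximising, over lags, the number of self-matching positions within the
best contiguous span where lag-windows reach 80% identity, then cuts the
span into units (ties toward the shortest period, so a two-unit lag never
beats the true period; spans must yield at least two units). Random
proteins yield nothing.

`scan_motifs()` records exact-substring motif hits (degenerate matching is
deliberately off: the grammars are literal motif tables) and classifies the
unit tail with fixed precedence: a trailing run of ≥ 4 alanines is poly-A;
a trailing tandem of ≥ 3 GA is poly-GA; a trailing stretch of ≥ 6 residues
from {S, V, I, T, L} is poly-X; otherwise none. The thresholds are
implementation choices; the neutral-residue alphabet follows the observed
poly-A replacements (S, V, I, T plus the leucine of SSSVAISL).

`classify_family()` scores each family as (fraction of units with a core
motif) + a tail bonus averaged over units: 0.5 for the family's primary
tail rule, 0.25 for a secondary rule. The graded bonus is what separates
MiSp1B (poly-A primary) from MiSp1D (poly-GA primary), which share cores;
families whose tails are genuinely interchangeable therefore resolve
deterministically, and the acceptance case treats MiSp1B/D as one group.
Nomenclature follows repeat content: an NTD clade assignment that
contradicts the motif winner is flagged (`conflict = TRUE`) but does not
override it, and an NTD in the winner's own clade — the MaSp4-with-MaSp2-NTD
case — is not a conflict.

`composition_stats()` reports exact residue fractions with a cysteine-rich
flag (`crp_threshold` 0.05, comfortably below the 10%-cysteine positive
control and above background); `designate_spice()` ranks non-spidroin
proteins by proteome share subject to an mRNA floor (TPM > 1, top 4).

## Phylogeny

The NTD phylogeny uses the first 100 residues (`n_terminal_region()`),
pairwise global-alignment p-distances (identical columns over aligned
non-gap columns; BLOSUM62, gap 10/1), and a hand-implemented canonical
neighbor joining (`neighbor_joining()`): Q-matrix selection with ties
broken toward the lowest index pair, the standard branch-length formulas,
and negative branch lengths clamped to zero with the deficit moved to the
sibling so the pair's sum is preserved. On exactly additive matrices the
output reproduces the generating topology and path lengths to 1e-9 (tested
against 100 random trees and cross-checked against an independent NJ
implementation). Trees are returned as `ape` `phylo` objects, so newick IO
is standard.

Bootstrap support resamples columns of a stacked pseudo-alignment (pad to
the longest sequence with terminal gaps) and rebuilds replicate trees from
p-distances, reporting the percentage of replicates containing each
bipartition of the point tree. The padding stack is a deliberate
methodological substitution for progressive multiple alignment (a
non-goal); it is exact when the regions have equal length — the usual case
for fixed-length N-terminal regions — and only approximate otherwise. The
distance model is an uncorrected p-distance (no Poisson correction), the
conservative choice when the true model is unstated.

## Expression, proteome and silk metrics

TPM is implemented from its definition (rate = count/length, scaled to sum
to 10^6), with raw CDS length as the effective length — the contract here
is the formula, not a quantifier. Ratios use a pseudocount (default 0.5)
for sparse silk tables; shares are intensity fractions (an intensity-based
reading of proteome percentages, chosen where the metric is unstated).

`mechanics_summary()` integrates stress over strain by the trapezoid rule;
1 GPa × unit strain ≡ 1000 MJ m⁻³ is encoded exactly once. Young's modulus
is the least-squares slope over strain ≤ 0.02 (the initial linear region;
the fit window is a package choice). The break point is the last sample,
so curves must be truncated at failure by the caller.

`fit_crystallinity()` decomposes a background-subtracted 1-D WAXS profile
into n crystal Gaussians plus one amorphous-halo Gaussian by
Levenberg–Marquardt least squares; crystallinity is the crystal area over
total area. Identifiability is kept by initialising the halo wide and
bounding its width below at three times the largest initial peak width,
and amplitudes at zero; with a pure halo the forced peaks fit to ~zero
area. The number of crystal peaks is a required user input (silk profiles
typically fit the (120)/(200)/(211) reflections). Recovery on synthetic
profiles with 1% additive noise is within ±0.01 of truth across crystal
fractions 0.10–0.50.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script — a ~2.2 kb gene
at 50×/15× coverage, 100 random trees of 6–10 taxa, 50 fit replicates per
crystallinity fraction, 1000 random TPM tables — are desk-scale choices
that keep the whole validation suite comfortably reproducible on one CPU
while still exercising every code path at the stated study conditions.
Coordinates are 0-based half-open throughout with strands as `+`/`-`;
every stochastic function takes an explicit seed and restores the caller's
RNG state.

## Known limitations

* The assembler is a curation tool, not a general assembler: no paired-end
  exploitation beyond treating mates as reads, no scaffolding/polishing,
  no diploid phasing.
* Long-read correction repairs isolated substitutions only; it is exposed
  as an optional stage and the mapper does not depend on it.
* The terminal-domain reference set and the grammar table are synthetic /
  partially reconstructed stand-ins: real screens should supply their own
  domain FASTA and extend the grammar TSV-style via `spidroin_grammars()`.
* Classification assumes units from one gene; chimeric inputs will score
  as mixtures.
* The bootstrap's padded pseudo-alignment degrades for length-heterogeneous
  inputs; supply equal-length N-terminal regions.
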
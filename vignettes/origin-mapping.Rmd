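---
title: "Mapping replication origins with arscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication origins with arscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arscan)
```

This vignette is the package's account of the science behind each
analysis stage: the models, the conventions chosen where several were
defensible, the tunable parameters, and what the synthetic-data tests
do and do not establish about real data.

## The biological setting

An autonomously replicating sequence (ARS) is a DNA fragment that
supports replication of an episomal plasmid — the classic functional
proxy for a chromosomal replication origin in yeast.  A high-throughput
ARS screen clones a partial restriction digest of genomic DNA into a
non-replicating selective vector; only fragments containing an origin
yield colonies, and sequencing the surviving inserts maps origin
activity genome-wide.  In the system this package targets, origins come
in two classes: those carrying a 20 bp G/C-rich consensus motif with a
TYGAAC core (GC-ARSs), which sit in long, promoter-rich intergenes,
replicate early and show an extended (~450 bp) nucleosome-depleted
region (NDR) on the motif's 5′ side; and A/T-rich origins (AT-ARSs)
with a repetitive, alignment-resistant determinant, later replication
and a conventional single-nucleosome (~150 bp) NDR.

## Screen analysis (fragment tables to origin cores)

Mapped fragments are tibbles of 0-based half-open intervals with read
depth.  The processing chain is:

1. **End validation** (`validate_fragment_ends()`): each end snaps
   *outward* to the nearest restriction-site boundary within a
   tolerance (default 10 bp — the underlying protocols do not state a
   value, so it is an exposed parameter), removing truncation
   products.  A fragment with no site within tolerance keeps its
   coordinates and is labelled `"unk"`, mirroring the convention of the
   screen's supplementary tables.
2. **Assembly** (`assemble_contigs()`): transitively overlapping
   fragments become one contig.  Overlap means ≥ 1 shared bp; with
   half-open intervals, fragments that merely touch do not overlap.
   The sweep implementation is checked in the test suite against a
   brute-force O(n²) connected-components oracle.
3. **Filters**: ARS-seq contigs with combined read depth 1 are removed;
   miniARS contigs (built from sheared subfragments with read depth
   ≥ 2) need at least three unique member intervals.
4. **Bridge resolution** (`resolve_bridged_contigs()`): the published
   screens resolved chimera-bridged contigs manually by read depth.
   As an automated stand-in, a contig is split where an internal
   per-bp-depth valley is strictly below `bridge_fraction` (default
   0.1) of the smaller flanking maximum, and bridging fragments are
   dropped.  The strict inequality makes the boundary case
   (valley exactly at the threshold) a non-split.
5. **Core inference** (`infer_core()`): the functional core is the
   intersection of member fragments; cores shorter than 150 bp are
   extended symmetrically to exactly 150 bp.  At a chromosome end the
   clipped deficit is added to the opposite side, a convention the
   source material leaves open.  An empty intersection (possible after
   a chimera split) is flagged and falls back to the highest-depth
   fragment's overlap set.

Compiled tables use systematic names — chromosome letter plus midpoint
in kb (`A2772` = first chromosome, 2,772 kb) — with deterministic
`.2`, `.3` suffixes for collisions, and are exported 1-based inclusive
to match supplementary-table style; everything internal stays 0-based
half-open, converted exactly once at the file boundary.

## Motif scanning and the GC/AT split

Window scores are log-odds in **bits**:
$S = \sum_j \log_2 \frac{p_{\mathrm{PWM}}(b_j \mid j)}{p_{\mathrm{bg}}(b_j \mid \mathrm{context})}$,
with the background a 5th-order Markov model fitted to intergenic
sequence by maximum likelihood with add-one smoothing and
reverse-complement-symmetrized counts.  Near a sequence start the
context truncates to the longest available prefix (the model stores
all orders 0–5), so every window is scorable.  Whether the historical
screen scores were bits, p-values or E-values is not recorded; bits
were chosen and are stated in every output.  Minus-strand windows are
scored by scanning the reverse complement, which together with the
symmetrized background makes the hit set exactly mirror-equivariant (a
tested invariant).  Best hits break ties deterministically: lowest
offset, then plus strand.

The GC/AT classification fits one- and two-component Gaussian mixtures
(via `mclust`) to the per-origin best-hit scores.  A fixed valley
threshold would hard-code what is really a property of the score
distribution; the mixture operationalizes "bimodal" and returns "no
split" when BIC prefers one component, when fewer than 10 scores are
supplied, or when the scores are degenerate.  The class boundary is
the equal-posterior point between the two component densities, and the
upper component is labelled GC, so `class == "GC"` iff
`score >= threshold`.

## Deep mutational scanning

Competition libraries are mutagenized oligos (2% per-base substitution
probability; substitutions only, because positional analysis of a
fixed-length element breaks under indels) sampled at 0, 12, 24 and
36 h.  Analysis is positional: `freq(b, i)` is the read fraction of
base *b* at position *i*, and the enrichment score is
$\log_2 \left( \mathrm{freq}_t / \mathrm{freq}_0 \right)$ per
(position, base) cell, masked when either timepoint has fewer than
`min_count` (default 5) reads — the source gives no floor, so it is a
parameter.  Cell-wise replicate averaging propagates masks and reports
inter-replicate Pearson correlation.

Constrained regions are runs (merged within `window_bp`) of positions
whose mean non-reference enrichment falls below `drop_threshold`
(default −1, i.e. 2-fold depletion of the average mutant).

**Reference-base convention in the PWM conversion.**  Converting
enrichment ratios to allele frequencies (floor every cell at the 0.2
cutoff, then normalize the column) needs a value for the wild-type
base.  Under positional accounting the wild-type's raw frequency ratio
is pinned near zero in a 2%-mutagenized library (at most
log2(1/0.98) ≈ 0.03), which would floor *every* cell and yield a
uniform column.  The package therefore expresses the column in the
reference-relative frame: when `ref_seq` is supplied, the wild-type
cell carries its selection advantage over the average mutant allele,
$-\overline{\mathrm{ratio}}_{\mathrm{nonref}}$.  At a constrained
position this gives, e.g., a column like (3, 0.2, 0.2, 0.2) and a
consensus equal to the wild-type base; at an unconstrained position all
cells floor to the cutoff and the column is uniform.  Without
`ref_seq` the supplied values are floored and normalized as given.

## Replication timing

Sorted S- and G1-phase reads are binned into non-overlapping 1 kb
windows (each read increments exactly one bin), totals are equalized,
and the per-bin ratio is scaled by 1.5 because the average mid-S cell
has replicated half its DNA — mapping true copy number 1–2 onto a 1–2
ratio band.  Zero-G1 bins are masked, never infinite, and masked bins
are skipped by the smoother.

The replicate-mean track is LOESS-smoothed per chromosome — local
linear with tricube weights, with the bandwidth expressed in **kb**
(default 30 kb half-width) rather than a span fraction so behaviour
does not depend on chromosome length.  The smoothed curve is
"normalized to a baseline of 1" by dividing by the 2nd percentile of
the positive smoothed values: the late-replicating floor is the only
robustly interpretable baseline, since the minimum is noise-sensitive
and the mean is not 1 in either limit.

Peaks are turning points of the smoothed curve (sign changes of first
differences, with a small numeric tolerance so floating-point ripple
on flat tracks is not a turning point; plateaus yield their centre
bin), filtered by topographic prominence.  The default
`min_prominence = 0.02` normalized-ratio units suppresses the numerous
small shoulders a raw turning-point list contains; passing 0 recovers
the unfiltered list, so both conventions are available.

Class comparisons follow the study design: normalized values at origin
midpoints (with an "isolated" flag when no other origin lies within
40 kb on both sides), Welch t-tests between classes and against the
genome, removal of all bins within two-sided 30 kb windows around a
class ("60 kb ranges" and "30 kb windows" in the source are read as
the same two-sided 30 kb), and origin-to-nearest-peak distances
against uniform random control loci with KS tests.

## Nucleosome metaprofiles

MNase fragment tables become per-bp density tracks: in dyad mode each
fragment covers midpoint ± 73 bp (the standard mononucleosome
footprint convention; the source does not state its coverage
definition, so span mode is also provided), scaled to genome-wide mean
1 — per genome, not per chromosome, so chromosomes keep their relative
coverage.  Metaprofiles stack track slices around anchors, reverse
minus-strand rows, order rows by a ranking score, and append column
means.  NDR width is measured as the contiguous run of offsets below
half the genome mean (0.5) containing the profile minimum.

## The synthetic genome: what it emulates, and what it does not

`synth_config()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 2 × 1 Mb | desk-scale genome preserving multi-chromosome logic |
| genes per chromosome | 500 | gene-dense layout; median intergene 216 bp (log-normal, σ = 0.95) |
| GC / AT origins | 12 / 10 | ≈ 1 origin per 90 kb, the yeast-like density; GC slightly outnumbering AT keeps both classes testable |
| GC intergene factor | 4× | reproduces the long-intergene association (median ≈ 864 bp vs 216 bp) |
| strengths | GC 50, AT 5 | 10× capture-depth contrast between classes |
| firing | GC 12 min, AT 22 min (SD 2.5), efficiencies 0.9 / 0.85 | GC early, AT late; both efficient enough to form peaks |
| fork rate / S phase | 2 kb/min, 40 min | typical yeast replication kinetics |
| restriction site | GATC | four-cutter digest; partial digestion skips Geometric(0.5) sites per side |
| nucleosome repeat | 165 ± 8 bp | typical yeast repeat length |
| NDRs | 450 bp at 40 bp 5′ of GC motifs; 150 bp at AT elements and TSSs | the two observed depletion geometries |
| poly(dA) tract | 26 bp ending 10 bp 5′ of each GC motif | the upstream poly(dA) signature spanning the 10–35 bp band |
| mutagenesis | 2% per base, substitutions only, ≥ 20,000 variants | library design of the competition assay |

Planted origins are spread on a jittered even grid of intergenes with
a minimum 40 kb midpoint spacing, so each origin can resolve as its own
peak under 30 kb smoothing; this is a modelling choice about origin
*placement*, realistic for yeast origin spacing but deliberately
avoiding tight origin clusters.  Motif instances are sampled from the
PWM with the six core columns restricted to their strong bases, so the
TYGAAC core is never destroyed while flanks retain natural
variability.

The fork model is per-cell: each origin fires with its efficiency at a
Normal time, forks move at constant speed, and a locus replicates at
the minimum over fired origins of (firing time + distance / rate);
S-phase cells are sampled uniformly through S, giving bin copy numbers
in [1, 2], and reads are Poisson around copy number.  Deterministic
fork speed with stochastic firing is the simplest model producing the
observed ratio band and peak geometry.

Features of real data deliberately **not** modelled: PCR and
sequencing-composition bias, plasmid copy-number effects, FACS gate
impurity, transformation-efficiency variation, MNase sequence bias,
indels, mappability gaps and repeats.  Passing recovery tests
therefore demonstrates the correctness of the algorithms under the
stated generative model, not robustness to every artefact of real
libraries.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on the
2 Mb default genome at 2,900 reads per 1 kb bin per sample (the
sorted-cell sequencing depth), the mutational scan at 20,000 variants
× 500,000 reads per timepoint × 2 replicates, and nucleosome analyses
at 2–3 × 10⁵ fragments; these sizes give stable recovery metrics while
keeping a complete run in minutes on one CPU.  Every simulator takes a
seed and is byte-reproducible under it; Monte-Carlo p-values use the
add-one correction (b + 1)/(m + 1), so they are never exactly zero.

One power note: with only 12 planted GC origins, the genome-scale
Monte-Carlo intergene test is underpowered (a 4× median enrichment at
n = 12 under length-weighted sampling is not significant), which is
why the acceptance script reports that test both at genome scale and
at the ~100-element scale of the real GC class, where p < 0.01.

## Known limitations

* The bimodal split assumes approximately Gaussian score modes; a
  heavy-tailed AT-class score distribution could bias the threshold.
* `resolve_bridged_contigs()` splits at most one valley per contig per
  pass; pathological multi-chimera contigs would need repeated passes.
* The peak caller reports bin-resolution coordinates; sub-kb peak
  placement is outside its design.
* Expression-based ranking of TSS metaprofiles is accepted as an input
  column, not computed, since it requires external expression data.
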
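---
title: "Methods: anti-silencing analysis of transposable elements"
author: "vanscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anti-silencing analysis of transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vanscape)
library(data.table)
```

# The system being modelled

Plant genomes silence transposable elements (TEs) by DNA methylation in
three sequence contexts (CG, CHG, CHH; H = A/C/T). Some *Arabidopsis*
VANDAL-family DNA transposons encode VANC-class anti-silencing proteins
that reverse this repression in a strikingly sequence-specific way: a VANC
protein binds a short degenerate DNA motif that accumulates as
same-orientation tandem arrays in the non-coding regions of its own TE
family, and the bound family — and only that family — loses methylation.
The loss has a characteristic geometry: CG methylation drops locally,
around the motif arrays where the protein sits, while CHG/CHH methylation
is lost across the entire element.

vanscape implements the computational side of that analysis as a reusable,
fully testable pipeline: differential methylome profiling from
per-cytosine bisulfite reports, a count-weighted hypomethylation
significance statistic, CG-DMR calling, degenerate motif
scanning/typing/array detection, discriminative motif discovery, ChIP
enrichment summaries, and an evolution toolkit (dot plots, tandem-repeat
detection, Poisson-correction distances, neighbor-joining trees with
bootstrap). Because the real sequencing data cannot be assumed present,
the package ships a simulator that plants all of these signals with
machine-readable ground truth; every downstream method is validated by
parameter recovery against what was planted.

# The hypomethylation significance statistic

For one TE and one context, let `Mn`/`Cn` be the methylated and total
cytosine read counts pooled over the element in the non-transgenic
condition and `Mt`/`Ct` the same in the transgenic condition. The
statistic is

$$ \frac{M_n/C_n - M_t/C_t}{1/\sqrt{C_n} + 1/\sqrt{C_t}} $$

i.e. the drop in methylation ratio weighted by the square root of the
read counts, so that equal ratios score 0 regardless of depth and a fixed
ratio drop grows as $\sqrt{k}$ when counts grow as $k$. Two properties
make it convenient to test exactly: it is antisymmetric under swapping
the two conditions (when `Cn = Ct`), and multiplying all four counts by
$k^2$ multiplies the value by $k$. Zero totals make the value undefined
(`NA`), never silently zero.

```{r}
significance_value(90, 100, 10, 100)   # (0.9 - 0.1) / (0.1 + 0.1)
significance_value(360, 400, 40, 400)  # same ratios, 4x counts
```

# Methylome summaries

All summaries pool raw counts (sum of meth / sum of total) rather than
averaging per-site ratios, so sparse windows are dominated by the sites
that are actually covered and zero-coverage windows propagate as `NA`.
Methylation is pooled across strands within a context; the CX report
lists both strands separately but the analyses do not stratify by strand.

* **Fractional TE profiles** (`fractional_profile()`): each TE body is cut
  into 100 equal fractions and values are pooled over a sliding window of
  7 consecutive fractions, giving 94 points oriented 5ʹ→3ʹ on the TE
  strand. Flanks of the TE's own length are profiled identically. The
  flank length is proportional (not fixed) because the profile's x-axis
  is fractional; this keeps flank resolution comparable across TE sizes.
  TEs shorter than 100 bp are skipped explicitly.
* **Running profiles** (`running_profile()`): browser-style curves pooling
  each cytosine with its 4 successors in the same context; the last 4
  sites of a series are undefined.
* **Summit metaplots** (`summit_metaplot()`): for offsets at 50-bp steps,
  counts are pooled over a 500-bp window centred on the offset across all
  summits. Offsets are bin centres and the whole bin stays within the
  span, so a ±5 kb span yields (10000 − 500)/50 + 1 = 191 positions. The
  default span of ±5 kb is configurable.

# CG-DMR calling

Each chromosome is tiled with non-overlapping 100-bp windows from
coordinate 0. A window seeds a DMR when the CG methylation level drops by
at least 0.5 between conditions; runs of seeds separated by at most one
non-seed window are merged into a single region spanning the seeds and
the bridged gap. Two choices are not dictated by the definition and are
therefore explicit, configurable defaults:

* `min_covered_sites = 4` covered CG positions per window per condition.
  A 0.5-level call from one or two reads is noise; four covered sites at
  ~30x is the loosest filter that keeps the false-seed rate negligible in
  simulation.
* The tiling origin is coordinate 0 of each chromosome.

The caller is verified against a brute-force oracle (independent
window-by-window loop plus explicit merge scanning) on hundreds of random
toy genomes, including the one-gap merges.

# Motif analyses

Patterns are IUPAC strings; scanning reports every occurrence including
overlaps, on both strands, with `N` in the subject never matching.
Concrete instances of the YAGTATTAY consensus are typed by their terminal
base (C-type/T-type); AGTTGTCC and AGTTGTAC are the CC/AC types of the
second specificity. Counting per TE assigns hits by start-position
containment, with a pooled `background` row — both strands, overlaps
allowed, since the counting convention is not otherwise constrained.
Arrays are maximal same-strand runs of ≥ 3 hits with start-to-start gaps
≤ 200 bp; both thresholds are exposed because "high density" is a
qualitative observation, and they are reported with the output.

`motif_min_mismatch()` takes the minimum Hamming distance over all
concrete instance pairs and ungapped offsets of the shorter pattern in
the longer, forward strand only (both motif sets are reported in a fixed
orientation):

```{r}
motif_min_mismatch("AGTTGTAC", "YAGTATTAY")
motif_min_mismatch("AGTTGTCC", "YAGTATTAY")
```

**Discovery** (`discover_motifs()`) is a deliberately transparent,
DREME-like discriminative search: exhaustive enumeration of every exact
word of width 6–9 present in at least one positive sequence, a one-sided
Fisher exact test on the number of positive vs negative sequences
containing each word (computed as a vectorised hypergeometric tail), then
greedy single-position IUPAC generalisation of the best words whenever it
lowers the p-value. E-values are Bonferroni-style (p × number of exact
words tested), which is conservative; word heaps and richer regular
expressions of the original heuristic are intentionally not replicated.
The width cap of 9 matches the target motif class.

# ChIP enrichment

Coverage tracks are normalised to counts per million mapped reads, which
preserves ratios between positions exactly. Enrichment is summarised as
the mean normalised depth of IP and input in 10-kb tiles with a
pseudocounted ratio; the pseudocount (default 0.5 CPM) and the decision
to emit both the IP signal and the ratio are explicit because "signal" is
not otherwise pinned down. Terminal partial tiles are kept and flagged.
Masks (e.g. centromeric satellite regions) drop whole tiles. Summit
annotation labels each summit by the containing TE segment
(coding/non-coding) under closed-interval containment.

# Evolution toolkit

* **DNA dot plots** place a point wherever two 10-bp words match exactly;
  tandem repeats of n and m copies produce n + m − 1 parallel diagonals.
* **Protein dot plots** use a 10-residue sliding window with a BLOSUM62
  score threshold of 23 (the matrix name is recorded in the output; it is
  fixed to BLOSUM62 as the conventional default for this style of plot).
* **Tandem repeats** are found by diagonal periodicity: the sequence is
  compared to itself shifted by each candidate unit length, stretches
  with identity ≥ 0.9 mark a repeat of that period, the consensus is the
  column majority over full copies, and overlapping calls at different
  periods keep the longest spanning region. This is a simplified,
  deterministic replacement for probabilistic repeat-alignment models;
  its parameters (unit range, min copies, identity) are all exposed.
* **Distances** are Poisson corrections, `d = -ln(1 - p)` over ungapped
  columns, undefined (flagged) at `p = 1`.
* **Trees** come from neighbor joining, delegated to the reference
  implementation in `ape` behind `neighbor_joining()`; validation relies
  on the classic consistency property (exact recovery of additive
  matrices) rather than on any tie-breaking convention. Bootstrap
  resamples alignment columns, not sequences, and reports per-edge
  bipartition frequencies; the trivial basal bipartition is `NA`.

# The simulator and what it does (not) emulate

`sim_config()` fixes the study conditions; `simulate_genome()`,
`simulate_methylomes()`, `simulate_chip()` and
`simulate_family_evolution()` generate the data with ground truth. The
defaults describe a desk-scale version of the biological setting:

| parameter | default | rationale |
|---|---|---|
| genome_length | 200 kb | smallest size that holds 20 well-separated TEs |
| families × copies | 4 × 5 | 20 TEs > 1 kb, one targeted family of 5 |
| te_length_range | 2–3.5 kb | typical VANDAL-scale elements |
| repeat unit / copies | 30 bp × 4–8 | arrays of ~120–240 bp |
| unit_divergence | 0.1/site | copies' repeat units diverge, motifs stay intact |
| wt_meth_levels | CG 0.85, CHG 0.40, CHH 0.15 | typical TE methylation in this system |
| bg_meth_levels | 0.05/0.03/0.02 | low background outside TEs |
| hypo drops | CG 0.6 (local, ±250 bp), CHG 0.2, CHH 0.1 (element-wide) | the observed geometry: strong local CG loss, broad non-CG loss |
| mean_coverage | 30x | routine WGBS depth |
| chip_enrichment_factor | 8 | free parameter; no quantitative value is dictated |

Counts are Poisson coverage × Binomial methylation. Motif arrays sit in
non-coding segments on the TE's annotated strand in consistent
orientation; coding segments are scrubbed of the family motif. Each
copy's repeat unit diverges from the family consensus at non-motif sites
(units within one copy evolve together) while the embedded motif instance
is drawn per unit — this mirrors the observation that repeat units vary
considerably between copies while motif instances of both types mix
within arrays, and it is what makes de novo discovery on DMR sequences
single out the motif rather than arbitrary repeat-unit words.

The simulator intentionally does **not** emulate read-level artefacts:
no FASTQ reads, bisulfite conversion errors, PCR duplicates, mapping
bias, or peak-calling noise (summits are planted at array midpoints).
Passing recovery tests therefore demonstrates that the analysis logic is
correct under the stated generative model, not that the pipeline is
robust to upstream artefacts of real libraries.

Determinism: every `simulate_*` stage derives its own seed from
`config$seed` plus a fixed stage offset, so each operation is
individually reproducible and byte-identical across runs regardless of
stage order; `run_full()` writes a manifest of MD5 checksums that is
identical across runs with the same config.

# Coordinates and numerical conventions

Internally all intervals are 1-based closed, the native convention of R
and Bioconductor ranges; on disk the standard formats keep their own
conventions (CX reports 1-based, BED/bedGraph 0-based half-open).
Undefined ratios are `NA`, never 0. Window pooling is exact integer
count arithmetic; the only floating-point steps are final ratios,
distances and p-values.

# Problem sizes used in validation

The shipped tests and the acceptance script run, by choice, at sizes a
laptop handles in seconds to minutes: the default 200-kb / 20-TE
simulation (~100k cytosines per methylome) for end-to-end recovery, 200
random 50-kb toy genomes for the DMR-vs-oracle equivalence, 50 + 50
500-bp sequences for discovery, and trees of up to 8 taxa for NJ
exactness. Headline counts from genome-scale data (thousands of TEs,
~90 DMRs per transgene) depend on a full genome and deposited libraries
and are out of scope; the package validates the methods' behaviour, not
those totals.

# Known limitations

* The DMR caller assumes both conditions were sequenced deeply enough for
  the coverage filter; it does not model biological replicates.
* Discovery E-values are Bonferroni-conservative; with few positive
  sequences (e.g. a handful of DMRs) true motifs can tie with other
  perfectly discriminative words, and the reported rank among ties is
  alphabetical.
* The tandem-repeat finder is exact-period based; highly degenerate
  repeats with indels are outside its model.
* The protein-family simulator uses a uniform substitution model with a
  rate multiplier for conserved domains; it is meant to exercise the
  distance/tree code, not to be a realistic protein evolution model.
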
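---
title: "Models and methods behind scmethpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmethpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmethpipe)
```

## The measurement model

Direct-conversion sequencing chemistry reads a *modified* cytosine as T:
under TAPS, 5mC and (after TET oxidation) 5hmC convert; under CAPS only
5hmC does; unmodified C stays C. The caller's job is therefore the mirror
image of bisulfite calling — at a reference C on the sequenced template
strand, a read T is evidence *for* modification — and the genome retains
its sequence complexity, which is why mapping rates stay high.

`scmethpipe` models one cytosine base call as a Bernoulli draw:

$$
P(\text{read T} \mid \text{state}) =
\begin{cases}
p_{\mathrm{mC}} & \text{state} = \text{5mC}\\
p_{\mathrm{hmC}} & \text{state} = \text{5hmC}\\
p_{\mathrm{uC}} & \text{state} = \text{C}
\end{cases}
$$

followed by an independent uniform substitution error. Conversion events
at distinct sites are independent, and conversion happens once per
original molecule — PCR duplicates inherit their fragment's converted
template and only the sequencing error is redrawn per copy.

The two shipped presets pin these probabilities to the measured
single-cell rates: `sctaps` = (0.966, 0.850, 0.0019) and `sccaps` =
(0.0025, 0.930, 0.0038) for (5mC, 5hmC, C). Under `sccaps`, the 0.0025
entry *is* the 5mC false-positive rate: the chemistry should leave 5mC
untouched, so any 5mC read as T is an error of the method, which is why
the fully methylated spike-in doubles as a false-positive control there.

## Library model and the strand-inference rule

Tagmentation is modelled as uniform fragment starts with uniform insert
lengths (default 200–700 bp; the post-selection insert distribution of a
real library is narrower, but only coverage breadth depends on it) and a
fair-coin template strand. The libraries are **directional: R1 always
reports the converted template strand**. The caller's rule follows
directly: a read derives from the top strand iff it is (R1 ∧ forward) ∨
(R2 ∧ reverse); top-strand reads are scored at reference C positions
(C→T), bottom-strand reads at reference G positions (G→A). Real protocols
do not document the post-conversion strand structure precisely; this is
the simplest model consistent with Tn5 insertion followed by PCR, it is
exactly self-consistent between simulator and caller (verified read-by-read
in the tests), and `infer_template_strand()` is the single point to change
for non-directional data.

Two further caller conventions where common practice varies:

* **Mate overlap** is counted once, preferring R1 — the overlap covers one
  physical template, and counting it twice would double-weight the centre
  of short fragments.
* **`n_other`** (read bases that are neither the converted nor the
  unconverted base) never enters a level denominator: a level is
  `n_mod / (n_mod + n_unmod)`, i.e. modified calls over C-or-T calls.

Duplicates are marked per cell on (fragment start, fragment end,
orientation): fragments from different cells are distinct molecules even
at identical coordinates, so pooling before deduplication would delete
real data. Note that coordinate-based deduplication on a very short
contig (such as the hmC spike-in oligo) flags genuine coincidental
collisions; that is inherent to the coordinate criterion, not a defect of
the simulation.

## Filters and their defaults

| parameter | default | meaning |
|---|---|---|
| `min_mapq` (caller) | 10 | discard ambiguous alignments |
| `end_trim` | 10 bp | ignore call positions near read ends (end-repair artefacts) |
| QC mapping cut | MAPQ > 1, post-dedup | the *properly mapped* count used for cell gating — deliberately looser than the caller's cut |
| cell gate | 500,000–3,000,000 properly mapped reads | too few reads → unusable coverage; too many → suspected doublets/over-amplification |
| `min_calls` (gene bodies) | 5 | a level estimated from fewer than 5 calls is noise; the entry is missing, not zero |
| `min_pct` (markers) | 0.25 | a gene must be detected (non-missing) in ≥ 25% of one side to be tested |
| marker selection | BH-adjusted p < 0.05 | two-sided Wilcoxon rank-sum on raw levels |

## What the simulator emulates, and what it does not

The generator reproduces the features the pipeline's statistics depend
on: per-CpG truth states drawn at global rates (with built-in profiles
`neuron` / `nonneuron` at global 5hmC 22.04% / 9.29%, and a generic
`somatic` profile at 80% 5mC / 5% 5hmC), symmetric CpG methylation by
default, a triangular TSS dip (half-width 2 kb, depth 0.8 — chosen to make
the promoter dip visible at realistic sharpness; the dip is documented
qualitatively in the literature without parameters), the three spike-in
controls, 96 (i5, i7) barcode combinations with pairwise Hamming distance
≥ 3 within each tag set, 120-bp paired reads, PCR duplication, and
uniform sequencing error.

It does **not** emulate repeat structure, mappability, GC-coverage bias,
chromatin-state-dependent methylation, C→T SNVs (which a caller on real
data must mask), indels or quality-score decay. Passing tests therefore
demonstrate correctness of the *computational* method under its stated
model — parameter recovery, filter fidelity, conservation — not
performance on any real genome. Whether a global 5hmC figure is a
per-cell mean or a pooled ratio is ambiguous in published summaries; the
simulator draws per-CpG states at the global rate, under which the two
interpretations coincide in expectation, and `spikein_rates()` /
`coverage_stats()` report pooled ratios.

The spike-in controls deserve one note: the fully methylated control is a
random 2-kb sequence whose every CpG carries 5mC — only that property, not
any particular phage sequence, matters to the estimators. The hmC oligo
carries 5hmC at declared positions only (default: its CpG cytosines), so
the hmC conversion estimate is computed strictly over truth-modified
sites. The unmodified control's false-positive rate pools **every**
cytosine, so the caller should be run with `contexts = c("CG", "CH")`
when feeding `spikein_rates()`. Real libraries add ~0.1% spike-in DNA;
simulated fixtures raise `spikein_fraction` (and shrink the control
contigs) so that each class accumulates ≥ 2·10⁴–10⁵ calls in seconds —
this changes statistical power only, not the estimand.

## Quantification choices

* **Gene bodies** are the full annotated interval; TSS and TES are the
  stranded interval ends. Chromatin-state aggregation is the same
  operation over a BED-derived region table — no separate code path.
* **Metagene profiles** use scale-regions semantics (real-coordinate
  flanks, body linearly rescaled; defaults 5 kb / 5 kb / 5 kb at 10 bp →
  1500 bins). The profile is the pooled mean of *site levels* per bin
  across genes: each covered site contributes its level once per
  overlapping gene, rather than averaging per-gene profiles — pooling
  weights data, not genes, and behaves better when most genes have sparse
  single-cell coverage. Body bins are assigned from the site centre
  (`x + 0.5`), which makes strand mirroring map bin *b* to bin
  *n − 1 − b* exactly whenever the bin count is odd; with an even bin
  count a site centre can land exactly on a bin boundary and is assigned
  to the left bin.
* **Saturation curves** use nested subsamples (every smaller sample is a
  subset of the larger), so monotonicity is guaranteed by construction
  rather than on average.
* **Wilson score intervals** (via `prop.test(correct = FALSE)`) are used
  for spike-in rates because the false-positive rates sit at 0.2–0.4%,
  where Wald intervals collapse or cross zero.

## Clustering and markers

The analysis matrix drops QC-failing cells, drops genes missing in more
than 80% of cells, imputes remaining missing entries with the gene mean,
drops zero-variance genes, and standardises per gene — *for the reduction
only*. Marker tests always run on raw, unimputed levels with missing
entries excluded: imputation would fabricate evidence exactly where
coverage is weakest. The detection fractions `pct_in` / `pct_out` count
non-missing levels, the closest analogue of an expression detection rate
for coverage-limited data.

Clustering is PCA (default 20 components) followed by a
k-nearest-neighbour / shared-nearest-neighbour graph (k = 20, Jaccard
edge weights, weak edges pruned below 1/15) and Louvain modularity
communities at resolution 0.8, or k-means with a fixed seed. These mirror
the de-facto standard single-cell workflow; the acceptance surface is
truth recovery on synthetic populations (adjusted Rand index), never
label-identical output of any particular external tool. The attached 2-D
embedding is deliberately the first two principal components: it is
deterministic, adds no dependency, and labels are never derived from the
embedding, so swapping in t-SNE/UMAP for presentation changes nothing
statistical.

The matrix-level generator `simulate_region_matrix()` encodes the
two-population study conditions directly: 48 + 48 cells, 200 genes of
which 30 are shifted by Δ = 0.15 between populations, per-gene baselines
Beta-distributed around the mean of the two global-5hmC profiles (0.2204,
0.0929), binomial observation noise at ~100 calls per gene and cell, and
entries below 5 calls (plus 5% at random) missing. Putting the
population difference in the shifted genes — rather than offsetting every
gene by the global difference — keeps the null genes genuinely null, so
the same generator supports both the marker-recall condition (Δ = 0.15)
and the false-selection control on null genes.

## Numerical and degenerate-input behaviour

* All randomness flows through explicit `seed` arguments (an isolated RNG
  scope, so the user's global RNG state is untouched); the same seed
  reproduces sequences, fragments, reads, subsamples, and cluster labels
  bit-for-bit.
* Coordinates are 0-based half-open everywhere internally; GTF/SAM
  writers convert at the boundary. The strand of a CpG call is the strand
  of the cytosine; merged CpGs are reported at the top-strand C position.
* Degenerate inputs: zero genes → a valid header-only GTF; an empty call
  table → zero coverage, not an error; a constant gene → dropped before
  standardisation; fragments shorter than the read length → truncated
  reads, logged; unsupported CIGAR operations → read skipped with a
  warning; spike-in classes with zero calls → absent from the report
  rather than reported as 0.
* Non-CpG cytosines carry no modification in the generator by default
  (CpH methylation is negligible in most somatic contexts); the caller
  still scores CH sites when asked, which is how the unmodified spike-in
  pools all cytosines.

## Problem sizes used by the test-suite

The suite simulates small genomes (0.05–0.25 Mb, 4–96 cells, 10³–10⁴
fragments) chosen so each statistical check retains its intended power:
binomial recovery checks run at ≥ 2·10⁴ eligible calls per modified class
and ≥ 10⁵ for the false-positive classes; oracle-equivalence checks
(brute-force pileup, exhaustive Hamming demultiplexing, naive CpG scans)
run at a few hundred reads where bit-identity is meaningful; clustering
recovery uses the 48 + 48 × 200-gene condition above. The full suite and
the acceptance script each complete in a few minutes on one core.

## Known limitations

* The caller assumes a directional library; non-directional data needs a
  different `infer_template_strand()`.
* No SNV masking: a C→T variant is indistinguishable from full
  modification at that site.
* The saturation estimator subsamples fragments, not unseen library
  complexity; it cannot extrapolate beyond the observed reads.
* The SNN implementation computes a dense distance matrix — appropriate
  for plate-scale (≤ a few thousand cells), not atlas-scale data.
* Alignment itself is out of scope: the simulator emits truth-position
  SAM so the pipeline is testable without an aligner, and any external
  aligner producing standard SAM/BAM plugs in via `read_alignments()`.
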
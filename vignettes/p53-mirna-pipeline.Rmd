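---
title: "Methods: identifying p53-regulated miRNAs and their regulatory loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying p53-regulated miRNAs and their regulatory loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53mirnet)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package. The pipeline identifies miRNAs regulated by
an activated transcription factor (the motivating case is p53 activated by
doxorubicin-induced DNA damage in a hepatocellular carcinoma cell line)
from two-condition, two-replicate small RNA sequencing, locates TF binding
sites in miRNA promoters, and enumerates TF–miRNA–gene feed-forward loops.

## Read cleaning

Raw ~50-nt sequencing tags are filtered in a fixed cascade; each read is
charged to the first class it fails, so class counts always sum to the raw
input count:

| class | rule | default |
|---|---|---|
| `low_quality` | mean Phred < threshold, or >10% N | threshold 20 |
| `adapter5_contaminant` | read begins with the first 8 bases of the 5′ adapter | exact match |
| `no_adapter3` | no exact 8-base 3′-adapter prefix anywhere, and the read is longer than the maximum insert | — |
| `no_insert` | zero-length insert after trimming | — |
| `polyA` | trimmed insert ≥ 80% adenine | — |
| `length_out_of_bounds` | insert outside the size-selection bounds | 18–30 nt |

The class names follow the conventional small-RNA cleaning vocabulary, but
the field literature rarely pins down their operational definitions; the
rules above are explicit, deterministic (adapter matching is exact) and
each is unit-testable. One rule deserves a note: a read with *no* 3′
adapter match is discarded only when it is longer than the maximum insert
length. A shorter adapter-free read is treated as an already-trimmed
insert, which makes cleaning idempotent — cleaning an already-clean set
removes nothing — while still discarding full-length tags in which the
sequencer never reached the adapter.

Insert length bounds default to 18–30 nt, matching the gel size selection
used for small-RNA libraries.

## Mapping and counting

Reads are aligned by substitution-only matching with at most one mismatch
(no indels), on both strands; coordinates are 0-based half-open on the
forward strand. The matcher is deliberately simple — a stand-in for a
short-read aligner restricted to the guarantee actually used downstream
(≤ 1 substitution) — and is verified in the test suite against a
brute-force sliding-window scan.

Mature miRNA counting matches the full insert against each mature
sequence of the same length within one substitution. A read within the
budget of several mature sequences increments *each* of them by default
(`multi = "all"`); `multi = "best"` restricts to minimum-mismatch hits.
Multi-assignment is the permissive reading of database matching; the
choice is exposed because the two conventions disagree precisely for
families of near-identical mature sequences.

## Differential expression

Counts are normalised to reads per million clean reads (RPM). Fold change
is the ratio of treated to control RPM; a pseudo-expression of 0.01 RPM
replaces zeros *in the ratio only* (stored RPM values keep their zeros).
0.01 RPM keeps extreme but finite fold changes representable — a miRNA
observed at ~14 RPM in one condition and 0 in the other yields a log2
fold change near −10.4, the magnitude range seen in real induction data —
while never dominating a non-zero measurement at realistic depths.

Significance uses the exact two-library count test: with `x` tags out of
`N1` and `y` out of `N2`,

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

the posterior predictive of a Poisson rate under a flat prior. The
two-sided p-value is `min(1, 2*min(lower, upper))` where `lower` sums
`p(k|x)` for `k ≤ y` and `upper` for `k ≥ y`.

Numerical notes:

* Terms are evaluated in log-gamma space and combined with log-sum-exp.
* The upper tail is computed as the complement of the finite lower sum
  only when that complement is accurate (lower sum < 0.5). When the upper
  tail is small, it is summed directly in log space: the complement of a
  number near 1 cannot resolve tails below ~1e-16, and the test suite
  holds the implementation to 1e-10 *relative* agreement with an
  independent term-recurrence oracle.
* The p-value is floored at the smallest positive double, so it is always
  in (0, 1].
* The statistic depends on the library sizes only through `N2/N1`.
* The doubled-minimum-tail construction is **not** symmetric under
  swapping `(x, N1)` with `(y, N2)`: both tails include the observed
  point, so the doubling is anchored to the conditioning side. (Small
  counterexample: `x=0, y=2, N1=N2` gives 1/2 one way and 1/4 the other.)
  The package always conditions on the control library.

Multiple testing uses Benjamini–Hochberg (the field default; the method
is configurable), applied within each replicate comparison.

Selected DEMs must satisfy all of: |log2 fold change| > 1 with the *same
sign* in both replicate comparisons; raw count > 10 (strict, raw scale) in
at least one of the four samples; raw p < 0.01 in at least one comparison.
The count and p thresholds are read as raw-scale and raw-p because the
printed per-replicate p-values in the packaged table are raw; both are
configurable via `selection_criteria()`. miRNAs passing the magnitude
threshold with opposite signs are excluded and recorded in the
`sign_conflicts` attribute rather than treated as errors.

### Clustering

The selected set is clustered on its miRNA × replicate log2 fold-change
matrix with agglomerative hierarchical clustering, Euclidean distance,
cut at k = 2. The linkage is **Ward** (`ward.D2`): on the packaged 33-row
table, complete and average linkage both split off the extreme induced
miRNAs and misassign three weakly induced ones, whereas Ward's
variance-minimising criterion reproduces exactly the induced/repressed
partition that the two published expression clusters describe. Only the
k = 2 partition is contractual; leaf order is reported for heatmaps but
not guaranteed.

## TSS assignment and promoter windows

Each miRNA's transcription start site is assigned with a three-step
priority: a curated TSS when available; else, for intragenic miRNAs, the
transcription initiation site of the host-gene transcript; else the
genomic position of the precursor's first nucleotide (on the minus strand,
the highest coordinate). Curated tables are accepted as 1-based with a
declared flag; everything internal is 0-based half-open.

The putative promoter is 10 kb upstream to 1 kb downstream of the TSS in
transcription orientation: `[pos−U, pos+D)` on the plus strand and
`[pos−D+1, pos+U+1)` on the minus strand, clipped to the chromosome. A
window clipped to zero length is an error. Peak–promoter intersection uses
an any-overlap (≥ 1 bp) rule — the most permissive reading of "binding
sites around the TSS" — with a configurable minimum overlap. Distances are
signed from the TSS to the peak *midpoint* (peaks arrive as summit-less
BED intervals), negative meaning upstream. Peaks duplicated across study
tags are kept with their tags, since per-study provenance is part of the
display; a deduplicated view can be had by dropping the tag column before
intersection.

## Target integration and enrichment

Per miRNA, the integrated target set is (predictions A ∩ predictions B) ∪
validated interactions, with per-gene provenance. The intersection
reduces prediction false positives; validated interactions are kept
unconditionally.

Enrichment is the hypergeometric upper tail `P(X ≥ k)` with BH adjustment
across categories *per query set* (not globally across miRNAs), at
adjusted p < 0.05. This deliberately replaces web-service scores (e.g.
EASE-modified Fisher) with the exact tail: it is reproducible offline and
testable against the closed form (`N=20, K=5, n=5, k=5` gives
`1/C(20,5) = 1/15504`). The default universe is the genes appearing in the
annotation sets intersected with the target-table gene space, since no
background is otherwise declared; callers can pass their own.

## Network and feed-forward loops

The regulatory network has typed nodes (TF, miRNA, gene) and typed edges:
`tf_mirna` only for selected miRNAs with at least one promoter binding
site (signed by expression direction), `mirna_gene` from integrated
targets, `tf_gene` from an explicit TF direct-target gene list, and
undirected `ppi` context edges restricted to genes already in the network.
The TF direct-target list is an explicit input because it makes the loop
definition operational; pathway-membership shortcuts would tie the result
to a particular pathway database version.

A feed-forward loop is a triple (TF, miRNA, gene) with all three
regulatory edges present; PPI edges never participate, and gene = TF
self-loops are excluded. Enumeration is exact, deterministic (sorted
output) and verified against a cubic brute force. Exports are SIF (plus
node/edge attribute tables) and GraphML; both round-trip through the
package's importers.

## The synthetic-data generator

The generator emulates, with recorded truth: a toy genome with placed
precursors and embedded ~22-nt matures; four libraries (two conditions ×
two replicates) of 50-nt tags whose miRNA abundances follow a shared
log-normal base profile (`sdlog = 1`, the right-skew typical of small-RNA
libraries) with planted per-miRNA fold changes; mutually exclusive
per-read contamination classes injected in the cleaning cascade's order,
so report fractions estimate the planted rates directly; promoter peaks
planted inside the windows of chosen miRNAs (decoys outside all windows);
target tables with a controlled Jaccard overlap between the two
prediction sources; annotation sets with planted over-represented
categories; and a G(n, p) PPI graph.

Design points worth spelling out:

* **Compositional closure.** Library-size normalisation measures
  *relative* abundance, so raising some miRNAs must depress the measured
  share of the rest. The default planted profile keeps this distortion
  small in two ways that mirror real data: 30% of clean reads are
  non-miRNA background species, and induced miRNAs start from a low
  baseline (`induced_baseline = 0.15` × the log-normal draw) — strongly
  induced miRNAs in DNA-damage programs are near-silent before treatment.
  The residual shift is well below the 1-unit selection margin for
  planted effects of |log2fc| ≥ 2.
* **Default planted truth** (`default_planted_truth()`): 33 DE miRNAs of
  40 (12 induced at +2..+4, 21 repressed at −2..−6), 18 bound (5 induced,
  13 repressed), 7 with two peaks from different pseudo-studies;
  contamination ~2% low-quality (matching the ~98% retention typical of
  these libraries) plus small rates for the other classes.
* **Unambiguous peak recovery.** The pipeline's toy genome places
  precursors with a 30-kb minimum gap — larger than the promoter span —
  so promoter windows never overlap and a planted peak identifies exactly
  one miRNA, for any seed. Planted peaks are additionally sampled from
  the positions that avoid every other window, and decoys from positions
  avoiding all windows.
* **Sequencing depth** is a free parameter (the study design does not fix
  one). Unit tests run at 1,500–50,000 reads per library; the deep
  recovery test runs at 100,000, where planted direction is recovered
  with zero sign errors and the planted bound-miRNA and loop counts are
  recovered exactly.
* Reads carry Phred+33 qualities (clean ~Q30–40, planted low-quality
  ~Q5–18). The generator does **not** emulate platform error profiles,
  ligation bias, hairpin folding, or ChIP-seq read-level signal (peaks
  are generated directly). Passing tests therefore demonstrate the
  *pipeline logic* — filters, statistics, interval arithmetic, set
  algebra, enumeration — not robustness to instrument artefacts.

Every generator is bit-reproducible given its seed; the pipeline derives
stage seeds from one master seed and writes an MD5 manifest, and two runs
with the same configuration are byte-identical.

## Degenerate inputs and tie-breaks

* Empty read sets: length/nucleotide summaries error (fractions would be
  undefined); an unmapped read is reported, not an error.
* A single selected miRNA: clustering degenerates to one cluster with a
  warning.
* No binding sites: the summary reports zero counts and NA fractions.
* A miRNA absent from a target table: empty set with a warning, not an
  error; an empty query or universe in enrichment is an error.
* Cluster labels: cluster 1 is the cluster with the higher mean fold
  change, making the induced/repressed labelling deterministic.

## Known limitations

* The count test treats the two replicate comparisons independently; no
  replicate-aware dispersion model is fitted. This is faithful to the
  pairwise-library design but less powerful than negative-binomial
  models when more replicates exist.
* The ≤ 1-mismatch matcher ignores indels and does not scale to real
  genomes; it exists to make the pipeline self-contained and exactly
  testable.
* Hypergeometric enrichment on flat annotation sets ignores ontology
  structure and annotation propagation.
* Real supplementary binding-site tables (per-study peak coordinates)
  are not packaged; the promoter-summary checks run on planted synthetic
  structure instead.
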
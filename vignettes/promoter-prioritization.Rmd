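---
title: "Methods: rank-aggregation screening for constitutive promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-aggregation screening for constitutive promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promrank)
library(dplyr)
```

## The problem

Heterologous expression in filamentous fungi needs promoters that drive
high transcription regardless of culture condition. Single-condition
expression data are a poor guide: a gene that tops the list in one medium
may be strongly condition-responsive. promrank implements the screening
strategy of ranking genes *within* each of many transcriptome datasets and
prioritizing by the *median* of those ranks, so that a gene must be highly
expressed in at least half of all datasets to reach the head of the list.
Candidates must additionally offer enough upstream intergenic space to cut
a usable promoter fragment.

## The procedure

For a collection of $N$ datasets over a universe of $G$ genes:

1. **Within-dataset ranking.** In each dataset, genes are sorted by
   intensity, rank 1 being the highest. Ties are broken by gene identifier
   (lexicographic ascending). This keeps every dataset's ranks an exact
   permutation of $1..G$, which matters for the next step: the median is
   then a true order statistic of integers, not of averaged tie-ranks.
   Because ranking only uses within-dataset order, no cross-dataset
   normalisation is needed — any strictly increasing per-dataset transform
   (log, scaling, quantile mapping) leaves every result unchanged, and the
   package applies none.
2. **Rank aggregation.** Each gene's $N$ ranks are summarised by their
   minimum, maximum and median, where the median of an odd $N$ is the
   $\frac{N+1}{2}$-th smallest value (for $N = 83$, the 42nd of the sorted
   ranks) and for even $N$ the mean of the two middle values. Genes are
   ordered by ascending median rank; ties are resolved by smaller maximum
   rank, then smaller minimum rank, then gene id. The max-then-min order
   prefers, among equally central genes, the one whose *worst* behaviour
   is better — the right instinct for a constitutive-expression screen —
   and makes the output deterministic.
3. **Filters.** Two exclusion rules, both boundary-inclusive:
   `max_rank <= 1000` (a gene that ever drops below rank 1000 is unlikely
   to behave constitutively) and `utr_length >= 950` bp (shorter upstream
   intergenic regions risk clipping the regulatory elements a promoter
   fragment needs). Both thresholds are plain parameters with these
   defaults.
4. **Selection.** The first `n = 6` genes (in list order) passing both
   filters are selected; their promoter windows of
   `min(target_length, utr_length)` bp (default target 1024) are extracted
   upstream of the 5′ anchor.

## Upstream distance and coordinate conventions

The "5′-UTR size to the next gene" is the intergenic distance from a
gene's 5′ end to the nearest gene body upstream of it, on either strand:
for a `+` gene, the feature with the greatest end before its start
(`utr = start − neighbor_end − 1`); for a `−` gene, the feature with the
least start past its end (`utr = neighbor_start − end − 1`). Neighbor
strand is deliberately ignored — any gene body terminates the usable
promoter space. An overlapping neighbor yields distance 0 (never a
negative value); a gene with no upstream neighbor gets the distance to the
contig edge and an `at_contig_edge` flag, since that distance is a lower
bound of a different kind.

GFF3 coordinates are 1-based inclusive; promoter windows and BED output
are 0-based half-open. The window for a `+` gene at `start` is
`[start − 1 − L, start − 1)`; for a `−` gene at `end` it is
`[end, end + L)` and the extracted sequence is reverse-complemented, so
returned sequences always read 5′→3′ toward the start codon.

The 5′ anchor defaults to the `gene` feature start. Annotations with
curated per-gene CDS features can anchor at the start codon instead
(`feature_type = "CDS"`); many GFF3 files lack reliable CDS records, hence
the default. A per-gene `target_overrides` table supports cutting a
slightly longer fragment for individual promoters (historically tested
fragments are not always exactly the default length).

## Input policies

* **Gene universe** — default `require-identical`: datasets from one
  platform should cover identical gene sets, and silent divergence is more
  often a data error than a design choice. `intersect` and
  `union-worst-rank` (a gene absent from a dataset gets rank $G$ there)
  make the tool usable on mixed collections; under `union-worst-rank` a
  dataset's ranks are no longer a full permutation, which is the honest
  representation of "we never observed this gene here".
* **Replicates** — multiple sample columns mapped to one dataset are
  mean-averaged on the stored scale before ranking (`average`), the least
  surprising reduction; `each-sample` treats every array as its own
  dataset.
* **Missing values** — `strict` errors by default; `drop-gene` removes
  the gene everywhere, so the universe stays identical across datasets.

## The synthetic-data generator

Every stage is testable without downloads because the generator produces
the full input set — intensity matrix, manifest, genome FASTA, GFF3 — with
known ground truth. The expression model is

$$x(g,d) = \mu_g + \beta_{g,c(d)} + \varepsilon_{g,d}$$

on a log2-like intensity scale: planted constitutive genes have
$\mu_g = \mu_\text{high}$ (default 12) and $\beta \equiv 0$; other genes
draw $\mu_g \sim N(7, 2)$ truncated strictly below $\mu_\text{high}$, and
per-condition effects $\beta_{g,c} \sim N(0, \tau)$ ($\tau = 2$ by
default) shared by all datasets of one condition — datasets are assigned
to conditions round-robin, reproducing the correlation structure of
replicate datasets per condition. Per-sample noise has s.d. 0.5. The
truncation is what makes the zero-noise limit exact: with
$\sigma = \tau = 0$ the planted genes occupy the top ranks of every
dataset by construction.

Genome geometry places genes sequentially per contig with intergenic gaps
from a half/half mixture of short (50–949 bp) and long (950–6500 bp)
uniform components — bracketing the UTR filter threshold so both filter
outcomes occur — and a 500 bp tail after the last gene. Recorded true
upstream distances use the same strand-aware convention as the analysis
code and are verified by re-parsing the emitted files. Sequence content is
uniform random A/C/G/T: no promoter motif realism is attempted, because
only lengths and coordinates matter to anything downstream. One master
seed drives separate deterministic sub-streams for expression, geometry
and sequence, so equal configurations reproduce every artifact
byte-for-byte.

What the generator does *not* emulate: microarray probe effects,
background correction, vendor normalisation, heavy-tailed or
intensity-dependent noise, and any relationship between expression and
genomic position. Passing tests on synthetic data therefore demonstrate
the correctness and stability of the *procedure*, not platform-specific
robustness on real arrays.

The package's benchmark configuration uses 3000 genes, 20 datasets over
10 conditions and 25 planted genes — large enough for stable rank
statistics, small enough that the whole benchmark (20 seeds) runs in
under a minute. A point worth stating plainly: with baseline means
truncated just below $\mu_\text{high}$ and condition effects of the same
magnitude as the planted margin ($\tau = 2$ against a 5-unit mean gap but
a continuum of baselines reaching to within fractions of a unit), the
planted genes are *not* fully separable at the median — near-high
baseline genes with favourable condition effects legitimately outrank
them. The acceptance script reports the measured recovery; the
stability analysis, which does not depend on separability, shows the
intended monotone improvement of list reproducibility with dataset count.

## Stability analysis

`stability_curve()` draws random subsets of datasets (without replacement
within a subset; optionally stratified across condition labels so small
subsets do not drop whole conditions), recomputes the aggregation on each
subset with semantics identical to the full pipeline — the median order
statistic is recomputed for the subset's own $N$ — and compares each
subset's top-$k$ with the full-collection top-$k$ by overlap count and
Jaccard index. The baseline is the full-collection list rather than
pairwise subset comparisons, matching the practical question "would fewer
datasets have given me the same candidates?". At the full subset size the
overlap equals $k$ exactly, a built-in self-check.

## Numerical and degenerate-input choices

* Ranks, coordinates and distances are integers throughout; the only
  non-integer quantity is an even-$N$ median (half-integers).
* A gene with `utr_length` 0 gets an empty, flagged promoter window — not
  an error — so reports stay complete.
* Genes lacking an upstream-distance record remain in the candidate table
  flagged `annotated = FALSE` and failing the UTR filter; dropping them
  silently would misrepresent the funnel.
* If fewer than `n` candidates pass both filters, all passing candidates
  are selected and a warning is raised.
* `topk_overlap()` with `k` beyond a list's length warns and uses the
  full list.
* Report writing happens after all stages succeed, so a failed run leaves
  no partial report; every stage error is labelled with its stage name.

## Limitations

* The screen finds genes with available upstream *space*, not verified
  promoter *activity*; wet-lab validation of selected fragments remains
  essential, and historically some highly ranked candidates have failed
  in practice.
* The intergenic distance is a proxy for the 5′-UTR; without
  transcript-level evidence the true transcription start is unknown.
* The maximum-rank threshold is a blunt instrument against
  condition-responsive genes; genes responsive in conditions absent from
  the collection will not be caught.
* Aggregation statistics beyond min/max/median (rank products, geometric
  means) are out of scope.
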
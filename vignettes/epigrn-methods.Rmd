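---
title: "Methods: tree-ensemble network inference with epigenetic regulators"
author: "epigrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-ensemble network inference with epigenetic regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigrn)
```

## The model

`epigrn` infers a directed, weighted gene regulatory network (GRN) from a
gene × sample expression matrix. The predictor set is deliberately wider than
the usual transcription-factor catalogue: it combines TFs with *epigenetic
regulators* — writers, erasers and remodelers of chromatin state, grouped into
histone modification, DNA methylation, chromatin remodeling and siRNA
biogenesis — so that chromatin-level control can surface in the inferred
network rather than being folded invisibly into TF effects.

For every non-constant gene $g$, an ensemble of regression trees predicts
$g$'s unit-variance expression from the expression of all candidate
regulators except $g$ itself. The weight of the edge $r \to g$ is the
importance of $r$ in that ensemble:

$$ w_{r \to g} \;=\; \frac{1}{T}\sum_{t=1}^{T}\ \sum_{\text{splits on } r}
   \frac{ \mathrm{SS}(\text{node}) - \mathrm{SS}(\text{left}) -
          \mathrm{SS}(\text{right}) }{ n }, $$

the total sum-of-squares reduction attributable to $r$, per tree, scaled by
the sample count $n$. On a unit-variance target the incoming weights of a
tree grown to purity sum to the target's (population) variance, so weights
are comparable across targets — the property that makes "sum of edge weights"
a meaningful influence statistic later. Because regulators are themselves
predicted as targets, the network contains regulator→regulator edges
(regulatory cascades); self-edges are excluded by construction.

The full weight matrix is noisy, so the pipeline retains only the top
fraction of edges by weight (default 10%) as the high-confidence network.
Ties at the cutoff are broken by (weight desc, regulator id asc, target id
asc), and the retained count is `ceiling(fraction × E)` so a positive
fraction never yields an empty network.

## Downstream operations

*Subnetworks.* A differential-expression study contributes a DEG list; the
subnetwork for a biological process is simply every retained edge whose
**target** is in that list. Regulators are deliberately not required to be
differentially expressed — a constitutively expressed chromatin remodeler can
still dominate a process through its targets.

*Ranking.* Within a subnetwork each regulator's influence is the sum of its
edge weights. Ties are broken by gene id so ranks are a permutation of
1..k, which keeps the rank-sum aggregation below well defined. Rankings can
be filtered by regulator class (e.g. top 10 epigenetic regulators) while
retaining the pre-filter global rank.

*Rank-sum aggregation.* Two studies of the same process yield two rankings;
they are combined by summing each regulator's rank across the truncated
top-$n$ lists. A regulator absent from one list's top $n$ contributes rank
$n + 1$ — the smallest penalty that keeps sums comparable; this choice is a
package convention (the aggregation method itself does not prescribe one) and
is surfaced prominently in the documentation. An alternative that uses ranks
within the *full* rankings is available via `fullRanks = TRUE`; the candidate
set is the union of top-$n$ members either way.

*Validation.* A regulator's in silico targets (all targets of its retained
edges) are compared with an experimentally determined gene list by the upper
tail of the hypergeometric distribution, $P(X \ge k)$, computed as the
survival function at $k - 1$ (the overrepresentation direction; the
off-by-one at $k$ is the classic footgun). With a microarray-derived
experimental list, both sets are first intersected with the probed genes and
the probe count is the background; otherwise a genome-wide background is
used. Its default size (27416, an Arabidopsis protein-coding gene count) is a
configurable constant and every report records the background actually used.
Raw p-values are reported; Benjamini–Hochberg across a report's rows is
optional.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nTrees` | 1000 | trees per target; 500 is used in the package benchmark |
| `kMode` | `ALL` | candidate predictors per split (`ALL` or `SQRT`) |
| `minLeaf` | 5 | minimum samples per leaf (regression random-forest convention); 1 grows to purity |
| `maxDepth` | 0 | 0 = no depth limit; 1 gives stumps (used by the oracle tests) |
| `bootstrap` | TRUE | per-tree resampling of samples with replacement |
| `minVariance` | 1e-12 | at/below this sample variance a gene is constant: not a target, not a predictor |
| trim `fraction` | 0.1 | retained top-weight fraction |
| `topN` | 25 | truncation depth for rankings and rank-sum |

## Determinism

All randomness flows from one integer seed. Each target gene draws its
bootstrap and feature-sampling stream from a hash of its gene id mixed with
the seed, and samples and candidate predictors are canonicalised (sorted by
id) before tree building. Consequently results are bit-identical under
permutation of gene rows or sample columns, under any target processing
order, and under any worker count — reproducibility does not depend on
scheduling. Split ties are resolved toward the first candidate regulator (in
sorted id order) and the smallest threshold.

## The synthetic benchmark

The generator emulates the statistical situation the pipeline assumes, not
any particular organism: a sparse regulator→target DAG in which regulators
may regulate later regulators (so "regulator as target" is exercised), with
planted hub "process regulators" whose targets concentrate in a process
module — the ground-truth DEG list. Expression follows a linear-Gaussian
structural model evaluated in topological order: parentless genes are
standard normal, every other gene is the effect-weighted sum of its parents
plus Gaussian noise. This is the simplest generative process under which
variance-importance inference provably concentrates weight on true parents;
it is a benchmark assumption, not a biological claim.

Both degree distributions are heavy-tailed, as in real regulatory networks:
background out-degrees are lognormal around `outDegreeMean` (sdlog 1.2), and
background targets are drawn proportionally to a bimodal lognormal gene
"popularity" — only about a quarter of genes are responsive to the predictor
set at all, and among those in-edges concentrate on regulatory hotspots.
Degree-homogeneous networks (e.g. constant-mean Poisson out-degrees with
uniform target choice) would give every regulator the same expected
influence, and regulator rankings over such a network have no stable signal
to recover; the heavy-tailed structure is what makes influence ranking a
meaningful exercise.

The reference benchmark (the `syntheticGRNSpec()` defaults) uses 30 TFs and
10 epigenetic regulators over 200 targets, mean background out-degree 8,
three planted hubs (at least one epigenetic) driving a 30-gene module at hub
concentration 0.8, effect magnitudes uniform in [0.5, 1.5], noise sd 0.5 and
300 samples — a regime where signal is clear but far from trivial
(per-module-gene signal-to-noise is modest at the low end of the effect
range). The hub share of module driver edges is exact
(`round(concentration × moduleSize)` edges are assigned to hubs round-robin)
rather than drawn, so the generator's advertised structure holds
deterministically. Synthetic DEG lists replace the *tail* of the sorted
module with random non-module decoys, so two lists drawn with different
seeds share an identical true core; an `exclude` argument makes decoy sets
disjoint when two independent "studies" are simulated.

What passing the benchmark does **not** show: real transcriptomes have
count noise (negative binomial, library-size effects), hidden confounders,
feedback loops (no DAG), and correlated regulators; recovery there will be
worse than on this benchmark, which is why the pipeline trims aggressively
and treats weights as confidence scores rather than effect estimates.

## Numerical choices

- Constant genes are flagged at sample variance ≤ `minVariance` and set to
  zero rather than dropped, so matrix dimensions are stable.
- `trimTopFraction` computes `ceiling(f·E)` with a 1e-9 guard against
  floating-point excess in `f·E` (e.g. `0.1 × 30` evaluating just above 3).
- The precision–recall area ranks *all* candidate regulator→target pairs
  (absent pairs at weight 0) and integrates tied blocks with the continuous
  interpolation between operating points, so an all-tied ranking integrates
  exactly to the edge prevalence and the metric is invariant to monotone
  weight transformations.
- Ranking comparisons report r² together with the signed correlation,
  because r² alone cannot distinguish a reversed ranking from an identical
  one. Regulators absent from one ranking are excluded from the correlation
  rather than imputed.
- Edge weights are written with 10 significant digits; files round-trip to
  that precision.

## Problem sizes used by the test suite

The package's own checks run the full benchmark (240 genes × 300 samples,
500 trees per target) across five seeds for recovery and robustness, and
twice more for byte-identity of the full pipeline; unit tests use matrices
of up to a few hundred cells where exhaustive oracles (split enumeration,
urn enumeration at N ≤ 12, numeric PR integration) are feasible. These sizes
were chosen so every claim is backed by an independent computation.

## Ranking robustness and scale

A deliberate design point: ranking robustness to DEG-list perturbation is a
*large-list* property. When two DEG lists of thousands of genes overlap only
partially, each private gene carries well under 0.1% of a subnetwork's
weight and regulator rankings barely move. At the benchmark's deliberately
small scale (30-gene lists sharing 15 genes), a single private gene carries
several percent of the subnetwork weight, and the fixed top-10% trim retains
more edges than the ground truth contains, so the tail of every ranking is
populated by noise edges whose order is exchangeable between lists. The test
suite measures this honestly: planted hubs' weight sums agree to about 1%
across half-overlapping lists, and weight-sum correlations are high, while
rank correlations over *all* common regulators stay moderate. Users
comparing rankings on real data should therefore compare weight sums, or
ranks within the top lists, rather than full-depth rank vectors, unless
their DEG lists are large.

## Known limitations

- The packaged regulator lists are synthetic stand-ins that preserve the
  curated resource's class/category structure and counts (see the extdata
  README); analyses of real Arabidopsis data should substitute the genuine
  curated tables in the same TSV format.
- Inference cost grows as targets × trees × samples·log(samples); the
  corpus-scale networks this pipeline is modelled on (thousands of
  transcriptomes, tens of thousands of genes) are multi-day computations and
  out of scope here.
- The hypergeometric test treats gene sets as exchangeable draws; gene-length
  or expression-level ascertainment biases are not modelled.
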
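# epigrn

Gene regulatory network (GRN) inference from expression matrices with
**epigenetic regulators as first-class predictors**, and the downstream
toolkit to turn the inferred network into ranked regulator candidates for a
biological process.

Classical GRN inference uses transcription factors as the only predictors.
`epigrn` widens the predictor set to include curated epigenetic regulators —
writers, erasers and remodelers of chromatin state (histone modification, DNA
methylation, chromatin remodeling, siRNA biogenesis) — so chromatin-level
control can be detected and ranked alongside TF control. It is aimed at
systems biologists who have (i) a large expression compendium, (ii) DEG lists
from studies of a process (e.g. shoot or root apical meristem development),
and (iii) optionally, experimental target lists to validate predictions
against.

## The method in brief

For each non-constant gene $g$, an ensemble of $T$ regression trees predicts
$g$'s unit-variance expression from all candidate regulators $r \ne g$. The
edge weight is the tree-ensemble variance importance

$$ w_{r \to g} = \frac{1}{T}\sum_{t}\sum_{\text{splits on } r}
   \frac{\Delta\mathrm{SS}}{n}, $$

i.e. the per-tree total variance reduction attributable to $r$. The weighted
network is trimmed to its top 10% of edges (the high-confidence network);
a process subnetwork is the set of retained edges whose **target** is in a
DEG list; regulators are ranked by their summed edge weight within the
subnetwork; rankings from independent studies are merged by rank sum; and a
regulator's predicted ("in silico") targets are validated against
experimental gene lists with an upper-tail hypergeometric test (genome or
microarray-probe background). A synthetic benchmark module generates
ground-truth networks with planted hub regulators so the entire pipeline is
testable by recovery. See `vignettes/epigrn-methods.Rmd` for the full
methods account.

## Worked example

```r
library(epigrn)

spec <- syntheticGRNSpec(nTF = 8, nEpi = 3, nTargets = 40, nSamples = 80,
                         outDegreeMean = 4, nProcessRegulators = 2,
                         processModuleSize = 12, seed = 7)
net  <- generateTrueNetwork(spec)          # ground truth with 2 planted hubs
expr <- simulateExpression(net, spec)      # 51 genes x 80 samples
rs   <- regulatorSetFromTruth(net)

grn    <- inferNetwork(expr, rs, inferenceConfig(nTrees = 200, seed = 7))
topnet <- trimTopFraction(grn, 0.1)        # high-confidence network
topnet
#> GRNetwork: 55 edge(s), 11 regulator(s) in universe, 41 distinct target(s)

degs <- makeDegList(net, contamination = 0.25, seed = 7)   # a noisy "study"
rk   <- rankRegulators(extractSubnetwork(topnet, degs, "toy-study"),
                       regulators = rs)
head(rankingTable(rk), 5)
#>   regulator symbol   regClass weightSum rank globalRank
#> 1   G000003                TF 3.4231939    1          1
#> 2   G000010        EPIGENETIC 2.4613182    2          2
#> 3   G000008                TF 0.9165997    3          3
#> 4   G000002                TF 0.7306572    4          4
#> 5   G000011        EPIGENETIC 0.1426688    5          5
```

The two planted process regulators (`G000003`, `G000010` — one TF, one
epigenetic) rank first and second: `recoveryAtK(rk, processRegulators(net),
k = 3)` is `1`. Validating the top regulator's predicted targets against the
planted module:

```r
ts <- getTargets(topnet, rankingTable(rk)$regulator[1])
hypergeomOverlap(ts, processModule(net),
                 genomeBackground(length(net@genes)))
#>   n_insilico n_experimental n_overlap   p_value
#>           10             12         5 0.0422308
```

5 of the 10 predicted targets fall in the 12-gene planted module
(p ≈ 0.042 against a 51-gene background) — the overlap statistic reported,
one row per comparison, by `validateAgainstExperiments()`.

Real data enter through the same interfaces: `readExpressionMatrix()`,
`loadRegulators()` (+ the packaged predictor lists via
`packagedRegulatorFile()`), `readGeneList()` for DEG lists, and
`runPipeline()` / `inst/scripts/epigrn` to drive the whole chain from a
config file or the shell.

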
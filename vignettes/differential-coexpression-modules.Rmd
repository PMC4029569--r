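---
title: "Differential co-expression modules: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression modules: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmsnet)
```

## The model

`edmsnet` treats a disease that progresses through $K$ ordered stages as a
sequence of co-expression states of a fixed protein interaction network.
For an edge $(i, j)$ and stage $k$, the Pearson correlation $r_k$ of the
two genes over that stage's samples is Fisher transformed,
$R_k = \tfrac12 \log\frac{1 + r_k}{1 - r_k}$, and the differential
correlation of transition $k$ is $dC(k) = R_{k+1} - R_k$. The transform is
monotone, odd and expanding ($|R| \ge |r|$), so it acts as a soft
threshold: a change from 0.8 to 0.95 counts for much more than a change
from 0.0 to 0.15. Each edge thus carries a $(K-1)$-vector of $dC$ values;
everything downstream — seeding, module search, clustering — operates on
these vectors.

Assumptions worth stating explicitly:

* expression is on a log scale, so differences of stage means are log fold
  changes, and Pearson correlation is an adequate co-expression measure
  (no rank-based variant is offered);
* stages are an ordered partition of samples with at least 3 (practically
  ≥ 10) samples each — $r$ from fewer samples is too noisy to difference;
* the interactome is an undirected simple graph in the same gene namespace
  as the expression matrix; identifier mapping happens upstream.

## The search (eDMS)

Edges ranked by $|dC(k)|$ give, at a configurable top fraction, the
differentially co-expressed pairs (DCPs) that seed the search. Connected
components of the seed edges are the initial modules. Each module grows
greedily: among all network edges with at least one endpoint in the module
("directly connecting"), the one with maximal $|dC|$ is absorbed iff the
relative decrease of the module score $S$ (mean $|dC|$ of member edges)
satisfies $(S - S')/S \le \delta$; increases are always accepted. The loop
stops at the first rejection or after `max_iterations` accepted steps.
Expanded modules are combined by edge union, components with fewer than
`min_component_genes` genes are dropped, and the surviving subnetwork is
scored by the unweighted mean of its components' module scores. $\delta$
is selected by running the whole search across `delta_grid` and keeping
the grid value with the best overall score.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `seed_fraction` | 0.001 | proportion of ranked edges | keeps subnetworks from outgrowing interpretability; counts are rounded half-up, so 64,865 edges give 65 seeds |
| `delta_grid` | 0, 0.01, …, 0.10 | relative score decrease | a tolerance above ~10% lets low-signal edges flood the module; 0 forbids any decrease |
| `max_iterations` | 100 | accepted absorptions per initial module | size control; with ~1 edge per node in outputs this caps modules at ~100 edges |
| `min_component_genes` | 5 | genes | fragments below 5 genes are unreadable as "modules" and inflate the overall score |
| `k_clusters` | 6 | clusters | the trajectory dendrogram has no canonical cut; 6 matches the granularity at which early/late, up/down patterns stay distinguishable |
| `pattern_fdr` | 0.25 | FDR | the level at which per-stage correlation significance (HP/HN/NS labels) is called within the edge family under scrutiny |
| `alpha` (enrichment) | 0.001 | adjusted p | strict because interactome-wide GO-style annotations yield thousands of tests |
| `clamp_eps` | 1e-7 | correlation | $R$ diverges at $|r| = 1$; perfect correlations (duplicated values) are clamped to $\pm(1-\varepsilon)$ |

### Interpretation conventions

* **Decreasing rate** is the *relative* decrease $(S - S')/S$ — a
  dimensionless rate is the only reading under which a tolerance of
  0.00–0.10 is meaningful.
* The loop guard is *stop at first rejection*, not skip-and-try-next: the
  best candidate failing the guard means any further candidate would fail
  it harder at the current score.
* The iteration cap applies per initial module, and component filtering
  happens after the union, before the overall score that drives the
  $\delta$ scan.
* Ties everywhere (rankings, candidate selection, cluster labels) break on
  the canonical lexicographic edge key `"a|b"` with `a < b`, which makes
  every output a pure function of the inputs. Re-running a pipeline with
  identical inputs is hash-identical; this is asserted in the tests.
* Zero-variance gene/stage combinations set $r = 0$ with a `zero_var`
  flag instead of propagating `NaN`, so every edge keeps a complete
  $dC$ vector.

## Process-wise clustering

The union of the transition subnetworks is clustered on the edges' full
$dC$ vectors with Euclidean distance and complete linkage
(`stats::hclust`), cut at `k_clusters`. Rows are sorted by canonical edge
key before clustering; since `hclust` is deterministic given its input
order, this makes the partition invariant to the order in which edges
arrive — a bespoke tie-broken linkage implementation was considered and
rejected because, on real-valued $dC$ vectors, exact distance ties occur
with probability zero and the pre-sort already guarantees reproducibility.
Cluster trajectories are reported as mean raw $r$ per stage (not mean
transformed $R$): raw correlations are bounded and directly readable as
co-expression strength in plots.

The one-sided two-sample Kolmogorov–Smirnov comparison of edge versus
background $|r|$ uses a seeded random sample of non-interacting pairs
(default up to $10^6$) rather than all pairs, which are quadratic in gene
count; the direction tested is "interacting pairs correlate more
strongly".

## Enrichment

Term enrichment is an upper-tail hypergeometric draw against the network's
gene set as universe. Reporting follows a three-step rule: terms with
fewer than `min_foreground` (default 5) annotated foreground genes are
dropped *before* adjustment (changing the BH family size $m$), survivors
are BH-adjusted and cut at `alpha`, and when a parent→child term hierarchy
is supplied only the most specific retained terms are kept. A full
ontology parser is deliberately out of scope; the hierarchy input is a
plain two-column table.

## What the simulator emulates — and what it does not

`simulate_dataset` mirrors the structure of a five-stage progression
series: default stage sizes 10, 10, 17, 18, 17 (a realistic small
microarray cohort), a scale-free background interactome (preferential
attachment, so hubs exist), and planted edge groups wired as random
spanning trees whose per-stage population correlation follows a prescribed
trajectory via a shared latent factor
$x = s\sqrt{|r|}\, z + \sqrt{1-|r|}\, e$. For negative targets the signs
$s$ alternate along a 2-colouring of the tree, making every planted
*edge's* correlation exactly $-|r|$; the sign pattern is applied only in
negative-target stages, since a common-sign loading is what produces
positive correlation. Marker gene sets overrepresent planted genes by a
configurable factor (default 5×) for direction tests of seed-quality
diagnostics.

Not emulated: probe-level and batch effects, heavy-tailed intensity
noise, correlated background structure (background genes are independent),
missing values, and overlapping planted groups. A green recovery test
therefore establishes that the algorithms behave as specified under
controlled rewiring — not that any particular biological dataset will
yield stable modules; with 10-sample stages the sampling noise of $r$
(s.d. ≈ 0.35 under the null) makes top-ranked $dC$ lists genuinely
unstable, which is a property of the statistic, not a bug.

## Numerical choices and degenerate inputs

* $|r|$ within `1e-7` of 1 is clamped before the Fisher transform.
* Correlation p-values use the exact $t$ null with $n - 2$ degrees of
  freedom; $|r| = 1$ maps to $p = 0$.
* `top_fraction` rounds half up (`floor(x + 0.5)`), the convention that
  reproduces a 65-edge 0.1% seed set from 64,865 edges.
* Welch's unequal-variance $t$-test is used for differential expression
  calls; two constant equal groups give $p = 1$, constant unequal groups
  the degenerate $p = 0$.
* The standard deviation of a single retained shortest-path length is
  reported as 0, with the number of excluded (disconnected) pairs exposed.
* An eDMS run in which every component falls below the gene threshold is
  an error, not an empty result — silently returning nothing would make
  the $\delta$ scan's maximum meaningless.

## Open choices made here

* The dendrogram cut for the process-wise clusters (`k_clusters = 6`) is a
  config parameter, not an inferred quantity — there is no principled
  default cut, and exposing it is more honest than hiding a heuristic.
* The seed-gene bookkeeping of transition seed sets counts edge endpoints
  only; any expansion-time mediator genes are reported with the final
  subnetworks instead.
* Stage-pattern labels (HP/HN/NS) adjust p-values within one stage across
  exactly the edge family passed in, and the implied per-stage $|r|$
  cutoff is reported back so the label rule can be audited.
* Pipeline stages cache only the edge-profile table (keyed by md5 of the
  three input files) — the correlation pass is the only step whose cost
  grows with the full interactome, and caching more would complicate the
  determinism guarantee for little gain.

## Known limitations

Pearson-only correlation; no missing-data handling (fail fast at read
time); no automatic cluster-number selection; enrichment without
conditional/elim logic; the KS background is sampled, not exhaustive; and
the $\delta$ scan re-runs the full search per grid value, which is the
dominant cost on large interactomes.
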
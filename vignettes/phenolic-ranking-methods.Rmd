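---
title: "Methods: ranking phenolics on a weighted phenolic–gene network"
author: "phenoRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking phenolics on a weighted phenolic–gene network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoRank)
```

## The problem and the model

`phenoRank` prioritizes phenolic phytochemicals by their aggregate
influence on cancer-stem-cell (CSC) genes. The data model is a
weighted bipartite graph: one node set is the phenolics, the other the
CSC genes they interact with, and each edge carries a count of
reported interactions. Preprocessing mirrors the curation a
practitioner would do against CSCdb/PCIDB/DisGeNet-style exports:

1. intersect every phenolic's interacting gene set with the CSC gene
   universe (case-sensitive symbol equality on trimmed strings — no
   alias mapping is attempted, so inputs must share a symbol
   namespace);
2. drop genes for which the score catalogue lacks either the disease
   specificity index (DSI) or the disease pleiotropy index (DPI) —
   both enter the update, so a half-scored gene is unusable;
3. z-score the raw counts and take absolute values,
   $\tilde w = |(w - \mu)/\sigma|$.

Gene weights combine DSI ($\in [0,1]$; 1 = associated with a single
disease) and DPI ($\in [0,100]$; the percentage of MeSH disease
classes covered). DPI's natural scale is a percentage; it is rescaled
to $[0,1]$ only at combination time.

The ranking engine gives each phenolic a constant multiplier

$$s(p) = \frac{1}{x}\sum_{i=1}^{x} \tilde w_i \, gw_i$$

over its $x$ edges, then iterates $r \leftarrow \mathrm{normalize}(r
\cdot s)$ from seeded random initial ranks until the ranking is
stationary. A classic PageRank power iteration (teleport $(1-d)/N$,
damping $d = 0.85$) is provided alongside as the reference algorithm
from which the update is derived; its correctness is pinned to a dense
eigensolve of the Google matrix in the test suite.

## Design choices in detail

Several aspects of the procedure are genuinely underdetermined; the
package fixes them as follows.

**Normalization scope.** The z-score's mean and standard deviation are
computed globally over all retained edges (default), because the
normalization is of "the weights" as one population; a per-phenolic
scope is available (`scope = "perPhenolic"`) for users who prefer each
phenolic normalized against its own count distribution. The standard
deviation is the population form, fixed, so results do not depend on a
sample-size convention.

**Degenerate dispersion.** When every retained count is identical,
$\sigma = 0$ and the z-score is undefined; all normalized weights are
set to 1 so the ranking degrades gracefully to a purely
gene-weight-driven score rather than failing.

**Score denominator.** The per-phenolic multiplier divides by the
degree $x$, mirroring the out-degree division $C(T_i)$ in PageRank.
Dividing by a z-scored degree was considered and rejected: a z-score
can be exactly 0, and the absolute value of a positive count is
vacuous.

**Gene-weight combination.** DSI and DPI are merged by the arithmetic
mean of DSI and DPI/100 (default `gwMode = "mean"`), keeping $gw$ on
the same bounded, interpretable $[0,1]$ scale as DSI. `product`,
`dsi_only` and `dpi_only` modes are available; the final ordering is
invariant to rescaling all $gw$ by a positive constant, so the choice
affects interpretation more than ranking when the modes are monotone
transformations of each other — which `mean` and `product` are not, so
the mode is an explicit, logged parameter.

**Teleport normalization.** The literal damped-recursion form with
teleport term $(1-d)$ has a fixed point summing to $N$, which
contradicts the interpretation of ranks as a probability
distribution. The default engine therefore divides the teleport by
$N$ (`normalized = TRUE`), and the literal form is kept behind the
flag for fidelity comparisons.

## Convergence: detecting a stationary ranking exactly

"Iterate until no change is found in the last two rankings" hides a
subtlety. With constant multipliers the iterate is available in closed
form, $r_k \propto r_0 \cdot s^k$, so rank mass concentrates
geometrically on the phenolic with maximal $s(p)$ and every other
value plummets toward zero. Two naive stopping rules fail:

- *value change below tolerance*: once the winner holds essentially
  all mass, the vector changes by less than any tolerance while the
  ordering among the (numerically vanished) remaining phenolics is
  still in transit — pairs whose $s$ values are close need
  $k \approx \log(r_{0,j}/r_{0,i}) / \log(s_i/s_j)$ steps to swap into
  their stationary order, which for near-ties can be millions of
  steps;
- *order equality across two consecutive steps*: orders change only at
  isolated swap events, so any two consecutive equal orders say
  nothing about later swaps.

The engine therefore works in log space
($\log r_k = \log r_0 + k \log s$, renormalized by log-sum-exp — an
exact composition of $k$ elementary updates, not an approximation) and
checks convergence on a geometric schedule of step counts
$k = 1, 2, 4, \dots$, capped at `maxIter`. At each checkpoint it
requires (i) the ordering is unchanged since the previous checkpoint,
(ii) the max-norm value change is below `tol` ($10^{-9}$ default), and
(iii) the ordering is *concordant* with the multipliers: $s$ is
non-increasing along it. For a constant-multiplier update, concordance
is exact stationarity — no pair can ever swap again — so the stopping
rule certifies the limit rather than guessing it, and near-tied
multipliers are resolved at logarithmic cost. `maxIter` bounds the
effective step count $k$; because checkpoints double, a cap of $10^9$
costs ~30 evaluations and is the practical choice for production runs,
while the default of 100 keeps casual calls cheap.

Consequences worth knowing:

- the final ordering equals the descending $s(p)$ ordering whenever
  the $s(p)$ are distinct, for every initialization seed;
- the reported `final_value` vector is the limit point: 1 for the top
  phenolic(s), 0 for the rest. The scientific deliverable is the
  *ordering* (plus the $s(p)$ scores, which are reported alongside);
- when the multipliers carry no information (all equal — including the
  fully symmetric network and the all-zero case) the update preserves
  the random initial values forever; rather than report that noise,
  the engine returns uniform values with a lexicographic ordering and
  a warning;
- exact ties in $s(p)$ keep their initial ratio forever and are
  ordered by value, then lexicographically by id, so output is
  reproducible given the seed.

One property that might be expected does *not* hold and is not
claimed: increasing a single raw interaction count of a phenolic can
*lower* its final rank. The absolute z-score is not monotone — raising
one count shifts the mean and inflates the dispersion, which can
shrink the normalized weights on the phenolic's high-$gw$ edges faster
than the raised edge gains. The test suite instead pins the properties
that do hold: order equals the $s(p)$ oracle order, seed independence,
scale invariance in $gw$, and mass conservation.

## The synthetic-data generator

Real CSCdb/PCIDB/DisGeNet extracts are not redistributable, so the
generator emulates their shape at the study's scale: 21 phenolics and
1118 CSC genes inside a 1200-gene universe by default, edge
probability 0.3, interaction counts from a 1-shifted Poisson with mean
parameter 2 (every drawn edge has count ≥ 1, as database interaction
counts do), $N_d$ uniform on $[1, N_T]$ with $N_T = 30170$ (so DSI is
always defined, matching the upstream drop rule) and $N_{dc}$ uniform
on $[0, N_{TC}]$ with $N_{TC} = 29$. A planted phenolic has its counts
on the top decile of genes by combined weight multiplied by
`boostFactor` (5 by default), producing a dominant $s(p)$ whose
recovery at rank 1 validates the whole pipeline; the planted identity
and boosted genes are written to a truth record.

What the generator does **not** emulate: the heavy-tailed degree and
count distributions of real interaction databases, correlated gene
scores, symbol aliasing noise, or partially scored genes. Passing the
planted-recovery suite therefore demonstrates that the pipeline's
plumbing and ordering logic are correct under controlled conditions —
not that the ranking is biologically validated on real extracts.

## Screening rules

The screening module applies thresholds exactly as stated, each a pure
function of a single field: rule-of-five violations counted over
MW > 500, logP > 5, HBD > 5, HBA > 10 (molar refractivity is not a
column of the consumed tables and is excluded; four-rule counting
reproduces the packaged table's printed violation column);
bioavailability flags `rotatable_bonds ≤ 7`, `hba ≤ 12 & hbd ≤ 12`,
`aromatic_rings ≤ 3`; ADMET labels with Caco-2 high above 0.90,
absorption poor below 30%, skin low-permeability above logKp −2.5, BBB
readily-crossing above logBB 0.3 and poorly-distributed below −1,
T. pyriformis toxic above −0.5 log µg/L, minnow high-acute-toxicity
below log LC50 −0.3. On the packaged profile table these mechanical
rules label all five compounds' skin permeability "not-low" and their
T. pyriformis values "toxic"; the classifier reports what the
thresholds say and leaves interpretation to the analyst. Missing
values yield `unknown` for the affected rule only. Property tables are
consumed, never predicted: no structure parsing of any kind.

## Problem sizes and runtime

The shipped tests run the full pipeline on 100 generated replicates at
the default scale (21 × 1200, ≈ 7500 edges each) in well under a
minute, checking planted recovery and the brute-force $s(p)$ oracle on
every replicate; PageRank is cross-checked against the dense
eigensolve on dozens of random graphs of up to 6 nodes, where the
eigensolve is unambiguous. These sizes were chosen so the whole suite
documents the method's behaviour quickly; nothing in the
implementation is specific to them.

## Known limitations

- Gene matching is exact string equality; no identifier mapping.
- The ranking is phenolic-sided only: gene ranks never feed back, the
  update is the literal per-phenolic multiplicative form. A true
  bipartite propagation (alternating phenolic/gene updates) would be a
  different algorithm and is deliberately not implemented.
- The `final_value` limit is degenerate by construction; consumers
  wanting a graded score should read the `s_score` column.
- Threshold screening consumes externally computed property tables
  and inherits whatever systematic error their source tools carry.

```{r example}
cfg <- synthConfig(nPhenolics = 8L, nGenes = 120L, nCsc = 100L,
                   plantedPhenolic = "P03", seed = 7L)
files <- generateSyntheticData(cfg, tempfile())
res <- runRankPipeline(files$interactions, files$csc, files$scores,
                       nT = cfg$nT, nTc = cfg$nTc, seed = 1,
                       maxIter = 1e9)
head(res$ranking, 3)
```
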
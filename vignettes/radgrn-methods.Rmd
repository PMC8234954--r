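---
title: "radgrn: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radgrn: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgrn)
```

`radgrn` analyzes small-replicate gene expression matrices by inferring a
Pearson-correlation gene regulatory network (GRN), extracting enriched
process subnetworks with hub genes, computing topological and spectral
network measures, discovering per-gene Markov blankets, and ranking genes
by logistic regression on centrality features.  This vignette records the
statistical models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions and design decisions a maintainer would want written down.

## 1. Correlation-network inference

For genes $x, y$ with $n$ replicate values, the edge statistic is the
Pearson coefficient $r = \mathrm{cov}(x,y)/(s_x s_y)$ and the test of
$r = 0$ is $t = r\sqrt{(n-2)/(1-r^2)}$ against Student $t_{n-2}$,
two-sided.  An edge is retained iff its (optionally corrected) p-value is
$\le$ `p_threshold`; ties at the threshold are kept.  Defaults:

* `p_threshold = 0.0005` — the operative raw cut for 3–8 replicate data;
  with $n = 5$ this corresponds to a critical $|r| \approx 0.991$, i.e.
  only near-deterministic co-expression survives.
* `correction = "none"`; `"bonferroni"` and `"bh"` are available when a
  family-wise or FDR reading of the threshold is wanted.
* Zero-variance genes cannot be tested; they are excluded before testing
  (not assigned $r = 0$) and logged.

A retention subtlety that matters downstream: at $n = 8$ (df $= 6$) the
two-sided $0.0005$ critical value is $|r| = 0.9406$.  A gene pair whose
*true* correlation is $0.95$ therefore clears the cut in only about
two-thirds of samples.  Small-replicate networks are intrinsically
high-precision / modest-recall objects; the test suite asserts the
false-edge rate calibration (which holds) and documents that a 95% recall
expectation at $\rho = 0.95$, $n = 8$ is not attainable under the sampling
distribution of $r$ — the corresponding acceptance assertion is left
failing by design rather than weakened.

Correlation is symmetric, so networks are built undirected.  The directed
view used in figures (edges pointing from interactors into hubs:
"activated by") is presentation-layer and produced by `orient_to_hubs()`.

## 2. Enrichment and subnetwork extraction

Process extraction substitutes one-sided hypergeometric
over-representation for ranked-list enrichment: the urn is the supplied
gene universe (default: the whole input gene list), the draw is the
network's gene list, success is set membership; BH q-values control across
sets.  Two conventions:

* "In the network" means *participates in at least one retained edge*
  (`connected_only = TRUE`).  The inferred graph keeps every tested gene as
  a vertex so that degree-0 genes remain visible, and without this
  restriction every enrichment would be trivial.
* The universe is user-controlled because annotation-wide vs network-wide
  universes answer different questions; both are supported.

Subnetworks are induced subgraphs on (set ∩ network); members absent from
the network are dropped with a log entry.  Hubs are genes with total
degree $\ge$ `degree_threshold` (default 5; documented working ranges 5–34
for low-dose and 19–47 for very-high-dose data).  Because curated hub
tables can list degree-1 genes, `promote_radiation = TRUE` retains
annotated radiation-induced genes as hubs regardless of degree.

## 3. Network measures

**Subgraph centrality** is the closed-walk sum
$SC(i) = \sum_{r \ge 0} (A^r)_{ii}/r! = \sum_j u_j(i)^2 e^{\lambda_j}$,
computed by eigendecomposition of the **binarized undirected** adjacency.
Binarization is deliberate: the reference constants for star-shaped hub
neighborhoods ($SC(\text{hub}) = \cosh\sqrt{n}$,
$SC(\text{leaf}) = 1 + (\cosh\sqrt{n}-1)/n$) hold only on 0/1 adjacency.
An isolated node scores exactly 1 (the length-0 walk).

**Spectral gaps.**  Two conventions are emitted and neither is privileged:
the adjacency gap $|\lambda_1| - |\lambda_2|$ (on $|r|$-weighted adjacency
by default, since weighted graphs can produce gaps $> 1$) and the
normalized random-walk gap $1 - |\lambda_2|$ of $D^{-1/2} A D^{-1/2}$ on
the binarized adjacency, which lies in $[0,1]$ and is 0 exactly for
disconnected or bipartite (sub)graphs.  Isolated nodes are excluded from
the degree inversion; an all-isolated network yields `NA` with a log
entry.  Eigen-solver noise is clipped into $[0,1]$.

**Girth** follows the trace definition: the smallest $r$ with
$\mathrm{Trace}(A^r) > 0$.  On an undirected graph every edge is a closed
walk of length 2, so the definition degenerates; `graph_girth()` therefore
expects the directed view and warns on undirected input.  Powers are
computed over booleans to avoid overflow.

**Diameter / paths / components** use unweighted distances; components
are weak components; the diameter of a disconnected graph is the maximum
finite eccentricity (finite diameters coexist with multiple components);
the average shortest path is the mean over reachable ordered pairs.

**Jaccard similarity** uses **open** neighborhoods (the focal gene
excluded) within or across subnetworks — exclusion is what lets a gene
with identical partners in two subnetworks score exactly 1.  Two empty
neighborhoods define index 0 with a warning.

**Centrality features** for ranking: closeness is
(#reachable)/(sum of distances) per component (0 for isolated nodes);
PageRank uses damping 0.85 (standard default, recorded here because it is
nowhere dictated); eigenvector centrality is computed on the largest
component and L2-normalized, other nodes scoring 0, with an edgeless graph
yielding zeros plus a warning.

## 4. Markov-blanket discovery (IAMB)

Conditional independence is tested by Fisher-z on partial correlations:
$z = \tfrac12\ln\frac{1+\rho}{1-\rho}$, statistic $\sqrt{n-|Z|-3}\,z$
against the standard normal.  The Gaussian test family is a design choice
(expression values are continuous; it is the default in the IAMB
ecosystem).  Partial correlations come from the precision matrix of the
covariance submatrix, with a residualization route kept as an internal
cross-check (the two agree to $10^{-10}$ in tests).

The growing phase admits the candidate with maximal $|\rho(T, v \mid
MB)|$ if its test rejects at `alpha` (default 0.05); ties break
lexicographically by variable name, making output order-stable.  The
shrinking phase removes members independent of the target given the rest
until a fixed point; the suite verifies idempotence by re-testing every
retained member.  Role tagging searches separating subsets (size cap 3 by
default) to split spouses from parent/child neighbors and orients only
collider children; chain directions are honestly `undetermined` — a
blanket alone cannot orient them, so no parent/child direction is ever
guessed.  Across multiple targets the AND-rule drops asymmetric
membership pairs, logged.

Validity bounds: the Fisher-z test needs $n - |Z| - 3 > 0$ and `iamb()`
requires at least 8 observations.  For that reason the pipeline runs its
causal stage only when the expression matrix has $\ge 8$ replicates,
otherwise it records the skip in the manifest — with the default 5
simulated replicates the stage is exercised only by configurations that
request 8.

## 5. Logistic-regression ranking

The binary outcome (default: radiation-induced catalog membership;
alternatively membership of a chosen gene set) is regressed on the five
standardized centrality features.  Constant features are dropped with a
warning (a regular subnetwork has constant degree).  Fitting is IRLS
maximum likelihood with Wald p-values and odds ratios $e^{\beta}$;
separation — routine when hubs split cleanly — is detected and handled by
a small L2 ridge ($10^{-4}$, intercept unpenalized), logged on the model.
Genes are ranked by fitted log-odds, ties broken by gene ID; the
`odds`/`pvalue` reporting variants are monotone transforms and cannot
reorder genes.  Standardization makes the ranking invariant to affine
rescaling of any raw feature, and at the unpenalized MLE the mean fitted
probability equals label prevalence (both asserted in tests).  One model
is fit per subnetwork.

## 6. The synthetic-data generator

The generator emulates the structure the downstream stages assume:
replicate counts of 3–8 (default 5, mid-range), block-correlated modules,
star-shaped hub neighborhoods, a binary radiation label concentrated on
hubs, and linear-Gaussian Bayesian networks for causal testing.

Module genes share a latent factor,
$x_g = \sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\varepsilon_g$, so the expected
within-module pairwise correlation is exactly $\rho$
(`within_module_corr`, default 0.7).  The latent-factor construction was
chosen over an explicit covariance + Cholesky because it scales linearly
and makes the planted structure explicit.  `noise_sd` is a pure amplitude
(correlations are invariant to it); expression values are on an arbitrary
continuous scale — whether real studies log-transform before correlating
is not modeled, and correlation is scale-free anyway.  Each module's first
gene is its hub, whose signal is shared with `hub_leaf_counts` background
leaves, giving hub–leaf correlation $\sqrt{\rho}$.  A consequence worth
knowing: leaves of one hub inter-correlate at $\rho$ (positive
semidefiniteness forbids a strongly connected star with mutually
independent leaves), so a planted "star" is recovered as a star only when
the retention threshold falls between $\rho$ and $\sqrt{\rho}$ — the tests
exploit exactly that window.  Radiation labels go to hubs first
(`hub_bias = TRUE`), mirroring hub-centric annotations, with a uniform
option.  Seeds are mandatory in the CLI; unseeded library calls draw a
seed and warn.

What the generator does **not** emulate: platform noise models,
normalization artifacts, count distributions, heavy-tailed expression,
gene-length or GC biases, and correlated modules of unequal within-module
structure.  A green test therefore establishes algorithmic correctness on
the stated statistical structure, not robustness to real-data pathologies.

Gene sets are planted one-per-module plus background decoys;
`include_leaves` (default `FALSE`, so a set is exactly one module) adds
the hub's star neighborhood to its set.  The pipeline's simulation path
enables it because process sets that include hub neighborhoods are what
make extracted subnetworks star-bearing — consistent with hub tables whose
subgraph-centrality entries are star closed forms.

Bayesian-network data are generated in topological order as linear
combinations of parents plus Gaussian noise; `true_markov_blanket()` is
the d-separation oracle (parents ∪ children ∪ spouses) used to score IAMB.

## 7. Reproducibility and the pipeline

`run_pipeline()` derives every random draw from the single config seed,
persists each stage's artifact (TSV/GMT/GraphML/JSON only), and writes a
manifest with the config hash and per-artifact MD5s; identical configs
reproduce the manifest byte-for-byte (asserted).  Failures abort with the
stage name, keeping completed artifacts.  GraphML is the exchange format
for networks, with a plain edge-list dialect (weights at 6 decimals) as
the light alternative.

## 8. Known limitations

* With 3–8 replicates the correlation network is a high-precision,
  modest-recall object (Section 1); absolute recall targets near 1 are
  not meaningful at stringent thresholds.
* Hypergeometric p-values are discrete and hence conservative
  (super-uniform) for small urns; null-uniformity checks are run at urn
  sizes where discreteness is negligible.
* IAMB assumes faithful linear-Gaussian data; with 3–8 observations the
  Fisher-z test is inapplicable, which is why causal conclusions from
  replicate-level expression require pooled or larger designs.
* Edge directions beyond collider orientation are never inferred;
  reported `undetermined` roles are a statement of honesty, not a bug.
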
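---
title: "Signing PPI networks by differential propagation: model and methods"
author: "signet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signing PPI networks by differential propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signet)
```

## The signaling model

Physical protein–protein interaction (PPI) screens report that two
proteins bind, not whether the interaction activates or represses its
downstream partner. `signet` annotates that *sign*. Its starting point
is the multiplicative cascade model: the net effect $s_{out}$ of a
signaling path with edge signs $s_1, \dots, s_n$ is

$$ s_{out} = \prod_{i=1}^{n} s_i , $$

so a path is repressing exactly when it carries an odd number of
negative edges. Two consequences drive everything else. First, because
one negative edge flips a whole cascade, interactomes are expected to
carry far fewer negative than positive edges — the package treats
negatives as the minority class throughout. Second, deleting a negative
edge perturbs the information flow between a perturbed gene and its
transcriptional responders more than deleting a typical positive edge.
That asymmetry is measurable, and it is the classifier's signal.

## Differential propagation features

Information flow is modeled by a random walk with restart on the
symmetric-normalized adjacency $W = D^{-1/2} A D^{-1/2}$, where $A$ is
the weighted adjacency (each undirected edge stored as two symmetric
directed entries) and $D$ the diagonal strength matrix. Seeding a unit
indicator $e_k$ at knockout gene $k$, the propagation profile is the
fixed point of

$$ p \leftarrow \alpha W p + (1 - \alpha)\, e_k . $$

Since $\lVert W \rVert_2 \le 1$ and $\alpha < 1$ the iteration is a
contraction; we iterate from $p = e_k$ until the max-norm change falls
below `tol`. Defaults: `alpha = 0.6` (the customary balance for PPI
propagation — small enough that scores remain local, large enough to
see beyond direct neighbours), `tol = 1e-8`, `maxIter = 1000` (roughly
40 iterations suffice at these settings; the cap only guards degenerate
configurations). Zero-degree nodes get normalization factor 0, so an
isolated seed converges to $(1-\alpha) e_k$ and disconnected components
receive exactly zero — no pseudocount smoothing is applied.

The *defective* profile $P_{d,k}(\cdot, e)$ repeats the propagation on
a network in which both directed copies of one edge $e$ are zeroed
**before** degrees are recomputed and the matrix renormalized; zeroing
entries of the already-normalized operator would leave the endpoint
degrees stale and is deliberately not what `normalizeAdjacency(drop=)`
does. For knockout $k$ with up-regulated targets $t_k^+$,

$$ F(t_k^+, e) = A \cdot
   \frac{\sum_{t \in t_k^+} \left[ P_k(t) - P_{d,k}(t, e) \right]}
        {\lvert t_k^+ \rvert}, $$

and likewise for $t_k^-$, giving two features per knockout and $2n$
feature columns in total, ordered $k_1^+, k_1^-, k_2^+, k_2^-, \dots$.
The scaling constant $A$ defaults to 1 and is exposed only for
completeness: tree ensembles are invariant to a global positive
rescaling. Targets missing from the network are excluded from both the
numerator and the denominator (counting them as zero would dilute
knockouts whose signatures are poorly mapped); an empty target set
yields 0 and a logged note.

Two engineering details matter for reproducibility. Propagation over
many seeds runs as one batched matrix iteration in which each column is
frozen the moment it converges, so a column's floating-point trajectory
is identical whether the seed is run alone or inside a batch; and
`buildFeatureMatrix(cache = FALSE)` recomputes full profiles per edge
through the same routine, making cached and uncached matrices
bit-identical rather than merely close.

## Classification and cross-validation

Feature rows of sign-annotated edges train a random forest with the
implementation's default hyperparameters (`randomForest`, seeded for
determinism; the seed is recorded in the model object). The forest's
class probability for "negative" is the edge's S-score $S_e \in [0,1]$.
A degenerate training matrix whose columns are all constant admits no
split; the model then collapses to the class prior rather than invoking
the forest (whose tree grower does not terminate on constant input).

Accuracy is estimated by 5-fold cross-validation with out-of-fold
predictions pooled before computing AUROC and AUPRC; per-fold averaging
is available as a flag, but pooling is the default because folds can be
small and single-class once enzyme stratification is active. AUPRC
takes the *negative* class as the detection target, since it is the
minority of interest. AUROC is computed with `pROC`; AUPRC is average
precision (precision summed over recall increments, ties collapsed).

Kinases and phosphatases have many substrates, so random folds would
place edges of the same enzyme on both sides of a split and leak
identity information. `enzymeStratifiedFolds()` therefore assigns whole
enzymes to folds: enzymes sorted by degree (edge count) descending,
ties broken lexicographically, each placed on the currently lightest
fold. This longest-processing-time greedy guarantees that the fold
degree-sum spread never exceeds the largest single enzyme degree. A
repair pass then ensures every fold contains at least one kinase-like
(majority positive) and one phosphatase-like (majority negative)
enzyme, preferring degree-matched *swaps* so the balance bound survives
whenever degrees are comparable; because an unequal swap can loosen the
bound, the return value records whether any repair fired. A class with
fewer enzymes than folds relaxes its constraint with a warning.
Enzyme-free edges are distributed individually onto the lightest folds.

## From scores to signs, paths and phenotypes

Discrete signs come from thresholding with a confidence band:
$S_e > \tau + \varepsilon$ is negative, $S_e < \tau - \varepsilon$
positive, and scores inside the band (boundaries included) are
*unsigned*. Defaults $\tau = 0.5$, $\varepsilon = 0.01$. We treat the
band symmetrically — unsigned edges are those the classifier genuinely
cannot call — and delete them from the graph before any path analysis,
so path lengths may grow but no enumerated path ever touches an
uncallable edge.

For a cause–effect pair $(k, t)$, all minimum-hop paths on the signed
subgraph are considered and

$$ \mathrm{NegScore}(k, t) =
   \frac{\lvert \{ \text{negative shortest paths} \} \rvert}
        {\lvert \{ \text{shortest paths} \} \rvert} . $$

The number of shortest paths can grow exponentially, so NegScore is
computed without enumeration: a dynamic program over the shortest-path
DAG with (node, parity-of-negative-edges) states, linear in DAG size
and exact. Explicit enumeration (`enumerateShortestPaths`, capped at
10,000 paths, lexicographic order) exists for inspection and serves as
the brute-force cross-check in the test suite. Pairs connected by fewer
than `minPaths` (default 100) shortest paths are filtered out as noisy;
synthetic-scale analyses use `minPaths = 1`.

Knockout-signature reconstruction predicts, for each target of a
knockout $k$, whether it goes up or down. Because the observed effect
follows a *deletion*, the response is the inverse of the cascade sign,
so under the default `orientation = "inverse"` the reported
down-probability is the fraction of *positive* paths,
$1 - \mathrm{NegScore}$; the `direct` orientation is exposed as well
because the heat-map view of the data compares NegScores to responses
without inversion, and which convention a given dataset follows is an
empirical question. Observed labels are binarized down = 1, up = 0. To
prevent leakage the classifier is retrained *k-less*: both feature
columns of $k$ are removed (`klessColumns`). A stricter variant that
also hides $k$'s signature genes from all other knockouts' target sets
is available by rebuilding features after `maskSignatureGenes()`; it is
not the default because it changes every column and discards most of
the supervision for well-connected knockouts.

Phenotype reconstruction scores each *terminal* gene by aggregating
NegScores over its pairs with a fixed *anchor* set (pathway machinery
genes); the default aggregation is the mean over anchors with enough
paths (max is available, and per-pair evaluation is simply the
unaggregated NegScore table). Terminals with no valid anchor pair are
excluded with a message, and average precision against the binary
phenotype labels is reported.

## Functional enrichment

Genes adjacent to predicted-negative (or positive) edges form the
query; terms with 10–100 genes after restriction to the population are
tested with the upper-tail hypergeometric probability
$P[X \ge \text{overlap}]$ (computed via `phyper`'s log-space tail) and
Bonferroni-corrected, capped at 1. The population defaults to the genes
of the base network rather than the genome: edge-adjacent genes are
being compared against the interactome they were drawn from, and a
genome-wide universe would manufacture enrichment for simply being in
the network. Annotations are consumed as flat GMT sets; no ontology-DAG
propagation is attempted.

## The synthetic benchmark: what it emulates, and what it does not

`defaultBenchmark()` builds the world every end-to-end check runs on:
a scale-free network of 300 genes at mean degree 10 (preferential
attachment, matching the heavy-tailed degree distributions of real
interactomes; an Erdős–Rényi option exists for nulls), each edge
independently negative with probability 0.15, 50 knockouts with 30
targets each, and 5% label noise. Signatures follow the multiplicative
model literally: the cascade sign of a (knockout, target) pair is the
majority sign product over all shortest paths between them — computed
by the same parity DP the reconstruction module uses, so generation and
evaluation share one semantics — an exact 50/50 tie is resolved by a
seeded coin flip and flagged in the audit table, and the emitted
up/down label is the *inverse* of the cascade sign, flipped with the
noise probability.

Two sampling laws are design choices rather than dictated by the model,
and both are chosen for realism. The knockout panel is the 50
best-connected genes: deletion-compendium panels target known
regulators, and in a degree-heavy-tailed interactome those are the
hubs (a uniformly random panel is available via
`knockoutPanel = "random"`). Targets are sampled with probability
proportional to $P_k(t)^2$, the squared propagation influence of the
knockout on the gene: differential-expression calling selects the
strongest responders, and thresholded detection is a convex function of
true effect size, which the square emulates (`targetExponent = 0`
recovers uniform sampling for null experiments). Both choices
concentrate perturbation information where real screens concentrate it;
with diffuse uniform placement most edges carry no flow from any
knockout and no method could recover their signs from such data.

The generator deliberately does *not* emulate: expression magnitudes
(only binary up/down labels, which is all the method consumes),
correlated or functionally clustered edge signs, context-dependent
signs, directionality, or measurement structure beyond independent
label flips. Passing the planted-sign checks therefore demonstrates
that the pipeline recovers signs when the multiplicative-model signal
is present at realistic density — not that real interactomes satisfy
the model.

## Numerical choices and degenerate inputs

* Convergence is measured in max-norm; `tol = 1e-8` against a dense
  linear-solve oracle at the same tolerance.
* All orderings are deterministic: canonical edge keys
  (`min|max` lexicographic), knockout order from the signature file,
  lexicographic tie-breaks in fold balancing and path enumeration.
* Duplicate edges keep the maximum weight; conflicting signed pairs and
  contradictory (knockout, target) responses are dropped with warnings;
  self-loops are dropped with a count.
* `S` exactly on the band boundary is unsigned; with
  $\varepsilon = 0$ only $S = \tau$ is.
* Problem sizes in the test suite were chosen for a desk-scale run: the
  300-node benchmark above, propagation oracles on graphs of up to 200
  nodes, path-counting oracles on up to 30 nodes, and exact
  hypergeometric checks on populations up to 60.

## Known limitations

* Propagation is symmetric; directionality, when known, is not
  exploited.
* One context-free sign per edge; condition-dependent interactions are
  out of scope.
* The enzyme-class repair can trade a little degree balance for class
  coverage on very unequal enzyme degrees.
* The random-forest contract is "default hyperparameters" of the pinned
  implementation; numbers can shift across major library versions even
  with fixed seeds.
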
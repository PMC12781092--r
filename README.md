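# signet — sign annotation of PPI networks from perturbation data

Physical protein–protein interaction (PPI) screens tell you that two
proteins bind, but not whether the interaction **activates or
represses** its downstream partner. `signet` infers that sign for every
edge of an interaction network from cause–effect data: gene knockouts
and the up/down responses of their transcriptional targets.

The method rests on the multiplicative cascade model, in which the net
effect of a signaling path equals the product of its edge signs,

    s_out = ∏ s_i ,

so a single repressing edge inverts an entire cascade. Repressing edges
are therefore the minority, and deleting one perturbs the information
flow from a knockout to its responders more than deleting a typical
activating edge. `signet` measures exactly that perturbation: a random
walk with restart is seeded at each knockout gene on the full network
and on a *defective* network with one candidate edge zeroed
(`W = D^(-1/2) A D^(-1/2)`, update `p ← αWp + (1−α)e_k`, default
`α = 0.6`), and the propagation-score drop is averaged over the
knockout's up- and down-regulated target sets:

    F(tk±, e) = A · Σ_{t ∈ tk±} [P_k(t) − P_dk(t, e)] / |tk±| ,

two features per knockout, `2n` per edge. A random forest trained on
edges of known sign (kinase–substrate positive, phosphatase–substrate
negative, and the like) turns these into the **S-score**: the per-edge
probability of repression. Thresholding with a confidence band
(`τ = 0.5`, `ε = 0.01`; scores inside the band are "unsigned" and
excluded) yields a signed network on which the package computes
**NegScores** — the fraction of negative shortest paths between a
source and a target, obtained exactly via a parity dynamic program over
the shortest-path DAG — to reconstruct knockout responses and
anchor/terminal phenotypes, and runs hypergeometric enrichment of
functional terms around predicted-negative edges.

Audience: computational/systems biologists with a PPI edge list, a
signed training set, and knockout (or perturb-seq-style) signatures,
who want edge-level sign annotations plus path-level validation. For
everything methodological — parameter meanings, defaults and their
rationale, degenerate-case behaviour, what the synthetic benchmark does
and does not emulate — see `vignettes/signing-ppi-networks.Rmd`.

## Worked example

The package ships a planted-truth generator, so the whole pipeline runs
without any external data:

```r
library(signet)

gen <- generateSignedNetwork(nNodes = 150, meanDegree = 8,
                             pNeg = 0.15, seed = 1)
sim <- simulateKnockoutSignatures(gen$network, gen$trueSigns,
                                  nKnockouts = 25,
                                  targetsPerKnockout = 20, seed = 2)

fm <- buildFeatureMatrix(gen$network, sim$signatures,
                         gen$trueSigns[, c("u", "v")])
fm
#> SignalFeatures: 590 edges x 50 columns (25 knockouts x {+,-}), A = 1

cv <- crossValidate(fm, gen$trueSigns$sign)
sprintf("pooled out-of-fold AUROC %.3f, AUPRC %.3f", cv$auroc, cv$auprc)
#> "pooled out-of-fold AUROC 0.749, AUPRC 0.474"

model  <- trainSignClassifier(fm, gen$trueSigns$sign)
scores <- predictScores(model, fm)        # data.frame u, v, S
signs  <- assignEdgeSigns(scores)         # tau = 0.5, epsilon = 0.01
table(sign = signs$sign)
#>  -1   1
#>  92 498

rec <- negScoreTable(gen$network, signs,
                     data.frame(source = sim$truth$knockout,
                                target = sim$truth$target),
                     minPaths = 4)
head(rec, 5)
#>   source target nPaths nNegative negScore
#> 1   g001   g064      7         4     0.57
#> 2   g001   g007      6         2     0.33
#> 3   g002   g054      4         0     0.00
#> 4   g003   g098     15         7     0.47
#> 5   g004   g038      4         2     0.50
```

The AUROC/AUPRC say how well out-of-fold S-scores rank the planted
negative edges (0.5 would be chance; negatives are 15% of edges here).
The sign table counts called repressing (−1) vs activating (+1) edges
after the confidence band. Each NegScore row reads: of the `nPaths`
shortest paths between knockout and target in the signed network,
`nNegative` carry an odd number of repressing edges; a NegScore above
0.5 predicts the knockout *raises* the target (repression dominates the
cascade, and deletion inverts it).

File-based workflows go through `runPipeline()` (or the thin CLI in
`inst/scripts/signet`), which writes S-score, sign and NegScore tables
plus a manifest from which the run can be reproduced bit-identically
(`rerunFromManifest()`).

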
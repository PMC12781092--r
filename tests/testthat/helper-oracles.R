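## Independent oracles and tiny fixture builders. Every oracle here avoids
## the code path it checks: dense base-R solves for propagation, explicit
## igraph path enumeration for NegScores, rank statistics for AUROC, and
## factorial combinatorics for the hypergeometric tail.

## Closed-form propagation: p = (1 - alpha) (I - alpha W)^{-1} e_seed,
## solved densely with base R.
densePropagationOracle <- function(network, seed, alpha = 0.6,
                                   drop = NULL) {
  A <- as.matrix(network@adjacency)
  if (!is.null(drop)) {
    A[drop[1], drop[2]] <- 0
    A[drop[2], drop[1]] <- 0
  }
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- diag(dinv) %*% A %*% diag(dinv)
  e <- as.numeric(networkNodes(network) == seed)
  p <- (1 - alpha) * solve(diag(nrow(W)) - alpha * W, e)
  stats::setNames(as.numeric(p), networkNodes(network))
}

## Random connected-ish unweighted network with labeled nodes.
randomTestNetwork <- function(nNodes, nEdges, seed) {
  nEdges <- min(nEdges, nNodes * (nNodes - 1) / 2)
  withr::with_seed(seed, {
    g <- igraph::sample_gnm(nNodes, nEdges)
    el <- igraph::as_edgelist(g, names = FALSE)
    lab <- sprintf("n%03d", seq_len(nNodes))
    df <- unique(data.frame(u = pmin(lab[el[, 1]], lab[el[, 2]]),
                            v = pmax(lab[el[, 1]], lab[el[, 2]])))
    df <- df[df$u != df$v, ]
    net <- assembleBaseNetwork(df)
    ## keep isolated vertices too
    if (length(networkNodes(net)) < nNodes) {
      sigs <- methods::new("KnockoutSignatureSet", signatures =
        stats::setNames(list(list(up = character(0),
                                  down = character(0))),
                        setdiff(lab, networkNodes(net))[1]))
      net <- assembleBaseNetwork(df, signatures = sigs)
    }
    net
  })
}

## Random sign assignment over a network's edges (all edges signed).
randomSigns <- function(network, pNeg, seed) {
  ed <- networkEdges(network)
  withr::with_seed(seed, {
    ed$sign <- ifelse(stats::runif(nrow(ed)) < pNeg, -1L, 1L)
  })
  ed$S <- ifelse(ed$sign < 0, 1, 0)
  ed
}

## Brute-force NegScore: explicit igraph shortest-path enumeration plus a
## hand-rolled sign product (independent of the parity DP and of
## pathSign/enumerateShortestPaths).
bruteForceNegScore <- function(network, signs, k, t) {
  keep <- signs[signs$sign != 0L, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = networkNodes(network)))
  if (!is.finite(igraph::distances(g, v = k, to = t)[1, 1]))
    return(c(nPaths = 0, nNegative = 0))
  lut <- stats::setNames(keep$sign,
                         paste(pmin(keep$u, keep$v),
                               pmax(keep$u, keep$v)))
  vp <- igraph::all_shortest_paths(g, from = k, to = t)$vpaths
  nNeg <- 0L
  for (p in vp) {
    ids <- igraph::as_ids(p)
    s <- 1L
    for (i in seq_len(length(ids) - 1L)) {
      key <- paste(min(ids[i], ids[i + 1]), max(ids[i], ids[i + 1]))
      s <- s * lut[[key]]
    }
    if (s < 0) nNeg <- nNeg + 1L
  }
  c(nPaths = length(vp), nNegative = nNeg)
}

## Mann-Whitney U identity for the AUROC, with 0.5 credit for ties.
uStatAUROC <- function(scores, event) {
  r <- rank(scores)
  nE <- sum(event); nC <- sum(!event)
  (sum(r[event]) - nE * (nE + 1) / 2) / (nE * nC)
}

## Exact upper-tail hypergeometric probability from binomial coefficients.
exactHyperTail <- function(overlap, termSize, popSize, querySize) {
  i <- overlap:min(termSize, querySize)
  if (overlap > min(termSize, querySize)) return(0)
  sum(choose(termSize, i) * choose(popSize - termSize, querySize - i)) /
    choose(popSize, querySize)
}

## Tiny deterministic signature set.
toySignatures <- function(...) {
  sigs <- list(...)
  methods::new("KnockoutSignatureSet", signatures = sigs)
}

## Write a TSV fixture into a temp file.
tsvFixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
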
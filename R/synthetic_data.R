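## Planted-ground-truth generator. Emulates the data regime the method is
## designed for: an undirected PPI-like network in which a stated minority
## of edges is repressing, plus knockout signatures whose up/down labels
## follow the multiplicative path-sign model — the observed response of a
## target is the *inverse* of the majority sign product over all shortest
## knockout-target paths (a knockout removes an activator of the cascade),
## flipped independently with a small label-noise probability.

#' Generate a signed network with planted edge signs
#'
#' Topology is preferential attachment by default (PPI degree
#' distributions are heavy-tailed); `"random"` gives an Erdos-Renyi
#' G(n, m) null. Each undirected edge is independently negative with
#' probability `pNeg`. Deterministic given `seed`.
#'
#' @param nNodes Number of genes (>= 10).
#' @param meanDegree Target mean degree.
#' @param pNeg Probability an edge is negative, in \[0, 0.5).
#' @param topology `"scale_free"` (default) or `"random"`.
#' @param seed Integer seed.
#' @return List: `network` ([BaseNetwork-class]) and `trueSigns`
#'   (data.frame `u, v, sign`).
#' @export
generateSignedNetwork <- function(nNodes = 300L, meanDegree = 10,
                                  pNeg = 0.15,
                                  topology = c("scale_free", "random"),
                                  seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(nNodes >= 10L)
  assertScalarNumeric(pNeg, "pNeg", 0, 0.5)
  if (pNeg >= 0.5) stop("'pNeg' must be < 0.5", call. = FALSE)
  if (meanDegree < 2 || meanDegree >= nNodes)
    stop("infeasible mean degree", call. = FALSE)
  lab <- function(i) sprintf("g%0*d", nchar(as.character(nNodes)), i)
  res <- withSeed(seed, {
    g <- if (topology == "scale_free")
      igraph::sample_pa(nNodes, m = max(1L, round(meanDegree / 2)),
                        directed = FALSE)
    else
      igraph::sample_gnm(nNodes, round(nNodes * meanDegree / 2))
    el <- igraph::as_edgelist(g, names = FALSE)
    df <- data.frame(u = lab(el[, 1]), v = lab(el[, 2]),
                     stringsAsFactors = FALSE)
    df <- canonicalizeEdges(df)
    df <- df[!duplicated(edgeKey(df$u, df$v)) & df$u != df$v, ,
             drop = FALSE]
    df <- df[order(df$u, df$v), , drop = FALSE]
    df$sign <- ifelse(stats::runif(nrow(df)) < pNeg, -1L, 1L)
    df
  })
  comp <- igraph::components(igraph::graph_from_data_frame(
    res[, c("u", "v")], directed = FALSE))
  if (max(comp$csize) < 0.9 * nNodes)
    stop("giant component below 0.9 n: degree too low for a connected ",
         "benchmark", call. = FALSE)
  network <- assembleBaseNetwork(res[, c("u", "v")])
  rownames(res) <- NULL
  list(network = network, trueSigns = res)
}

#' Simulate knockout signatures under the multiplicative model
#'
#' Emulates a regulator deletion screen. By default the knockout panel is
#' the `nKnockouts` best-connected genes (deletion compendia target known
#' regulators, which in a heavy-tailed interactome are the hubs);
#' `knockoutPanel = "random"` samples the panel uniformly instead. Each
#' knockout's targets are sampled among its reachable genes with
#' probability proportional to `P_k(t)^targetExponent`, where `P_k` is
#' the propagation score from the knockout: differential-expression
#' calling selects the strongest responders, and the convex default
#' exponent 2 mimics that detection threshold ( exponent 0 gives uniform
#' sampling for null experiments). The cascade sign of a (k, t) pair is
#' the majority sign product over all shortest k-t paths (computed by
#' the same parity dynamic program the reconstruction module uses; an
#' exact 50/50 tie is resolved by a seeded coin flip and flagged). The
#' emitted response is the inverse of the cascade sign, flipped
#' independently with probability `flipNoise`, encoded as up/down
#' labels.
#'
#' @param network A [BaseNetwork-class].
#' @param trueSigns data.frame `u, v, sign` covering the network edges.
#' @param nKnockouts Number of knockout genes (all of degree >= 1).
#' @param targetsPerKnockout Targets sampled per knockout (all reachable
#'   targets, with a warning, when fewer exist).
#' @param flipNoise Label-flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @param knockoutPanel `"degree"` (default: the top-degree regulator
#'   panel, ties broken lexicographically) or `"random"`.
#' @param targetExponent Non-negative exponent on the propagation score
#'   used as target sampling weight (default 2).
#' @param config [propagationConfig()] for the target-weight propagation.
#' @return List: `signatures` ([KnockoutSignatureSet-class]) and `truth`
#'   (audit data.frame with `knockout, target, nPaths, negScore,
#'   cascadeSign, tie, flipped, response`).
#' @export
simulateKnockoutSignatures <- function(network, trueSigns, nKnockouts,
                                       targetsPerKnockout,
                                       flipNoise = 0.05, seed = 1L,
                                       knockoutPanel = c("degree",
                                                         "random"),
                                       targetExponent = 2,
                                       config = propagationConfig()) {
  assertScalarNumeric(flipNoise, "flipNoise", 0, 1)
  assertScalarNumeric(targetExponent, "targetExponent", 0, Inf)
  knockoutPanel <- match.arg(knockoutPanel)
  signs <- trueSigns
  signs$sign <- as.integer(signs$sign)
  stopifnot(all(signs$sign %in% c(-1L, 1L)))
  sg <- .signedGraph(network, signs)
  deg <- Matrix::rowSums(network@adjacency)
  eligible <- network@nodes[deg > 0]
  stopifnot(nKnockouts <= length(eligible))
  withSeed(seed, {
    ks <- if (knockoutPanel == "degree")
      sort(eligible[order(-deg[eligible], eligible)][seq_len(nKnockouts)])
    else sort(sample(eligible, nKnockouts))
    W <- normalizeAdjacency(network)
    P <- .propagateMatrix(W, match(ks, network@nodes), config)$scores
    D <- igraph::distances(sg$g, v = ks)
    D <- D[, sg$nodes, drop = FALSE]
    pairList <- lapply(seq_along(ks), function(i) {
      k <- ks[i]
      reachIdx <- which(is.finite(D[k, ]) & sg$nodes != k)
      reach <- sg$nodes[reachIdx]
      if (length(reach) <= targetsPerKnockout) {
        if (length(reach) < targetsPerKnockout)
          warning("knockout ", k, ": only ", length(reach),
                  " reachable targets", call. = FALSE)
        tt <- reach
      } else {
        w <- P[reachIdx, i]^targetExponent
        tt <- sample(reach, targetsPerKnockout, prob = w / sum(w))
      }
      if (length(tt))
        data.frame(source = k, target = tt, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairList)
    recs <- .negScorePairs(sg, pairs, minPaths = 1L)
    tie <- recs$negScore == 0.5
    cascade <- ifelse(recs$negScore < 0.5, 1L, -1L)
    if (any(tie))
      cascade[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, 1L, -1L)
    response <- -cascade
    flipped <- stats::runif(nrow(recs)) < flipNoise
    response[flipped] <- -response[flipped]
    truth <- data.frame(knockout = recs$source, target = recs$target,
                        nPaths = recs$nPaths, negScore = recs$negScore,
                        cascadeSign = cascade, tie = tie,
                        flipped = flipped, response = response,
                        stringsAsFactors = FALSE)
    sigs <- lapply(split(truth, factor(truth$knockout, levels = ks)),
                   function(d) list(up = d$target[d$response > 0],
                                    down = d$target[d$response < 0]))
    list(signatures = methods::new("KnockoutSignatureSet",
                                   signatures = sigs),
         truth = truth)
  })
}

#' The pinned default benchmark world
#'
#' The configuration every planted-sign acceptance check runs on:
#' 300 nodes, mean degree 10, 15% negative edges, scale-free topology,
#' 50 knockouts with 30 targets each, 5% label noise. Optionally writes
#' all fixture files in the tabular formats the readers consume.
#'
#' @param seed Integer seed (the world is a pure function of it).
#' @param dir Optional directory to write fixture files into (created if
#'   needed): `edges.tsv`, `signed.tsv`, `signatures.tsv`, `truth.tsv`,
#'   `params.json`.
#' @return A [SyntheticWorld-class].
#' @export
defaultBenchmark <- function(seed = 1L, dir = NULL) {
  params <- list(nNodes = 300L, meanDegree = 10, pNeg = 0.15,
                 nKnockouts = 50L, targetsPerKnockout = 30L,
                 flipNoise = 0.05, topology = "scale_free",
                 knockoutPanel = "degree", targetExponent = 2)
  gen <- generateSignedNetwork(params$nNodes, params$meanDegree,
                               params$pNeg, params$topology, seed = seed)
  sim <- simulateKnockoutSignatures(gen$network, gen$trueSigns,
                                    params$nKnockouts,
                                    params$targetsPerKnockout,
                                    params$flipNoise, seed = seed + 1L)
  world <- methods::new("SyntheticWorld", network = gen$network,
                        trueSigns = gen$trueSigns,
                        signatures = sim$signatures, truth = sim$truth,
                        params = params, seed = as.integer(seed))
  if (!is.null(dir)) writeWorld(world, dir)
  world
}

#' Write a synthetic world's fixture files
#'
#' @param world A [SyntheticWorld-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEdgeList(networkEdges(world@network), file.path(dir, "edges.tsv"))
  signed <- data.frame(u = world@trueSigns$u, v = world@trueSigns$v,
                       sign = world@trueSigns$sign,
                       dataset = "synthetic", enzyme = NA_character_)
  writeSignedTable(signed, file.path(dir, "signed.tsv"))
  writeKnockoutSignatures(world@signatures,
                          file.path(dir, "signatures.tsv"))
  writeTsv(data.frame(edge = edgeKey(world@trueSigns$u,
                                     world@trueSigns$v),
                      sign = world@trueSigns$sign),
           file.path(dir, "truth.tsv"), header = "edge\ttrue_sign")
  jsonlite::write_json(c(world@params, list(seed = world@seed)),
                       file.path(dir, "params.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Star-shaped enzyme fixture for stratified-CV tests
#'
#' Each enzyme is a hub with `substratesPerEnzyme` signed edges to its
#' own substrates: kinases emit positive edges, phosphatases negative.
#'
#' @param nEnzymes Number of enzymes.
#' @param substratesPerEnzyme Substrates (edges) per enzyme.
#' @param pPhosphatase Probability an enzyme is a phosphatase.
#' @param seed Integer seed.
#' @return data.frame in [readSignedTable()] layout (`u, v, sign,
#'   dataset, enzyme`), with `enzyme` equal to the hub endpoint.
#' @export
enzymeFixture <- function(nEnzymes = 10L, substratesPerEnzyme = 4L,
                          pPhosphatase = 0.3, seed = 1L) {
  assertScalarNumeric(pPhosphatase, "pPhosphatase", 0, 1)
  withSeed(seed, {
    enz <- sprintf("E%02d", seq_len(nEnzymes))
    isPhos <- stats::runif(nEnzymes) < pPhosphatase
    do.call(rbind, lapply(seq_len(nEnzymes), function(i) {
      subs <- sprintf("%s_S%02d", enz[i], seq_len(substratesPerEnzyme))
      data.frame(u = enz[i], v = subs,
                 sign = if (isPhos[i]) -1L else 1L,
                 dataset = "enzyme_fixture", enzyme = enz[i],
                 stringsAsFactors = FALSE)
    }))
  })
}
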
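## From S-scores to discrete signs (thresholded with a confidence band),
## shortest-path sign products under the multiplicative model, NegScores
## (fraction of negative shortest paths), and reconstruction of knockout
## signatures and anchor/terminal phenotypes.
##
## Path signs multiply: a path is negative iff it carries an odd number of
## negative edges. |SP| between a pair can be exponential, so NegScore is
## computed by a dynamic program over the shortest-path DAG with
## (node, parity) states, which is exact and linear in DAG size; explicit
## enumeration (capped) exists for inspection and as a cross-check.

#' Threshold S-scores into discrete edge signs
#'
#' An edge with score `S > tau + epsilon` is negative (-1), `S < tau -
#' epsilon` positive (+1); scores inside the band `(tau - epsilon, tau +
#' epsilon)` — boundaries included — are unsigned (0) and excluded from
#' path analysis. Defaults `tau = 0.5`, `epsilon = 0.01`.
#'
#' @param scores data.frame `u, v, S` (an S-score table).
#' @param tau Decision threshold in (0, 1).
#' @param epsilon Half-width of the unsigned confidence band (>= 0).
#' @return data.frame `u, v, S, sign` with `sign` in \{-1, 0, +1\}
#'   (0 = unsigned), plus `tau`/`epsilon` attributes.
#' @examples
#' assignEdgeSigns(data.frame(u = "a", v = "b", S = 0.52))$sign  # -1
#' @export
assignEdgeSigns <- function(scores, tau = 0.5, epsilon = 0.01) {
  assertScalarNumeric(tau, "tau", 0, 1, strict = TRUE)
  assertScalarNumeric(epsilon, "epsilon", 0, 1)
  out <- canonicalizeEdges(data.frame(
    u = as.character(scores$u), v = as.character(scores$v),
    S = as.numeric(scores$S), stringsAsFactors = FALSE))
  out$sign <- ifelse(out$S > tau + epsilon, -1L,
                     ifelse(out$S < tau - epsilon, 1L, 0L))
  attr(out, "tau") <- tau
  attr(out, "epsilon") <- epsilon
  out
}

## Internal: signed-subgraph machinery shared by all path operations.
## Unsigned edges are deleted before any shortest-path search, so path
## lengths may grow relative to the raw network. All network nodes remain
## vertices (isolated is fine).
.signedGraph <- function(network, signs) {
  signs <- signs[signs$sign != 0L, , drop = FALSE]
  nodes <- network@nodes
  iu <- match(signs$u, nodes); iv <- match(signs$v, nodes)
  if (anyNA(iu) || anyNA(iv))
    stop("signed edge endpoint(s) missing from the network", call. = FALSE)
  n <- length(nodes)
  S <- Matrix::sparseMatrix(i = c(iu, iv), j = c(iv, iu),
                            x = rep(as.numeric(signs$sign), 2L),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  S <- methods::as(S, "CsparseMatrix")
  g <- igraph::graph_from_data_frame(
    signs[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = nodes))
  adj <- split(S@i + 1L, rep.int(seq_len(n), diff(S@p)))
  adjFull <- vector("list", n)
  adjFull[as.integer(names(adj))] <- adj
  list(g = g, S = S, adj = adjFull, nodes = nodes)
}

#' Sign product along a path
#'
#' The multiplicative model: a cascade's net effect is the product of its
#' edge signs, so a path is negative iff it contains an odd number of
#' negative edges.
#'
#' @param path Character vector of nodes visited in order.
#' @param signs Sign assignment from [assignEdgeSigns()] (or any data
#'   frame `u, v, sign`).
#' @return `+1` or `-1`.
#' @export
pathSign <- function(path, signs) {
  stopifnot(length(path) >= 2L)
  lut <- stats::setNames(signs$sign, edgeKey(signs$u, signs$v))
  keys <- edgeKey(path[-length(path)], path[-1])
  s <- lut[keys]
  if (anyNA(s) || any(s == 0L))
    stop("path contains an unsigned or unknown edge: ",
         keys[which(is.na(s) | s == 0L)[1]], call. = FALSE)
  prod(as.integer(s))
}

#' Enumerate all shortest paths between two genes
#'
#' Minimum-hop paths on the undirected graph restricted to signed edges
#' (unsigned edges deleted first). Paths are returned in lexicographic
#' order of their node sequences; an unreachable pair yields an empty
#' list.
#'
#' @param network A [BaseNetwork-class].
#' @param signs Sign assignment from [assignEdgeSigns()].
#' @param k,t Source and target genes.
#' @param maxPaths Enumeration cap (default 10000); exceeding it warns
#'   and truncates. Use [negScore()] for exact counting at scale.
#' @return List of character vectors (node sequences).
#' @export
enumerateShortestPaths <- function(network, signs, k, t,
                                   maxPaths = 10000L) {
  sg <- .signedGraph(network, signs)
  stopifnot(k %in% sg$nodes, t %in% sg$nodes)
  if (!is.finite(igraph::distances(sg$g, v = k, to = t)[1, 1]))
    return(list())
  asp <- igraph::all_shortest_paths(sg$g, from = k, to = t)
  vp <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
  paths <- lapply(vp, function(p) igraph::as_ids(p))
  paths <- paths[order(vapply(paths, paste, "", collapse = "\r"))]
  if (length(paths) > maxPaths) {
    warning("path enumeration capped at ", maxPaths, " of ",
            length(paths), call. = FALSE)
    paths <- paths[seq_len(maxPaths)]
  }
  paths
}

## Parity dynamic program on the shortest-path DAG.
## dk, dt: hop distances from source and target on the signed subgraph.
## Returns c(nPaths, nNegative) counting all shortest k-t paths and those
## with an odd number of negative edges.
.parityDP <- function(sg, dk, dt, kIdx, tIdx) {
  L <- dk[tIdx]
  if (!is.finite(L)) return(c(0, 0))
  onDag <- is.finite(dk) & is.finite(dt) & (dk + dt == L)
  dagIdx <- which(onDag)
  ord <- dagIdx[order(dk[dagIdx])]
  n <- length(sg$nodes)
  cntEven <- numeric(n); cntOdd <- numeric(n)
  cntEven[kIdx] <- 1
  for (v in ord) {
    if (v == kIdx) next
    for (u in sg$adj[[v]]) {
      if (!onDag[u] || dk[u] != dk[v] - 1) next
      if (sg$S[u, v] < 0) {
        cntEven[v] <- cntEven[v] + cntOdd[u]
        cntOdd[v] <- cntOdd[v] + cntEven[u]
      } else {
        cntEven[v] <- cntEven[v] + cntEven[u]
        cntOdd[v] <- cntOdd[v] + cntOdd[u]
      }
    }
  }
  c(cntEven[tIdx] + cntOdd[tIdx], cntOdd[tIdx])
}

#' NegScore of a source-target pair
#'
#' The fraction of negative shortest paths among all shortest paths
#' between `k` and `t` on the signed subgraph, computed exactly by a
#' (node, parity) dynamic program over the shortest-path DAG (no path
#' enumeration). Pairs connected by fewer than `minPaths` shortest paths
#' are filtered out (`NULL`).
#'
#' @param network A [BaseNetwork-class].
#' @param signs Sign assignment from [assignEdgeSigns()].
#' @param k,t Source and target genes.
#' @param minPaths Minimum number of shortest paths for the pair to be
#'   scored (default 100, the published noise filter; use 1 to keep all
#'   connected pairs).
#' @return `NULL`, or a list with `source`, `target`, `nPaths`,
#'   `nNegative`, `negScore`.
#' @export
negScore <- function(network, signs, k, t, minPaths = 100L) {
  sg <- .signedGraph(network, signs)
  recs <- .negScorePairs(sg, data.frame(source = k, target = t),
                         minPaths)
  if (!nrow(recs)) return(NULL)
  as.list(recs[1, ])
}

## Batched NegScores with distance caching over unique endpoints.
.negScorePairs <- function(sg, pairs, minPaths) {
  uniq <- unique(c(pairs$source, pairs$target))
  miss <- setdiff(uniq, sg$nodes)
  if (length(miss))
    stop("gene(s) not in the network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  D <- igraph::distances(sg$g, v = uniq)
  D <- D[, sg$nodes, drop = FALSE]   # column order = node order
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$source[i]; t <- pairs$target[i]
    if (k == t) next
    kIdx <- match(k, sg$nodes); tIdx <- match(t, sg$nodes)
    cnt <- .parityDP(sg, D[k, ], D[t, ], kIdx, tIdx)
    if (cnt[1] >= minPaths)
      out[[i]] <- data.frame(source = k, target = t, nPaths = cnt[1],
                             nNegative = cnt[2],
                             negScore = cnt[2] / cnt[1],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(source = character(0), target = character(0),
                      nPaths = numeric(0), nNegative = numeric(0),
                      negScore = numeric(0))
  rownames(out) <- NULL
  out
}

#' NegScores for a table of source-target pairs
#'
#' @param network A [BaseNetwork-class].
#' @param signs Sign assignment from [assignEdgeSigns()].
#' @param pairs data.frame with columns `source`, `target`.
#' @param minPaths Minimum shortest-path count (default 100).
#' @return data.frame `source, target, nPaths, nNegative, negScore`,
#'   one row per pair passing the filter.
#' @export
negScoreTable <- function(network, signs, pairs, minPaths = 100L) {
  sg <- .signedGraph(network, signs)
  pairs <- data.frame(source = as.character(pairs$source),
                      target = as.character(pairs$target),
                      stringsAsFactors = FALSE)
  .negScorePairs(sg, pairs, minPaths)
}

#' Reconstruct one knockout's signature from predicted signs
#'
#' Retrains the classifier without knockout `k`'s feature columns
#' (k-less training), scores the query edges, thresholds them into signs,
#' and scores every (k, target) pair of `k`'s signature by its NegScore.
#' Under the default `inverse` orientation the reported prediction is the
#' probability of *down*-regulation = fraction of positive paths
#' (`1 - NegScore`), because the observed effect follows a knockout and
#' so inverts the cascade sign; `direct` reports NegScore itself.
#' Observed labels are binarized down = 1, up = 0.
#'
#' @param network A [BaseNetwork-class].
#' @param signatures A [KnockoutSignatureSet-class] containing `k`.
#' @param k The knockout to reconstruct.
#' @param trainFeatures [SignalFeatures-class] over the labeled training
#'   edges (full column set, including `k`'s).
#' @param trainLabels Integer signs for the training edges.
#' @param queryFeatures [SignalFeatures-class] over the edges to sign
#'   (typically all network edges).
#' @param tau,epsilon Sign-assignment parameters (defaults 0.5 / 0.01).
#' @param minPaths Minimum shortest-path count per pair (default 100).
#' @param orientation `"inverse"` (default) or `"direct"`.
#' @param seed RNG seed for the retrained forest.
#' @return data.frame `target, nPaths, negScore, predicted, observed`
#'   (empty, with a warning, if no pair passes `minPaths`).
#' @export
reconstructSignature <- function(network, signatures, k, trainFeatures,
                                 trainLabels, queryFeatures, tau = 0.5,
                                 epsilon = 0.01, minPaths = 100L,
                                 orientation = c("inverse", "direct"),
                                 seed = 1L) {
  orientation <- match.arg(orientation)
  .checkKnockout(signatures, k)
  model <- trainSignClassifier(klessColumns(trainFeatures, k),
                               trainLabels, seed = seed)
  scores <- predictScores(model, klessColumns(queryFeatures, k))
  signs <- assignEdgeSigns(scores, tau, epsilon)
  up <- upTargets(signatures, k); dn <- downTargets(signatures, k)
  targets <- intersect(c(up, dn), network@nodes)
  if (!length(targets)) {
    warning("no signature targets of '", k, "' are in the network",
            call. = FALSE)
    return(.emptyReconstruction())
  }
  recs <- negScoreTable(network, signs,
                        data.frame(source = k, target = targets),
                        minPaths)
  if (!nrow(recs)) {
    warning("no (", k, ", target) pair passes the min-paths filter",
            call. = FALSE)
    return(.emptyReconstruction())
  }
  predicted <- if (orientation == "inverse") 1 - recs$negScore
               else recs$negScore
  data.frame(target = recs$target, nPaths = recs$nPaths,
             negScore = recs$negScore, predicted = predicted,
             observed = as.integer(recs$target %in% dn),
             stringsAsFactors = FALSE)
}

.emptyReconstruction <- function() {
  data.frame(target = character(0), nPaths = numeric(0),
             negScore = numeric(0), predicted = numeric(0),
             observed = integer(0))
}

#' Anchor/terminal phenotype reconstruction
#'
#' Scores each terminal gene by aggregating NegScores over its paths to a
#' fixed anchor set (pathway-machinery genes), then evaluates the scores
#' against binary phenotype labels by average precision. Self-pairs
#' (anchor == terminal) are excluded; terminals with no anchor pair
#' passing `minPaths` are dropped with a message.
#'
#' @param network A [BaseNetwork-class].
#' @param signs Sign assignment from [assignEdgeSigns()].
#' @param anchors Non-empty character vector of anchor genes.
#' @param terminals Named integer/logical vector: names are terminal
#'   genes, values the binary phenotype (1 = event class).
#' @param aggregation `"mean"` (default) or `"max"` over anchors.
#' @param minPaths Minimum shortest-path count per (anchor, terminal)
#'   pair (default 100).
#' @return List: `scores` (data.frame `terminal, score, nAnchors,
#'   label`) and `auprc`.
#' @export
reconstructPhenotype <- function(network, signs, anchors, terminals,
                                 aggregation = c("mean", "max"),
                                 minPaths = 100L) {
  aggregation <- match.arg(aggregation)
  anchors <- as.character(anchors)
  if (!length(anchors)) stop("empty anchor set", call. = FALSE)
  term <- names(terminals)
  stopifnot(!is.null(term))
  pairs <- expand.grid(source = anchors, target = term,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  recs <- negScoreTable(network, signs, pairs, minPaths)
  agg <- if (aggregation == "mean") mean else max
  rows <- lapply(term, function(t) {
    r <- recs[recs$target == t, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(terminal = t, score = agg(r$negScore),
               nAnchors = nrow(r),
               label = as.integer(terminals[[t]]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) message(dropped, " terminal(s) without a valid anchor ",
                       "pair excluded")
  scores <- do.call(rbind, rows)
  if (is.null(scores) || !nrow(scores))
    stop("no terminal has a valid anchor pair", call. = FALSE)
  auprc <- if (length(unique(scores$label)) == 2L)
    averagePrecision(scores$score, scores$label == 1L) else NA_real_
  list(scores = scores, auprc = auprc)
}
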
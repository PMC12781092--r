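## Differential-flow features. For a candidate edge e and knockout k the
## feature is the mean, over k's up- (or down-) regulated targets, of the
## drop in propagation score when e is zeroed:
##   F(tk+, e) = A * sum_{t in tk+} [P_k(t) - P_{k,e}(t)] / |tk+|
## giving two features per knockout and 2n columns for n knockouts.
## Negative (repressing) edges are expected to perturb this flow more than
## positive ones, which is the classifier's signal.

#' DeltaProfile: full-minus-defective propagation difference
#'
#' @slot seed The knockout gene the profiles were seeded at.
#' @slot edge The zeroed undirected edge (endpoints).
#' @slot delta Named numeric vector `P_k - P_{d,k}` over all nodes.
#' @export
setClass("DeltaProfile",
  slots = c(seed = "character", edge = "character", delta = "numeric"))

#' Difference between a full and a defective propagation profile
#'
#' @param full [PropagationProfile-class] on the full network.
#' @param defective [PropagationProfile-class] on the defective network,
#'   same seed and node ordering.
#' @return A [DeltaProfile-class].
#' @export
deltaProfile <- function(full, defective) {
  if (!identical(full@seed, defective@seed))
    stop("profiles were seeded at different genes", call. = FALSE)
  if (!identical(names(full@scores), names(defective@scores)))
    stop("profiles are over different node sets", call. = FALSE)
  methods::new("DeltaProfile", seed = full@seed,
               edge = defective@defectiveEdge,
               delta = full@scores - defective@scores)
}

#' Aggregate a delta profile over a target set
#'
#' Mean of the delta over the targets that are present in the network,
#' scaled by `A`; targets absent from the network are excluded from both
#' numerator and denominator. An empty (or fully absent) target set yields
#' 0 with a message.
#'
#' @param delta A [DeltaProfile-class] (or named numeric vector).
#' @param targets Character vector of target genes (may be empty).
#' @param A Positive scaling constant (default 1; any positive value is
#'   absorbed by the tree-ensemble classifier).
#' @return A single numeric feature value.
#' @export
edgeFeature <- function(delta, targets, A = 1) {
  assertScalarNumeric(A, "A", 0, Inf, strict = TRUE)
  d <- if (methods::is(delta, "DeltaProfile")) delta@delta else delta
  present <- targets[targets %in% names(d)]
  if (!length(present)) {
    message("empty target set: feature set to 0")
    return(0)
  }
  A * sum(d[present]) / length(present)
}

#' Build the differential-flow feature matrix
#'
#' For each knockout the full-network profile is computed once (unless
#' `cache = FALSE`, which recomputes it per edge with the identical
#' routine); for each candidate edge the defective operator is normalized
#' once and all knockouts are propagated on it in a single batch. Column
#' order is `k1+, k1-, k2+, k2-, ...` in the signature set's knockout
#' order.
#'
#' @param network A [BaseNetwork-class].
#' @param signatures A [KnockoutSignatureSet-class]; every knockout must
#'   be a network node.
#' @param edges Candidate edges: data.frame with columns `u`, `v`; each
#'   must exist in the network.
#' @param config A [propagationConfig()].
#' @param A Positive feature scaling constant (default 1).
#' @param cache Reuse full-network profiles across edges (default TRUE;
#'   FALSE recomputes them per edge, bit-identically).
#' @return A [SignalFeatures-class] of shape `|edges| x 2n`.
#' @export
buildFeatureMatrix <- function(network, signatures, edges,
                               config = propagationConfig(), A = 1,
                               cache = TRUE) {
  config <- .asConfig(config)
  assertScalarNumeric(A, "A", 0, Inf, strict = TRUE)
  ks <- knockouts(signatures)
  if (!length(ks)) stop("no knockouts in the signature set", call. = FALSE)
  seedIdx <- match(ks, network@nodes)
  if (anyNA(seedIdx))
    stop("knockout gene(s) not in the network: ",
         paste(ks[is.na(seedIdx)], collapse = ", "), call. = FALSE)
  edges <- canonicalizeEdges(data.frame(u = as.character(edges$u),
                                        v = as.character(edges$v),
                                        stringsAsFactors = FALSE))
  for (i in seq_len(nrow(edges)))
    if (!hasEdge(network, edges$u[i], edges$v[i]))
      stop(sprintf("candidate edge {%s, %s} is absent from the network",
                   edges$u[i], edges$v[i]), call. = FALSE)

  ## per-knockout target index lists, restricted to network nodes but
  ## preserving signature order (matching edgeFeature semantics)
  restrict <- function(tt) {
    tt <- tt[tt %in% network@nodes]
    match(tt, network@nodes)
  }
  upIdx <- lapply(ks, function(k) restrict(upTargets(signatures, k)))
  dnIdx <- lapply(ks, function(k) restrict(downTargets(signatures, k)))
  nEmpty <- sum(lengths(upIdx) == 0) + sum(lengths(dnIdx) == 0)
  if (nEmpty > 0)
    message(nEmpty, " empty target set(s): those features are 0")

  W <- normalizeAdjacency(network)
  Pfull <- .propagateMatrix(W, seedIdx, config)$scores
  nk <- length(ks)
  F <- matrix(0, nrow(edges), 2L * nk)
  for (i in seq_len(nrow(edges))) {
    e <- c(edges$u[i], edges$v[i])
    Wd <- normalizeAdjacency(network, drop = e)
    Pd <- .propagateMatrix(Wd, seedIdx, config)$scores
    Pf <- if (cache) Pfull else .propagateMatrix(W, seedIdx, config)$scores
    D <- Pf - Pd
    for (j in seq_len(nk)) {
      if (length(upIdx[[j]]))
        F[i, 2L * j - 1L] <- A * sum(D[upIdx[[j]], j]) / length(upIdx[[j]])
      if (length(dnIdx[[j]]))
        F[i, 2L * j] <- A * sum(D[dnIdx[[j]], j]) / length(dnIdx[[j]])
    }
  }
  rownames(F) <- edgeKey(edges$u, edges$v)
  colnames(F) <- as.vector(rbind(paste0(ks, "+"), paste0(ks, "-")))
  methods::new("SignalFeatures", values = F, edges = edges,
               knockouts = ks, scalingA = A)
}

#' Drop the feature columns of one knockout (k-less training)
#'
#' Removes exactly the `(k, +)` and `(k, -)` columns, leaving rows and all
#' other columns untouched. Used before reconstructing knockout `k`'s own
#' signature so the classifier never sees features derived from it. For
#' the stricter variant that also hides `k`'s signature genes from other
#' knockouts' target sets, rebuild the matrix after
#' [maskSignatureGenes()].
#'
#' @param features A [SignalFeatures-class].
#' @param k A knockout present in the matrix.
#' @return A [SignalFeatures-class] with `2(n-1)` columns.
#' @export
klessColumns <- function(features, k) {
  pos <- match(k, features@knockouts)
  if (is.na(pos))
    stop("'", k, "' is not a knockout of this feature matrix",
         call. = FALSE)
  keep <- setdiff(seq_len(ncol(features@values)),
                  c(2L * pos - 1L, 2L * pos))
  methods::new("SignalFeatures",
               values = features@values[, keep, drop = FALSE],
               edges = features@edges,
               knockouts = features@knockouts[-pos],
               scalingA = features@scalingA)
}

#' Mask genes out of every signature's target sets
#'
#' Strict k-less mode: removes the given genes (typically knockout `k`
#' plus its whole signature) from the up/down target sets of *all*
#' knockouts, and drops knockouts named in `genes` entirely. Rebuilding
#' the feature matrix on the result implements the strict exclusion.
#'
#' @param signatures A [KnockoutSignatureSet-class].
#' @param genes Character vector of genes to hide.
#' @return A new [KnockoutSignatureSet-class].
#' @export
maskSignatureGenes <- function(signatures, genes) {
  sigs <- signatures@signatures
  sigs <- sigs[!names(sigs) %in% genes]
  sigs <- lapply(sigs, function(s)
    list(up = setdiff(s$up, genes), down = setdiff(s$down, genes)))
  methods::new("KnockoutSignatureSet", signatures = sigs)
}

#' Write a feature matrix as TSV
#'
#' First column `edge` holds the canonical `"u|v"` key; remaining columns
#' are the `k+`/`k-` feature columns.
#'
#' @param features A [SignalFeatures-class].
#' @param path Output path.
#' @export
writeFeatureMatrix <- function(features, path) {
  df <- data.frame(edge = rownames(features@values),
                   features@values, check.names = FALSE)
  writeTsv(df, path,
           header = paste(c("edge", colnames(features@values)),
                          collapse = "\t"))
}
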
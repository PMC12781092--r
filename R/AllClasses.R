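#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' BaseNetwork: the propagation substrate
#'
#' A weighted, undirected PPI network stored as a symmetric sparse adjacency
#' matrix over an ordered node set. Every undirected edge \{u, v\} is
#' represented by the two symmetric entries (u, v) and (v, u), so that the
#' directed edge count equals twice the undirected edge count; all
#' propagation operates on this doubled-directed view.
#'
#' @slot nodes Ordered character vector of gene identifiers; defines the row
#'   index used by every propagation profile.
#' @slot adjacency Symmetric `dgCMatrix` of non-negative edge weights with
#'   zero diagonal; `dimnames` equal `nodes`.
#'
#' @seealso [assembleBaseNetwork()], [networkEdges()], [propagate()]
#' @export
setClass("BaseNetwork",
  slots = c(nodes = "character", adjacency = "dgCMatrix"))

setValidity("BaseNetwork", function(object) {
  n <- length(object@nodes)
  A <- object@adjacency
  msgs <- character(0)
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicated node identifiers")
  if (nrow(A) != n || ncol(A) != n)
    msgs <- c(msgs, "adjacency dimensions do not match node count")
  else {
    if (!identical(rownames(A), object@nodes) ||
        !identical(colnames(A), object@nodes))
      msgs <- c(msgs, "adjacency dimnames must equal the node vector")
    if (length(A@x) && any(A@x < 0))
      msgs <- c(msgs, "negative edge weights")
    if (n > 0 && any(Matrix::diag(A) != 0))
      msgs <- c(msgs, "self-loops are not permitted")
    if (!Matrix::isSymmetric(A, tol = 0))
      msgs <- c(msgs, "adjacency must be symmetric (edge doubling invariant)")
  }
  if (length(msgs)) msgs else TRUE
})

#' KnockoutSignatureSet: cause-effect supervision
#'
#' Per-knockout disjoint sets of up- and down-regulated target genes, the
#' transcriptional signature observed after deleting the knockout gene.
#'
#' @slot signatures Named list; element `k` is `list(up = <character>,
#'   down = <character>)` with `up` and `down` disjoint and excluding `k`.
#'
#' @seealso [readKnockoutSignatures()], [simulateKnockoutSignatures()]
#' @export
setClass("KnockoutSignatureSet", slots = c(signatures = "list"))

setValidity("KnockoutSignatureSet", function(object) {
  sig <- object@signatures
  if (length(sig) && is.null(names(sig)))
    return("signatures must be a named list keyed by knockout gene")
  for (k in names(sig)) {
    s <- sig[[k]]
    if (!is.list(s) || !all(c("up", "down") %in% names(s)))
      return(sprintf("signature '%s' lacks up/down sets", k))
    if (length(intersect(s$up, s$down)))
      return(sprintf("up and down targets of '%s' overlap", k))
    if (k %in% c(s$up, s$down))
      return(sprintf("knockout '%s' occurs among its own targets", k))
  }
  TRUE
})

#' PropagationProfile: one random-walk-with-restart solution
#'
#' The fixed point of \eqn{p \leftarrow \alpha W p + (1-\alpha) e_{seed}}
#' on the full network or on a defective network with one edge zeroed.
#'
#' @slot seed Seed gene (the knockout).
#' @slot scores Named non-negative numeric vector over all network nodes.
#' @slot defectiveEdge `character(0)` for the full network, otherwise the
#'   two endpoints of the zeroed edge.
#' @slot converged Whether the max-norm change dropped below `tol`.
#' @slot iterations Number of update steps performed.
#' @export
setClass("PropagationProfile",
  slots = c(seed = "character", scores = "numeric",
            defectiveEdge = "character", converged = "logical",
            iterations = "integer"))

setValidity("PropagationProfile", function(object) {
  if (length(object@seed) != 1L) return("seed must be a single gene")
  if (!length(object@defectiveEdge) %in% c(0L, 2L))
    return("defectiveEdge must be empty or a pair")
  if (any(!is.finite(object@scores)) || any(object@scores < -1e-12))
    return("scores must be finite and non-negative")
  TRUE
})

#' SignalFeatures: the differential-flow feature matrix
#'
#' Rows are candidate undirected edges; columns come in (knockout, polarity)
#' pairs, `2n` columns for `n` knockouts, ordered `k1+, k1-, k2+, k2-, ...`.
#' Entry (e, (k, +)) is `A * mean over t in up-targets(k) of
#' [P_k(t) - P_{k,e}(t)]`, the drop in propagation score at the targets when
#' edge e is zeroed.
#'
#' @slot values Numeric matrix, `|edges| x 2n`; rownames are canonical edge
#'   keys `"u|v"`, colnames `"k+"`/`"k-"`.
#' @slot edges data.frame with columns `u`, `v` (canonical order, u < v).
#' @slot knockouts Character vector giving column-pair order.
#' @slot scalingA The positive scaling constant applied to every feature.
#' @export
setClass("SignalFeatures",
  slots = c(values = "matrix", edges = "data.frame",
            knockouts = "character", scalingA = "numeric"))

setValidity("SignalFeatures", function(object) {
  if (ncol(object@values) != 2L * length(object@knockouts))
    return("column count must be 2 x number of knockouts")
  if (nrow(object@values) != nrow(object@edges))
    return("row count must match the edge table")
  if (any(!is.finite(object@values)))
    return("all feature values must be finite")
  if (length(object@scalingA) != 1L || object@scalingA <= 0)
    return("scalingA must be a single positive number")
  TRUE
})

#' SyntheticWorld: a planted-sign benchmark instance
#'
#' A generated signed network together with knockout signatures that obey
#' the multiplicative path-sign model (observed target response = inverse of
#' the majority sign product over shortest knockout-target paths, flipped
#' with a stated noise probability).
#'
#' @slot network The [BaseNetwork-class] substrate.
#' @slot trueSigns data.frame `u, v, sign` with planted signs in \{-1, +1\}.
#' @slot signatures The emitted [KnockoutSignatureSet-class].
#' @slot truth Audit table: one row per (knockout, target) with the cascade
#'   sign, tie flag, noise-flip flag and emitted label.
#' @slot params Generator parameter record.
#' @slot seed Integer seed the world is a pure function of.
#' @export
setClass("SyntheticWorld",
  slots = c(network = "BaseNetwork", trueSigns = "data.frame",
            signatures = "KnockoutSignatureSet", truth = "data.frame",
            params = "list", seed = "integer"))

## ---- generics ------------------------------------------------------------

#' @rdname BaseNetwork-class
#' @param x,object A `BaseNetwork`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname BaseNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname KnockoutSignatureSet-class
#' @param x,object A `KnockoutSignatureSet`.
#' @export
setGeneric("knockouts", function(x) standardGeneric("knockouts"))

#' @rdname KnockoutSignatureSet-class
#' @param k Knockout gene identifier.
#' @export
setGeneric("upTargets", function(x, k) standardGeneric("upTargets"))

#' @rdname KnockoutSignatureSet-class
#' @export
setGeneric("downTargets", function(x, k) standardGeneric("downTargets"))

#' @rdname SignalFeatures-class
#' @param x,object A `SignalFeatures`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname SignalFeatures-class
#' @export
setGeneric("featureEdges", function(x) standardGeneric("featureEdges"))

## ---- methods -------------------------------------------------------------

#' @rdname BaseNetwork-class
#' @export
setMethod("networkNodes", "BaseNetwork", function(x) x@nodes)

#' @describeIn BaseNetwork-class Undirected edge table (`u`, `v`, `weight`)
#'   with canonically ordered endpoints, sorted by edge key.
#' @export
setMethod("networkEdges", "BaseNetwork", function(x) {
  A <- methods::as(Matrix::triu(x@adjacency), "TsparseMatrix")
  u <- x@nodes[A@i + 1L]
  v <- x@nodes[A@j + 1L]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  out <- data.frame(u = u, v = v, weight = A@x, stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname BaseNetwork-class
#' @export
setMethod("length", "BaseNetwork", function(x) length(x@nodes))

setMethod("show", "BaseNetwork", function(object) {
  ne <- Matrix::nnzero(object@adjacency)
  cat(sprintf(
    "BaseNetwork: %d nodes, %d undirected edges (%d directed)\n",
    length(object@nodes), ne %/% 2L, ne))
})

#' @rdname KnockoutSignatureSet-class
#' @export
setMethod("knockouts", "KnockoutSignatureSet",
          function(x) names(x@signatures))

#' @rdname KnockoutSignatureSet-class
#' @export
setMethod("upTargets", "KnockoutSignatureSet", function(x, k) {
  .checkKnockout(x, k); x@signatures[[k]]$up
})

#' @rdname KnockoutSignatureSet-class
#' @export
setMethod("downTargets", "KnockoutSignatureSet", function(x, k) {
  .checkKnockout(x, k); x@signatures[[k]]$down
})

#' @rdname KnockoutSignatureSet-class
#' @export
setMethod("length", "KnockoutSignatureSet",
          function(x) length(x@signatures))

setMethod("show", "KnockoutSignatureSet", function(object) {
  nt <- vapply(object@signatures,
               function(s) length(s$up) + length(s$down), integer(1))
  cat(sprintf(
    "KnockoutSignatureSet: %d knockouts, %d (knockout, target) pairs\n",
    length(object@signatures), sum(nt)))
})

.checkKnockout <- function(x, k) {
  if (!k %in% names(x@signatures))
    stop("unknown knockout gene: ", k, call. = FALSE)
  invisible(TRUE)
}

#' @rdname SignalFeatures-class
#' @export
setMethod("featureValues", "SignalFeatures", function(x) x@values)

#' @rdname SignalFeatures-class
#' @export
setMethod("featureEdges", "SignalFeatures", function(x) x@edges)

setMethod("show", "SignalFeatures", function(object) {
  cat(sprintf(
    "SignalFeatures: %d edges x %d columns (%d knockouts x {+,-}), A = %g\n",
    nrow(object@values), ncol(object@values),
    length(object@knockouts), object@scalingA))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld (seed %d): %d nodes, %d edges (%.1f%% negative), %d knockouts\n",
    object@seed, length(object@network@nodes), nrow(object@trueSigns),
    100 * mean(object@trueSigns$sign < 0), length(object@signatures)))
})
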
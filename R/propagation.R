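## Random walk with restart on the symmetric-normalized adjacency,
## on the full network and on "defective" networks with one edge zeroed.
##
## The update is p <- alpha * W p + (1 - alpha) * e_seed iterated from
## p = e_seed, with W = D^{-1/2} A D^{-1/2}. Since the spectral norm of W
## is at most 1 and alpha < 1, the iteration contracts geometrically to
## the unique fixed point (1 - alpha) (I - alpha W)^{-1} e_seed.

#' Propagation parameters
#'
#' @param alpha Restart balance in (0, 1): weight on the network term of
#'   the update (default 0.6, the canonical PPI-propagation choice).
#' @param tol Max-norm convergence threshold (default 1e-8).
#' @param maxIter Iteration cap (default 1000; with alpha = 0.6 the
#'   contraction reaches 1e-8 in about 40 steps).
#' @return A validated list of class `PropagationConfig`.
#' @export
propagationConfig <- function(alpha = 0.6, tol = 1e-8, maxIter = 1000L) {
  assertScalarNumeric(alpha, "alpha", 0, 1, strict = TRUE)
  assertScalarNumeric(tol, "tol", 0, Inf, strict = TRUE)
  assertScalarNumeric(maxIter, "maxIter", 1, Inf)
  structure(list(alpha = alpha, tol = tol, maxIter = as.integer(maxIter)),
            class = "PropagationConfig")
}

.asConfig <- function(config) {
  if (inherits(config, "PropagationConfig")) return(config)
  do.call(propagationConfig, as.list(config))
}

#' Symmetric-normalized transition operator
#'
#' Computes `W = D^{-1/2} A D^{-1/2}` where `A` is the symmetric weighted
#' adjacency and `D` the diagonal strength matrix. Zero-degree nodes get a
#' normalization factor of 0, so their rows/columns are all zero. When
#' `drop` names an existing undirected edge, both directed copies are
#' zeroed in `A` *before* degrees are computed and the matrix is
#' normalized (the defective-network operator).
#'
#' @param network A [BaseNetwork-class].
#' @param drop Optional `c(u, v)`: undirected edge to zero out.
#' @return Sparse symmetric `dgCMatrix` with node dimnames.
#' @export
normalizeAdjacency <- function(network, drop = NULL) {
  stopifnot(methods::is(network, "BaseNetwork"))
  A <- network@adjacency
  if (!is.null(drop)) {
    drop <- as.character(drop)
    if (length(drop) != 2L)
      stop("'drop' must be a pair of endpoints", call. = FALSE)
    if (!hasEdge(network, drop[1], drop[2]))
      stop(sprintf("edge {%s, %s} is absent from the network",
                   drop[1], drop[2]), call. = FALSE)
    A[drop[1], drop[2]] <- 0
    A[drop[2], drop[1]] <- 0
    A <- Matrix::drop0(A)
  }
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(network@nodes, network@nodes)
  W
}

## Batched power iteration. One column per seed; each column is frozen the
## moment its own max-norm change drops below tol, so a column's trajectory
## is identical whether it is iterated alone or inside a batch.
.propagateMatrix <- function(W, seedIdx, config) {
  n <- nrow(W)
  m <- length(seedIdx)
  E <- matrix(0, n, m)
  E[cbind(seedIdx, seq_len(m))] <- 1
  P <- E
  restart <- (1 - config$alpha) * E
  active <- rep(TRUE, m)
  iters <- integer(m)
  converged <- logical(m)
  it <- 0L
  while (any(active) && it < config$maxIter) {
    it <- it + 1L
    ia <- which(active)
    Pa <- P[, ia, drop = FALSE]
    Pnew <- config$alpha * as.matrix(W %*% Pa) +
      restart[, ia, drop = FALSE]
    delta <- vapply(seq_along(ia),
                    function(j) max(abs(Pnew[, j] - Pa[, j])), numeric(1))
    P[, ia] <- Pnew
    iters[ia] <- it
    done <- delta < config$tol
    converged[ia[done]] <- TRUE
    active[ia[done]] <- FALSE
  }
  list(scores = P, iterations = iters, converged = converged)
}

#' Propagate from a knockout seed
#'
#' Iterates `p <- alpha W p + (1 - alpha) e_seed` from `p = e_seed` until
#' the max-norm change falls below `tol` (or `maxIter` is hit). Scores of
#' nodes outside the seed's connected component are exactly zero; an
#' isolated seed yields `(1 - alpha) e_seed`.
#'
#' @param network A [BaseNetwork-class].
#' @param seed Seed gene; must be a network node.
#' @param config A [propagationConfig()].
#' @param W Optional precomputed operator from [normalizeAdjacency()]
#'   (computed on the fly when `NULL`).
#' @return A [PropagationProfile-class].
#' @examples
#' net <- assembleBaseNetwork(data.frame(u = "a", v = "b"))
#' propagate(net, "a")@scores
#' @export
propagate <- function(network, seed, config = propagationConfig(),
                      W = NULL) {
  config <- .asConfig(config)
  idx <- match(seed, network@nodes)
  if (is.na(idx))
    stop("seed gene '", seed, "' is not in the network", call. = FALSE)
  if (is.null(W)) W <- normalizeAdjacency(network)
  res <- .propagateMatrix(W, idx, config)
  scores <- res$scores[, 1]
  names(scores) <- network@nodes
  methods::new("PropagationProfile", seed = seed, scores = scores,
               defectiveEdge = character(0),
               converged = res$converged[1],
               iterations = res$iterations[1])
}

#' Propagate on a defective network
#'
#' Identical to [propagate()] on a network where both directed copies of
#' `edge` have weight 0 and degrees are recomputed before normalization.
#' The original network is unmodified.
#'
#' @inheritParams propagate
#' @param edge `c(u, v)`: an existing undirected edge.
#' @return A [PropagationProfile-class] with `defectiveEdge` set.
#' @export
defectivePropagate <- function(network, seed, edge,
                               config = propagationConfig()) {
  config <- .asConfig(config)
  Wd <- normalizeAdjacency(network, drop = edge)
  prof <- propagate(network, seed, config, W = Wd)
  prof@defectiveEdge <- as.character(edge)
  prof
}

#' Batch propagation over seeds and defective edges
#'
#' Computes one profile per (seed, condition) pair where the conditions are
#' the full network plus each requested defective edge. Full-network
#' profiles are computed once per seed; for each defective edge the
#' operator is normalized once and all seeds are propagated on it as a
#' batch. Output order is deterministic: all full profiles in seed order,
#' then for each defective edge (in the given order) all seeds.
#'
#' @inheritParams propagate
#' @param seeds Character vector of seed genes.
#' @param defectiveEdges Optional list of `c(u, v)` pairs (or a two-column
#'   data.frame).
#' @return Named list of [PropagationProfile-class]; full profiles are
#'   named by seed, defective ones `"seed@u|v"`.
#' @export
propagateAll <- function(network, seeds, config = propagationConfig(),
                         defectiveEdges = NULL) {
  config <- .asConfig(config)
  seeds <- as.character(seeds)
  idx <- match(seeds, network@nodes)
  if (anyNA(idx))
    stop("seed gene(s) not in the network: ",
         paste(seeds[is.na(idx)], collapse = ", "), call. = FALSE)
  if (is.data.frame(defectiveEdges))
    defectiveEdges <- lapply(seq_len(nrow(defectiveEdges)), function(i)
      c(defectiveEdges[[1]][i], defectiveEdges[[2]][i]))
  out <- list()
  wrap <- function(res, j, seed, dedge) {
    scores <- res$scores[, j]
    names(scores) <- network@nodes
    methods::new("PropagationProfile", seed = seed, scores = scores,
                 defectiveEdge = dedge, converged = res$converged[j],
                 iterations = res$iterations[j])
  }
  W <- normalizeAdjacency(network)
  full <- .propagateMatrix(W, idx, config)
  for (j in seq_along(seeds))
    out[[seeds[j]]] <- wrap(full, j, seeds[j], character(0))
  for (e in defectiveEdges) {
    e <- as.character(e)
    Wd <- normalizeAdjacency(network, drop = e)
    res <- .propagateMatrix(Wd, idx, config)
    for (j in seq_along(seeds))
      out[[paste0(seeds[j], "@", edgeKey(e[1], e[2]))]] <-
        wrap(res, j, seeds[j], e)
  }
  out
}
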
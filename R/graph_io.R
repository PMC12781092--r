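## Readers/writers for the tabular inputs and assembly of the base network.
## All files are tab-delimited UTF-8 with an optional single header line
## starting with "#". Gene identifiers are opaque strings (inputs are
## assumed pre-mapped to a single identifier namespace).

#' Read an undirected PPI edge list
#'
#' Reads a TSV with columns `u`, `v` and an optional numeric `weight`
#' (default 1). Edges are canonicalized (`min(u,v), max(u,v)`) and
#' deduplicated; duplicates keep the maximum weight so the result is
#' independent of row order. Self-loops are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @param header Ignored content-wise: a first line starting `#` is always
#'   skipped; set `TRUE` to also skip a headerless first line. Default
#'   `FALSE`.
#' @return data.frame with columns `u`, `v`, `weight`, one row per
#'   undirected edge, sorted by edge key.
#' @examples
#' f <- tempfile(); writeLines(c("A\tB", "B\tA", "A\tA"), f)
#' readEdgeList(f)   # one edge {A,B}; the self-loop is dropped
#' @export
readEdgeList <- function(path, header = FALSE) {
  tsv <- readTsvLines(path)
  if (header && length(tsv$fields)) {
    tsv$fields <- tsv$fields[-1]
    tsv$lineno <- tsv$lineno[-1]
  }
  if (!length(tsv$fields)) {
    warning("empty edge list: ", path, call. = FALSE)
    return(data.frame(u = character(0), v = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  nf <- lengths(tsv$fields)
  bad <- which(nf < 2L)
  if (length(bad))
    stop(sprintf("malformed edge row at line %d of %s (need >= 2 columns)",
                 tsv$lineno[bad[1]], path), call. = FALSE)
  u <- vapply(tsv$fields, `[[`, character(1), 1L)
  v <- vapply(tsv$fields, `[[`, character(1), 2L)
  w <- rep(1, length(u))
  hasW <- nf >= 3L
  if (any(hasW)) {
    wRaw <- vapply(tsv$fields[hasW], `[[`, character(1), 3L)
    wNum <- suppressWarnings(as.numeric(wRaw))
    if (anyNA(wNum))
      stop(sprintf("non-numeric weight at line %d of %s",
                   tsv$lineno[hasW][which(is.na(wNum))[1]], path),
           call. = FALSE)
    if (any(wNum < 0))
      stop(sprintf("negative weight at line %d of %s",
                   tsv$lineno[hasW][which(wNum < 0)[1]], path),
           call. = FALSE)
    w[hasW] <- wNum
  }
  df <- canonicalizeEdges(
    data.frame(u = u, v = v, weight = w, stringsAsFactors = FALSE))
  loops <- df$u == df$v
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from ", path)
    df <- df[!loops, , drop = FALSE]
  }
  ## duplicates keep the maximum weight (order-independent)
  key <- edgeKey(df$u, df$v)
  if (anyDuplicated(key)) {
    wMax <- tapply(df$weight, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$weight <- as.numeric(wMax[edgeKey(df$u, df$v)])
  }
  df <- df[order(df$u, df$v), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an undirected edge list as TSV
#'
#' @param edges data.frame with columns `u`, `v` and optionally `weight`.
#' @param path Output path.
#' @export
writeEdgeList <- function(edges, path) {
  if (is.null(edges$weight)) edges$weight <- 1
  writeTsv(canonicalizeEdges(edges[, c("u", "v", "weight")]), path,
           header = "u\tv\tweight")
}

#' Read signed training interactions
#'
#' TSV columns: `u`, `v`, `sign` and optionally `dataset_label` and
#' `enzyme_id` (the kinase/phosphatase/ligase mediating the edge; when
#' present it must equal one of the endpoints). Accepted sign encodings:
#' `+`, `-`, `+1`, `-1`, `1`, `pos`, `neg` (and unicode minus). Duplicate
#' pairs with conflicting signs are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `u`, `v`, `sign` (integer -1/+1),
#'   `dataset`, `enzyme` (NA when absent).
#' @export
readSignedTable <- function(path) {
  tsv <- readTsvLines(path)
  empty <- data.frame(u = character(0), v = character(0),
                      sign = integer(0), dataset = character(0),
                      enzyme = character(0), stringsAsFactors = FALSE)
  if (!length(tsv$fields)) {
    warning("empty signed-interaction table: ", path, call. = FALSE)
    return(empty)
  }
  nf <- lengths(tsv$fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("malformed signed row at line %d of %s (need >= 3 columns)",
                 tsv$lineno[bad[1]], path), call. = FALSE)
  getcol <- function(i) vapply(tsv$fields, function(f)
    if (length(f) >= i && nzchar(f[[i]])) f[[i]] else NA_character_,
    character(1))
  u <- getcol(1L); v <- getcol(2L)
  sgn <- normalizeSign(getcol(3L), tsv$lineno, path)
  dataset <- getcol(4L); enzyme <- getcol(5L)
  okEnz <- is.na(enzyme) | enzyme == u | enzyme == v
  if (any(!okEnz))
    stop(sprintf("enzyme_id not an endpoint at line %d of %s",
                 tsv$lineno[which(!okEnz)[1]], path), call. = FALSE)
  df <- data.frame(u = u, v = v, sign = sgn, dataset = dataset,
                   enzyme = enzyme, stringsAsFactors = FALSE)
  key <- edgeKey(df$u, df$v)
  conflict <- unique(key[key %in% key[duplicated(key)] &
                           ave(df$sign, key, FUN = function(s)
                             length(unique(s))) > 1])
  if (length(conflict)) {
    warning(length(conflict),
            " signed pair(s) with conflicting signs dropped", call. = FALSE)
    df <- df[!key %in% conflict, , drop = FALSE]
    key <- edgeKey(df$u, df$v)
  }
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Normalize a vector of sign tokens to integer {-1, +1}.
normalizeSign <- function(tok, lineno = seq_along(tok), path = "<input>") {
  t <- trimws(tok)
  t <- gsub("−", "-", t)  # unicode minus
  pos <- t %in% c("+", "+1", "1", "pos", "positive", "up")
  neg <- t %in% c("-", "-1", "neg", "negative", "down")
  if (any(!(pos | neg)))
    stop(sprintf("unrecognized sign token '%s' at line %d of %s",
                 t[which(!(pos | neg))[1]],
                 lineno[which(!(pos | neg))[1]], path), call. = FALSE)
  ifelse(pos, 1L, -1L)
}

#' Write a signed interaction table as TSV
#'
#' @param signed data.frame as returned by [readSignedTable()].
#' @param path Output path.
#' @export
writeSignedTable <- function(signed, path) {
  out <- data.frame(u = signed$u, v = signed$v,
                    sign = ifelse(signed$sign > 0, "+", "-"),
                    dataset = ifelse(is.na(signed$dataset), "",
                                     signed$dataset),
                    enzyme = ifelse(is.na(signed$enzyme), "",
                                    signed$enzyme))
  writeTsv(out, path, header = "u\tv\tsign\tdataset\tenzyme")
}

#' Read knockout signatures (long format)
#'
#' TSV columns: `knockout`, `target`, `response` in `up`/`down`/`+1`/`-1`.
#' A (knockout, target) pair reported with both responses is dropped with a
#' warning (inconsistent measurement); a target equal to its knockout is
#' dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A [KnockoutSignatureSet-class].
#' @export
readKnockoutSignatures <- function(path) {
  tsv <- readTsvLines(path)
  if (!length(tsv$fields)) {
    warning("empty knockout-signature table: ", path, call. = FALSE)
    return(methods::new("KnockoutSignatureSet", signatures = list()))
  }
  nf <- lengths(tsv$fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("malformed signature row at line %d of %s",
                 tsv$lineno[bad[1]], path), call. = FALSE)
  k <- vapply(tsv$fields, `[[`, character(1), 1L)
  t <- vapply(tsv$fields, `[[`, character(1), 2L)
  r <- normalizeSign(vapply(tsv$fields, `[[`, character(1), 3L),
                     tsv$lineno, path)
  allK <- unique(k)
  self <- k == t
  if (any(self)) {
    warning(sum(self), " row(s) with target equal to knockout dropped",
            call. = FALSE)
    k <- k[!self]; t <- t[!self]; r <- r[!self]
  }
  pair <- paste(k, t, sep = "\r")
  conflicted <- unique(pair[ave(r, pair, FUN = function(s)
    length(unique(s))) > 1])
  if (length(conflicted)) {
    warning(length(conflicted),
            " (knockout, target) pair(s) with both responses dropped",
            call. = FALSE)
    keep <- !pair %in% conflicted
    k <- k[keep]; t <- t[keep]; r <- r[keep]; pair <- pair[keep]
  }
  keep <- !duplicated(pair)
  k <- k[keep]; t <- t[keep]; r <- r[keep]
  sigs <- list()
  for (kk in allK) {   # knockouts whose pairs all dropped keep empty sets
    sel <- k == kk
    sigs[[kk]] <- list(up = t[sel & r > 0], down = t[sel & r < 0])
  }
  methods::new("KnockoutSignatureSet", signatures = sigs)
}

#' Write knockout signatures in long TSV format
#'
#' @param signatures A [KnockoutSignatureSet-class].
#' @param path Output path.
#' @export
writeKnockoutSignatures <- function(signatures, path) {
  rows <- do.call(rbind, lapply(knockouts(signatures), function(k) {
    up <- upTargets(signatures, k); dn <- downTargets(signatures, k)
    data.frame(knockout = k,
               target = c(up, dn),
               response = c(rep("up", length(up)), rep("down", length(dn))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(knockout = character(0), target = character(0),
                       response = character(0))
  writeTsv(rows, path, header = "knockout\ttarget\tresponse")
}

#' Assemble the doubled-directed base network
#'
#' Builds the propagation substrate from the undirected PPI edge list,
#' integrating genes (and edges) from the signed training set and from the
#' knockout signatures: every gene appearing in either becomes a node, and
#' every signed interaction absent from the PPI list is inserted with
#' weight 1. Each undirected edge is stored as two symmetric directed
#' entries; isolated nodes are permitted.
#'
#' @param interactions data.frame `u, v[, weight]` as from
#'   [readEdgeList()].
#' @param signed Optional data.frame as from [readSignedTable()].
#' @param signatures Optional [KnockoutSignatureSet-class].
#' @return A [BaseNetwork-class].
#' @examples
#' edges <- data.frame(u = c("A", "B"), v = c("B", "C"))
#' net <- assembleBaseNetwork(edges)
#' networkEdges(net)
#' @export
assembleBaseNetwork <- function(interactions, signed = NULL,
                                signatures = NULL) {
  if (is.null(interactions$weight)) interactions$weight <- 1
  df <- canonicalizeEdges(
    data.frame(u = as.character(interactions$u),
               v = as.character(interactions$v),
               weight = as.numeric(interactions$weight),
               stringsAsFactors = FALSE))
  df <- df[df$u != df$v, , drop = FALSE]
  extraGenes <- character(0)
  if (!is.null(signed) && nrow(signed)) {
    se <- canonicalizeEdges(data.frame(
      u = as.character(signed$u), v = as.character(signed$v),
      weight = 1, stringsAsFactors = FALSE))
    se <- se[se$u != se$v, , drop = FALSE]
    newE <- !edgeKey(se$u, se$v) %in% edgeKey(df$u, df$v)
    df <- rbind(df, se[newE, , drop = FALSE])
    extraGenes <- c(extraGenes, se$u, se$v)
  }
  if (!is.null(signatures)) {
    for (k in knockouts(signatures))
      extraGenes <- c(extraGenes, k, upTargets(signatures, k),
                      downTargets(signatures, k))
  }
  ## dedupe (max weight) then build the symmetric sparse adjacency
  key <- edgeKey(df$u, df$v)
  if (anyDuplicated(key)) {
    wMax <- tapply(df$weight, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$weight <- as.numeric(wMax[edgeKey(df$u, df$v)])
  }
  nodes <- sort(unique(c(df$u, df$v, extraGenes)))
  idx <- seq_along(nodes); names(idx) <- nodes
  n <- length(nodes)
  A <- Matrix::sparseMatrix(
    i = c(idx[df$u], idx[df$v]),
    j = c(idx[df$v], idx[df$u]),
    x = rep(df$weight, 2L),
    dims = c(n, n), dimnames = list(nodes, nodes))
  methods::new("BaseNetwork", nodes = nodes,
               adjacency = methods::as(A, "CsparseMatrix"))
}

#' Look up whether an undirected edge is present
#'
#' @param network A [BaseNetwork-class].
#' @param u,v Endpoints.
#' @return `TRUE` if the edge exists with positive weight.
#' @export
hasEdge <- function(network, u, v) {
  nodes <- network@nodes
  if (!(u %in% nodes) || !(v %in% nodes)) return(FALSE)
  network@adjacency[u, v] > 0
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, fields `term id`, `description`,
#' then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list; element `term` is `list(name = <description>,
#'   genes = <character>)`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need term, description, >=1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    out[[f[1]]] <- list(name = f[2], genes = unique(f[-(1:2)]))
  }
  out
}
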
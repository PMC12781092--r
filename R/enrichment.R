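## Edge-level functional enrichment: genes adjacent to predicted-negative
## (or positive) edges are tested for over-representation in gene-set
## terms with an upper-tail hypergeometric test and Bonferroni correction.
## The population defaults to the genes of the base network (the
## interactome context the edges were drawn from), not the genome.

#' Genes adjacent to edges of one predicted sign
#'
#' @param signs Sign assignment from [assignEdgeSigns()].
#' @param which `"negative"` or `"positive"`.
#' @return Character vector: the union of endpoints of edges carrying the
#'   requested sign (a gene adjacent to both a positive and a negative
#'   edge appears in both query sets).
#' @export
genesAdjacentToSignedEdges <- function(signs,
                                       which = c("negative", "positive")) {
  which <- match.arg(which)
  want <- if (which == "negative") -1L else 1L
  sel <- signs$sign == want
  sort(unique(c(signs$u[sel], signs$v[sel])))
}

#' Filter gene-set terms by size
#'
#' Keeps terms whose gene set, after restriction to the population, has
#' between `minSize` and `maxSize` genes (inclusive); the published
#' analysis used 10-100 to focus on interpretable categories.
#'
#' @param collection Named list as from [readGmt()].
#' @param population Character vector: the gene universe (term sets are
#'   intersected with it before sizing). `NULL` to size terms as given.
#' @param minSize,maxSize Inclusive size bounds (defaults 10 and 100).
#' @return The filtered collection, with term gene sets restricted to the
#'   population when one was given.
#' @export
filterTerms <- function(collection, population = NULL, minSize = 10L,
                        maxSize = 100L) {
  if (!is.null(population))
    collection <- lapply(collection, function(tm) {
      tm$genes <- intersect(tm$genes, population)
      tm
    })
  sizes <- vapply(collection, function(tm) length(tm$genes), integer(1))
  collection[sizes >= minSize & sizes <= maxSize]
}

#' Hypergeometric over-representation test
#'
#' For each term, the upper-tail probability `P[X >= overlap]` of drawing
#' at least the observed overlap when `|query|` genes are sampled without
#' replacement from the population containing `|term|` annotated genes
#' (computed stably via `phyper`'s log-space upper tail). P-values are
#' Bonferroni-adjusted over the tested terms and capped at 1; results are
#' sorted by adjusted p, ties broken by term id.
#'
#' @param query Character vector of genes, a subset of `population`.
#' @param collection Named list as from [readGmt()] (term sets are
#'   intersected with the population).
#' @param population Character vector: the gene universe.
#' @return data.frame `term, name, overlap, termSize, querySize,
#'   populationSize, p, pAdjusted`.
#' @export
hypergeomEnrichment <- function(query, collection, population) {
  population <- unique(population)
  if (!length(population)) stop("empty population", call. = FALSE)
  query <- unique(query)
  if (length(setdiff(query, population)))
    stop("query contains genes outside the population", call. = FALSE)
  N <- length(population)
  q <- length(query)
  rows <- lapply(names(collection), function(id) {
    genes <- intersect(collection[[id]]$genes, population)
    m <- length(genes)
    ov <- length(intersect(genes, query))
    p <- stats::phyper(ov - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(term = id, name = collection[[id]]$name, overlap = ov,
               termSize = m, querySize = q, populationSize = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), name = character(0),
                      overlap = integer(0), termSize = integer(0),
                      querySize = integer(0), populationSize = integer(0),
                      p = numeric(0), pAdjusted = numeric(0)))
  out$pAdjusted <- pmin(1, out$p * nrow(out))
  out <- out[order(out$pAdjusted, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#'
#' Columns: name, term id, -log10 adjusted p (plus the raw counts).
#'
#' @param result data.frame from [hypergeomEnrichment()].
#' @param path Output path.
#' @export
writeEnrichment <- function(result, path) {
  out <- data.frame(name = result$name, term = result$term,
                    minusLog10AdjP = -log10(result$pAdjusted),
                    overlap = result$overlap, termSize = result$termSize,
                    p = result$p, pAdjusted = result$pAdjusted)
  writeTsv(out, path,
           header = paste(colnames(out), collapse = "\t"))
}
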
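## One-shot pipeline and flat configuration. Every artifact directory
## carries a manifest (config, seed, versions, input checksums) from
## which the run is exactly reproducible.

.configDefaults <- function() list(
  alpha = 0.6, tol = 1e-8, maxIter = 1000L, A = 1, folds = 5L,
  seed = 1L, tau = 0.5, epsilon = 0.01, minPaths = 100L,
  orientation = "inverse", minTermSize = 10L, maxTermSize = 100L,
  adjustment = "bonferroni", stratifyByEnzyme = FALSE,
  queryEdges = "all")

#' Validated pipeline configuration
#'
#' Flat key-value record of every tunable, with the package defaults;
#' unknown keys are rejected and ranges validated before any computation.
#'
#' @param ... Overrides of the defaults: `alpha` (0.6), `tol` (1e-8),
#'   `maxIter` (1000), `A` (1), `folds` (5), `seed` (1), `tau` (0.5),
#'   `epsilon` (0.01), `minPaths` (100), `orientation` ("inverse"),
#'   `minTermSize` (10), `maxTermSize` (100), `adjustment`
#'   ("bonferroni"), `stratifyByEnzyme` (FALSE), `queryEdges` ("all" or
#'   "labeled").
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  defaults <- .configDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) || (length(over) && is.null(names(over))))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  assertScalarNumeric(cfg$alpha, "alpha", 0, 1, strict = TRUE)
  assertScalarNumeric(cfg$tol, "tol", 0, Inf, strict = TRUE)
  assertScalarNumeric(cfg$maxIter, "maxIter", 1, Inf)
  assertScalarNumeric(cfg$A, "A", 0, Inf, strict = TRUE)
  assertScalarNumeric(cfg$folds, "folds", 2, Inf)
  assertScalarNumeric(cfg$seed, "seed", -2^31, 2^31)
  assertScalarNumeric(cfg$tau, "tau", 0, 1, strict = TRUE)
  assertScalarNumeric(cfg$epsilon, "epsilon", 0, 1)
  assertScalarNumeric(cfg$minPaths, "minPaths", 1, Inf)
  assertScalarNumeric(cfg$minTermSize, "minTermSize", 1, Inf)
  assertScalarNumeric(cfg$maxTermSize, "maxTermSize", cfg$minTermSize,
                      Inf)
  cfg$orientation <- match.arg(cfg$orientation, c("inverse", "direct"))
  cfg$adjustment <- match.arg(cfg$adjustment, "bonferroni")
  cfg$queryEdges <- match.arg(cfg$queryEdges, c("all", "labeled"))
  assertFlag(cfg$stratifyByEnzyme, "stratifyByEnzyme")
  structure(cfg, class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full annotation pipeline
#'
#' build-network -> features (training edges) -> cross-validation ->
#' train on all labels -> predict S-scores for the query edges ->
#' optional NegScore reconstruction and functional enrichment. Every
#' output is TSV with a `#` header line; `manifest.json` records the
#' configuration, seed, package/R versions and input checksums, so a run
#' is bit-reproducible from its manifest (see [rerunFromManifest()]).
#'
#' @param config A [runConfig()].
#' @param edgesFile,signedFile,signaturesFile Input TSV paths.
#' @param outDir Artifact directory (created if needed).
#' @param pairsFile Optional TSV `source<TAB>target` for NegScores.
#' @param gmtFile Optional GMT collection for enrichment of
#'   predicted-negative edges.
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, edgesFile, signedFile, signaturesFile,
                        outDir, pairsFile = NULL, gmtFile = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pcfg <- propagationConfig(config$alpha, config$tol, config$maxIter)

  inputs <- c(edges = edgesFile, signed = signedFile,
              signatures = signaturesFile)
  if (!is.null(pairsFile)) inputs["pairs"] <- pairsFile
  if (!is.null(gmtFile)) inputs["gmt"] <- gmtFile
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)

  edges <- .stage("read-edges", readEdgeList(edgesFile))
  signed <- .stage("read-signed", readSignedTable(signedFile))
  signatures <- .stage("read-signatures",
                       readKnockoutSignatures(signaturesFile))
  network <- .stage("build-network",
                    assembleBaseNetwork(edges, signed, signatures))
  message(sprintf("[build-network] %d nodes, %d undirected edges",
                  length(network), nrow(networkEdges(network))))

  trainEdges <- signed[, c("u", "v")]
  trainFM <- .stage("features", buildFeatureMatrix(
    network, signatures, trainEdges, pcfg, A = config$A))
  message(sprintf("[features] %d training edges x %d columns",
                  nrow(featureValues(trainFM)),
                  ncol(featureValues(trainFM))))

  folds <- if (isTRUE(config$stratifyByEnzyme))
    enzymeStratifiedFolds(signed, config$folds, config$seed)
  else NULL
  cv <- .stage("cross-validate", crossValidate(
    trainFM, signed$sign, folds = folds, nFolds = config$folds,
    seed = config$seed))
  message(sprintf("[cross-validate] pooled AUROC %.3f, AUPRC %.3f",
                  cv$auroc, cv$auprc))

  model <- .stage("train", trainSignClassifier(trainFM, signed$sign,
                                               seed = config$seed))
  queryEdges <- if (config$queryEdges == "all") networkEdges(network)
                else trainEdges
  queryFM <- if (config$queryEdges == "all")
    .stage("features-query", buildFeatureMatrix(
      network, signatures, queryEdges, pcfg, A = config$A))
  else trainFM
  scores <- .stage("predict", predictScores(model, queryFM))
  signs <- assignEdgeSigns(scores, config$tau, config$epsilon)
  message(sprintf("[predict] %d edges scored: %d negative, %d positive, %d unsigned",
                  nrow(signs), sum(signs$sign == -1L),
                  sum(signs$sign == 1L), sum(signs$sign == 0L)))

  paths <- list()
  write1 <- function(tag, df, file, header) {
    p <- file.path(outDir, file)
    writeTsv(df, p, header = header)
    paths[[tag]] <<- p
  }
  write1("scores", data.frame(u = scores$u, v = scores$v,
                              S = sprintf("%.17g", scores$S)),
         "scores.tsv", "u\tv\tS")
  write1("signs", data.frame(u = signs$u, v = signs$v,
                             S = sprintf("%.17g", signs$S),
                             sign = signs$sign),
         "signs.tsv", "u\tv\tS\tsign")
  write1("cv", data.frame(metric = c("auroc", "auprc"),
                          value = sprintf("%.17g", c(cv$auroc,
                                                     cv$auprc))),
         "cv_metrics.tsv", "metric\tvalue")

  if (!is.null(pairsFile)) {
    tsv <- readTsvLines(pairsFile)
    pairs <- data.frame(
      source = vapply(tsv$fields, `[[`, "", 1L),
      target = vapply(tsv$fields, `[[`, "", 2L))
    recs <- .stage("reconstruct",
                   negScoreTable(network, signs, pairs,
                                 config$minPaths))
    message(sprintf("[reconstruct] %d of %d pairs pass min-paths %d",
                    nrow(recs), nrow(pairs), config$minPaths))
    recs$negScore <- sprintf("%.17g", recs$negScore)
    write1("negscores", recs, "negscores.tsv",
           "source\ttarget\tn_paths\tn_negative\tneg_score")
  }
  if (!is.null(gmtFile)) {
    collection <- .stage("enrich-read", readGmt(gmtFile))
    population <- networkNodes(network)
    collection <- filterTerms(collection, population,
                              config$minTermSize, config$maxTermSize)
    query <- genesAdjacentToSignedEdges(signs, "negative")
    enr <- .stage("enrich", hypergeomEnrichment(query, collection,
                                                population))
    message(sprintf("[enrich] %d terms tested, %d with adjusted p < 0.05",
                    nrow(enr), sum(enr$pAdjusted < 0.05)))
    p <- file.path(outDir, "enrichment.tsv")
    writeEnrichment(enr, p)
    paths$enrichment <- p
  }

  manifest <- list(
    config = unclass(config),
    inputs = as.list(inputs),
    checksums = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        names(inputs))),
    packageVersion = as.character(utils::packageVersion("signet")),
    rVersion = R.version.string,
    artifacts = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(outDir, "manifest.json")
  invisible(paths)
}

#' Re-run a pipeline from its manifest
#'
#' Reads the manifest, verifies the input checksums still match, and
#' reruns [runPipeline()] with the recorded configuration; the score
#' tables are bit-identical to the original run.
#'
#' @param manifestPath Path to a `manifest.json`.
#' @param outDir Output directory for the rerun.
#' @return Invisibly, the artifact paths of the rerun.
#' @export
rerunFromManifest <- function(manifestPath, outDir) {
  m <- jsonlite::read_json(manifestPath)
  inputs <- unlist(m$inputs)
  sums <- stats::setNames(unname(tools::md5sum(inputs)), names(inputs))
  rec <- unlist(m$checksums)
  if (!identical(unname(sums[names(rec)]), unname(rec)))
    stop("input checksums no longer match the manifest", call. = FALSE)
  cfg <- do.call(runConfig, m$config)
  runPipeline(cfg, inputs[["edges"]], inputs[["signed"]],
              inputs[["signatures"]], outDir,
              pairsFile = if ("pairs" %in% names(inputs))
                inputs[["pairs"]],
              gmtFile = if ("gmt" %in% names(inputs)) inputs[["gmt"]])
}
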
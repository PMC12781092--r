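## Random-forest edge-sign classification. The classifier is trained with
## the implementation's default hyperparameters (randomForest); the output
## probability of the "negative" class is the per-edge S-score. Evaluation
## is 5-fold cross-validation, either plain random or stratified by enzyme
## so that all edges of one kinase/phosphatase share a fold (no leakage
## through shared enzymes).

#' Train the edge-sign random forest
#'
#' Fits a random forest with default hyperparameters on the feature rows
#' of sign-annotated edges. The model predicts the probability that an
#' edge is negative (repressing). Deterministic given `seed`. A feature
#' matrix whose columns are all constant admits no split; the model then
#' degenerates to the class prior (every prediction equals the training
#' fraction of negative edges).
#'
#' @param features A [SignalFeatures-class] (or numeric matrix) whose rows
#'   align with `labels`.
#' @param labels Integer signs in \{-1, +1\} (or a factor with levels
#'   `positive`/`negative`); both classes must be present.
#' @param seed Integer RNG seed recorded in the returned model.
#' @return An object of class `SignClassifier`.
#' @export
trainSignClassifier <- function(features, labels, seed = 1L) {
  X <- if (methods::is(features, "SignalFeatures"))
    featureValues(features) else as.matrix(features)
  y <- .asSignFactor(labels)
  if (nrow(X) != length(y))
    stop("feature rows and labels do not align", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  ## a fully constant feature matrix admits no split: the only honest
  ## prediction is the class prior
  constant <- all(apply(X, 2, function(col) max(col) == min(col)))
  fit <- if (constant) NULL
         else withSeed(seed, randomForest::randomForest(x = X, y = y))
  structure(list(model = fit, columns = colnames(X),
                 prior = mean(y == "negative"),
                 seed = as.integer(seed)),
            class = "SignClassifier")
}

## Probability of the negative class for a feature matrix.
.predictProb <- function(model, X) {
  if (is.null(model$model)) return(rep(model$prior, nrow(X)))
  as.numeric(stats::predict(model$model, X, type = "prob")[, "negative"])
}

.asSignFactor <- function(labels) {
  if (is.factor(labels)) {
    stopifnot(all(levels(labels) %in% c("positive", "negative")))
    return(factor(labels, levels = c("positive", "negative")))
  }
  factor(ifelse(labels < 0, "negative", "positive"),
         levels = c("positive", "negative"))
}

#' Predict S-scores (per-edge negativity probabilities)
#'
#' @param model A `SignClassifier` from [trainSignClassifier()].
#' @param features A [SignalFeatures-class] (or matrix) with exactly the
#'   training columns.
#' @return data.frame `u, v, S` with `S` in \[0, 1\] (the S-score table);
#'   when `features` is a bare matrix, `u`/`v` are parsed from rownames.
#' @export
predictScores <- function(model, features) {
  stopifnot(inherits(model, "SignClassifier"))
  if (methods::is(features, "SignalFeatures")) {
    X <- featureValues(features)
    edges <- featureEdges(features)
  } else {
    X <- as.matrix(features)
    parts <- strsplit(rownames(X), "|", fixed = TRUE)
    edges <- data.frame(u = vapply(parts, `[[`, "", 1L),
                        v = vapply(parts, `[[`, "", 2L))
  }
  if (!identical(colnames(X), model$columns))
    stop("feature columns do not match the training columns",
         call. = FALSE)
  data.frame(u = edges$u, v = edges$v, S = .predictProb(model, X),
             stringsAsFactors = FALSE)
}

#' Enzyme-stratified cross-validation folds
#'
#' Partitions signed training edges into `nFolds` folds such that all
#' edges sharing an enzyme land in one fold. Enzymes are sorted by degree
#' (edge count) descending, ties broken lexicographically, and greedily
#' assigned to the currently lightest fold (LPT balancing). A repair pass
#' then guarantees each fold holds at least one kinase-like (majority
#' positive) and one phosphatase-like (majority negative) enzyme, using
#' degree-matched swaps so the balance bound is preserved; if a class has
#' fewer enzymes than folds the constraint is relaxed with a warning.
#' Edges without an enzyme id are distributed individually to the
#' lightest folds.
#'
#' @param signed data.frame as from [readSignedTable()] (`u`, `v`,
#'   `sign`, `enzyme`).
#' @param nFolds Number of folds (default 5).
#' @param seed Unused by the deterministic greedy; kept for interface
#'   symmetry with [crossValidate()].
#' @return List with `fold` (integer per row of `signed`), `enzyme`
#'   (per-row enzyme id or NA), `loads` (degree-sum per fold) and
#'   `repaired` (whether the class-coverage repair moved any enzyme; the
#'   greedy balance bound max - min <= max enzyme degree is guaranteed
#'   only when it did not).
#' @export
enzymeStratifiedFolds <- function(signed, nFolds = 5L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  stopifnot(nFolds >= 2L, nrow(signed) >= nFolds)
  enz <- as.character(signed$enzyme)
  hasEnz <- !is.na(enz) & nzchar(enz)
  fold <- integer(nrow(signed))
  loads <- numeric(nFolds)

  groups <- split(which(hasEnz), enz[hasEnz])
  deg <- lengths(groups)
  cls <- vapply(groups, function(rows)
    if (sum(signed$sign[rows] < 0) > length(rows) / 2) -1L else 1L,
    integer(1))
  ord <- names(groups)[order(-deg, names(groups))]
  enzFold <- integer(length(groups)); names(enzFold) <- names(groups)
  for (e in ord) {
    f <- which.min(loads)
    enzFold[e] <- f
    loads[f] <- loads[f] + deg[e]
  }

  ## repair pass: every fold needs both enzyme classes, via swaps of
  ## near-equal degree (move only when the deficient fold has no partner);
  ## swaps of unequal degree can loosen the greedy balance bound, so the
  ## result records whether any repair fired
  repaired <- FALSE
  for (c in c(1L, -1L)) {
    ofClass <- names(groups)[cls == c]
    if (!length(ofClass)) next
    if (length(ofClass) < nFolds) {
      warning(sprintf(
        "only %d enzyme(s) of class %+d for %d folds; coverage relaxed",
        length(ofClass), c, nFolds), call. = FALSE)
      next
    }
    repeat {
      have <- tabulate(enzFold[ofClass], nFolds)
      lacking <- which(have == 0L)
      if (!length(lacking)) break
      donor <- which.max(have)
      if (have[donor] < 2L) break
      dEnz <- ofClass[enzFold[ofClass] == donor]
      x <- dEnz[order(deg[dEnz], dEnz)][1]        # smallest class-c enzyme
      f <- lacking[1]
      others <- names(groups)[enzFold == f & cls != c]
      if (length(others)) {
        y <- others[order(abs(deg[others] - deg[x]), others)][1]
        enzFold[y] <- donor
        loads[donor] <- loads[donor] - deg[x] + deg[y]
        loads[f] <- loads[f] + deg[x] - deg[y]
      } else {
        loads[donor] <- loads[donor] - deg[x]
        loads[f] <- loads[f] + deg[x]
      }
      enzFold[x] <- f
      repaired <- TRUE
    }
  }
  for (e in names(groups)) fold[groups[[e]]] <- enzFold[e]

  ## enzyme-free edges: one by one onto the lightest fold, in canonical
  ## edge-key order for determinism
  free <- which(!hasEnz)
  free <- free[order(edgeKey(signed$u[free], signed$v[free]))]
  for (i in free) {
    f <- which.min(loads)
    fold[i] <- f
    loads[f] <- loads[f] + 1
  }
  if (any(tabulate(fold, nFolds) == 0L))
    warning("empty fold(s): fewer groups than folds", call. = FALSE)
  list(fold = fold, enzyme = ifelse(hasEnz, enz, NA_character_),
       loads = loads, repaired = repaired)
}

#' Plain class-stratified random folds
#'
#' Random 5-way split of edges, stratified by sign class so every
#' training set contains both classes.
#'
#' @param labels Integer signs in \{-1, +1\}.
#' @param nFolds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold vector in `1..nFolds`.
#' @export
randomFolds <- function(labels, nFolds = 5L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

#' Cross-validated S-scores and metrics
#'
#' Trains on `nFolds - 1` folds and scores the held-out fold, pooling
#' out-of-fold predictions across folds; AUROC and AUPRC (average
#' precision, with the minority negative class as the detection target)
#' are computed on the pooled predictions. Per-fold AUCs are additionally
#' reported when `perFold = TRUE` (folds that are single-class at
#' evaluation are skipped there with a message).
#'
#' @param features A [SignalFeatures-class] (or matrix) of labeled edges.
#' @param labels Integer signs in \{-1, +1\} aligned with rows.
#' @param folds `NULL` for a plain class-stratified random split, an
#'   integer vector of fold ids, or the result of
#'   [enzymeStratifiedFolds()].
#' @param nFolds Number of folds when `folds` is `NULL` (default 5).
#' @param seed RNG seed (fold split and forests).
#' @param perFold Also compute per-fold AUCs (default `FALSE`).
#' @return List: `scores` (pooled out-of-fold S per edge), `fold`,
#'   `auroc`, `auprc`, and optionally `perFoldAuroc`.
#' @export
crossValidate <- function(features, labels, folds = NULL, nFolds = 5L,
                          seed = 1L, perFold = FALSE) {
  X <- if (methods::is(features, "SignalFeatures"))
    featureValues(features) else as.matrix(features)
  labels <- as.integer(labels)
  if (is.null(folds)) {
    fold <- randomFolds(labels, nFolds, seed)
  } else if (is.list(folds)) {
    fold <- folds$fold
  } else fold <- as.integer(folds)
  stopifnot(length(fold) == nrow(X))
  S <- rep(NA_real_, nrow(X))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    model <- trainSignClassifier(X[tr, , drop = FALSE], labels[tr],
                                 seed = seed)
    S[!tr] <- .predictProb(model, X[!tr, , drop = FALSE])
  }
  isNeg <- labels < 0
  out <- list(scores = S, fold = fold,
              auroc = aucROC(S, isNeg),
              auprc = averagePrecision(S, isNeg))
  if (perFold) {
    pf <- vapply(sort(unique(fold)), function(f) {
      ev <- fold == f
      if (length(unique(isNeg[ev])) < 2L) {
        message("fold ", f, " is single-class; skipped in per-fold AUCs")
        return(NA_real_)
      }
      aucROC(S[ev], isNeg[ev])
    }, numeric(1))
    out$perFoldAuroc <- pf
  }
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal AUROC with higher scores indicating the event class
#' (equivalently the normalized Mann-Whitney U statistic with 0.5 credit
#' for ties).
#'
#' @param scores Numeric predictor.
#' @param event Logical: TRUE for the detection-target class.
#' @return AUROC in \[0, 1\].
#' @export
aucROC <- function(scores, event) {
  r <- pROC::roc(response = factor(event, levels = c(FALSE, TRUE)),
                 predictor = scores, levels = c("FALSE", "TRUE"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Average precision (area under the precision-recall curve)
#'
#' Sum of precision at each threshold weighted by the recall increment,
#' with tied scores collapsed into one threshold.
#'
#' @param scores Numeric predictor.
#' @param event Logical: TRUE for the detection-target class.
#' @return AUPRC in \[0, 1\].
#' @export
averagePrecision <- function(scores, event) {
  stopifnot(length(scores) == length(event), any(event))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- event[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(prec * diff(c(0, rec)))
}
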
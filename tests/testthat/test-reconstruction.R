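test_that("sign assignment partitions scores with a confidence band", {
  sc <- data.frame(u = letters[1:5], v = LETTERS[1:5],
                   S = c(0.52, 0.5, 0.496, 0.48, 0.51))
  sa <- assignEdgeSigns(sc)
  expect_equal(sa$sign, c(-1L, 0L, 0L, 1L, 0L))

  ## epsilon = 0: only S == tau stays unsigned
  sa0 <- assignEdgeSigns(sc, epsilon = 0)
  expect_equal(sa0$sign, c(-1L, 0L, 1L, 1L, -1L))

  ## every edge gets exactly one state for arbitrary (tau, epsilon)
  for (s in 1:5) {
    withr::with_seed(s, {
      S <- stats::runif(50)
      tau <- stats::runif(1, 0.2, 0.8)
      eps <- stats::runif(1, 0, 0.2)
    })
    sa2 <- assignEdgeSigns(data.frame(u = paste0("x", 1:50),
                                      v = paste0("y", 1:50), S = S),
                           tau, eps)
    expect_true(all(sa2$sign %in% c(-1L, 0L, 1L)))
    expect_equal(sa2$sign == -1L, S > tau + eps)
    expect_equal(sa2$sign == 1L, S < tau - eps)
  }
  expect_error(assignEdgeSigns(sc, tau = 1.5), "tau")
})

test_that("path signs multiply and reject unsigned edges", {
  signs <- data.frame(u = c("a", "b", "c", "d"),
                      v = c("b", "c", "d", "e"),
                      sign = c(1L, 1L, 1L, 1L))
  expect_equal(pathSign(c("a", "b", "c", "d", "e"), signs), 1)
  signs$sign[2] <- -1L
  expect_equal(pathSign(c("a", "b", "c", "d", "e"), signs), -1)
  signs$sign[4] <- -1L
  expect_equal(pathSign(c("a", "b", "c", "d", "e"), signs), 1)
  signs$sign[1] <- 0L
  expect_error(pathSign(c("a", "b", "c"), signs), "unsigned")
})

test_that("shortest-path enumeration is exact, ordered and minimal", {
  ## 2x2 grid: two shortest diagonal paths
  grid <- assembleBaseNetwork(data.frame(
    u = c("a", "a", "b", "c"), v = c("b", "c", "d", "d")))
  signs <- randomSigns(grid, 0, seed = 1)
  paths <- enumerateShortestPaths(grid, signs, "a", "d")
  expect_length(paths, 2L)
  expect_equal(paths[[1]], c("a", "b", "d"))
  expect_equal(paths[[2]], c("a", "c", "d"))

  ## adjacency wins over longer alternatives
  tri <- assembleBaseNetwork(data.frame(u = c("a", "a", "b"),
                                        v = c("b", "c", "c")))
  p1 <- enumerateShortestPaths(tri, randomSigns(tri, 0, 1), "a", "b")
  expect_length(p1, 1L)
  expect_equal(p1[[1]], c("a", "b"))

  ## unreachable pair -> empty list
  comps <- assembleBaseNetwork(data.frame(u = c("a", "x"),
                                          v = c("b", "y")))
  expect_length(
    enumerateShortestPaths(comps, randomSigns(comps, 0, 1), "a", "y"),
    0L)
})

test_that("the parity DP matches brute-force enumeration on random graphs", {
  for (s in 1:12) {
    net <- randomTestNetwork(withr::with_seed(s, sample(8:30, 1)),
                             withr::with_seed(s + 1, sample(15:60, 1)),
                             seed = s)
    signs <- randomSigns(net, 0.3, seed = s + 50)
    nodes <- networkNodes(net)
    pick <- withr::with_seed(s + 99, sample(nodes, 4))
    for (i in 1:2) {
      k <- pick[i]; t <- pick[i + 2]
      if (k == t) next
      bf <- bruteForceNegScore(net, signs, k, t)
      rec <- negScore(net, signs, k, t, minPaths = 1)
      if (bf["nPaths"] == 0) {
        expect_null(rec)
      } else {
        expect_equal(rec$nPaths, unname(bf["nPaths"]))
        expect_equal(rec$nNegative, unname(bf["nNegative"]))
        expect_equal(rec$negScore,
                     unname(bf["nNegative"] / bf["nPaths"]))
      }
    }
  }
})

test_that("NegScore applies the minimum-path filter and basic fractions", {
  ## two parallel 2-hop routes, one through a negative edge
  net <- assembleBaseNetwork(data.frame(
    u = c("k", "k", "p", "q"), v = c("p", "q", "t", "t")))
  signs <- networkEdges(net)
  signs$sign <- ifelse(signs$u == "p" & signs$v == "t", -1L, 1L)
  rec <- negScore(net, signs, "k", "t", minPaths = 1)
  expect_equal(rec$nPaths, 2)
  expect_equal(rec$negScore, 0.5)
  expect_null(negScore(net, signs, "k", "t", minPaths = 3))

  allPos <- randomSigns(net, 0, seed = 1)
  expect_equal(negScore(net, allPos, "k", "t", minPaths = 1)$negScore, 0)
})

test_that("unsigned edges are deleted before path search", {
  ## direct k-t edge unsigned: paths must detour, not touch it
  net <- assembleBaseNetwork(data.frame(
    u = c("k", "k", "p"), v = c("t", "p", "t")))
  signs <- networkEdges(net)
  signs$sign <- ifelse(signs$u == "k" & signs$v == "t", 0L, 1L)
  paths <- enumerateShortestPaths(net, signs, "k", "t")
  expect_length(paths, 1L)
  expect_equal(paths[[1]], c("k", "p", "t"))
  rec <- negScore(net, signs, "k", "t", minPaths = 1)
  expect_equal(rec$nPaths, 2 - 1)  # only the detour counts
})

test_that("all-positive cascades give down-score 1 under inversion", {
  ## knockout of an activator cascade: every reachable target is labeled
  ## down, and with the true (all-positive) signs the fraction of
  ## positive paths is 1
  w <- generateSignedNetwork(nNodes = 60, meanDegree = 6, pNeg = 0,
                             seed = 3)
  sim <- simulateKnockoutSignatures(w$network, w$trueSigns, 3, 8,
                                    flipNoise = 0, seed = 3)
  expect_true(all(sim$truth$response == -1L))   # all "down"
  signs <- w$trueSigns
  signs$S <- 0
  recs <- negScoreTable(w$network, signs,
                        data.frame(source = sim$truth$knockout,
                                   target = sim$truth$target),
                        minPaths = 1)
  expect_true(all(recs$negScore == 0))
  expect_true(all(1 - recs$negScore == 1))      # inverse down-score
})

test_that("signature reconstruction retrains k-less and reports pairs", {
  w <- generateSignedNetwork(nNodes = 60, meanDegree = 6, pNeg = 0.2,
                             seed = 4)
  sim <- simulateKnockoutSignatures(w$network, w$trueSigns, 4, 10,
                                    flipNoise = 0, seed = 4)
  sigs <- sim$signatures
  k <- knockouts(sigs)[1]
  ed <- w$trueSigns[, c("u", "v")]
  fm <- suppressMessages(buildFeatureMatrix(w$network, sigs, ed))
  rec <- reconstructSignature(w$network, sigs, k, fm, w$trueSigns$sign,
                              fm, minPaths = 1, seed = 2)
  expect_gt(nrow(rec), 0)
  expect_setequal(
    rec$target[rec$observed == 1],
    intersect(downTargets(sigs, k), rec$target))
  expect_true(all(rec$predicted >= 0 & rec$predicted <= 1))
  recD <- reconstructSignature(w$network, sigs, k, fm,
                               w$trueSigns$sign, fm, minPaths = 1,
                               orientation = "direct", seed = 2)
  expect_equal(recD$predicted, 1 - rec$predicted)
  ## an unreachable min-paths bar warns and returns an empty frame
  expect_warning(
    none <- reconstructSignature(w$network, sigs, k, fm,
                                 w$trueSigns$sign, fm,
                                 minPaths = 1e6, seed = 2),
    "min-paths")
  expect_equal(nrow(none), 0L)
})

test_that("a single negative edge on every path predicts upregulation", {
  ## k -e- m -+- t : the only path crosses one negative edge
  net <- assembleBaseNetwork(data.frame(u = c("k", "m"),
                                        v = c("m", "t")))
  signs <- networkEdges(net)
  signs$sign <- ifelse(signs$u == "k", -1L, 1L)
  rec <- negScore(net, signs, "k", "t", minPaths = 1)
  expect_equal(rec$negScore, 1)
  ## inverse orientation: response = -(path sign) = +1 (up)
})

test_that("phenotypes aggregate NegScores over anchors", {
  net <- assembleBaseNetwork(data.frame(
    u = c("a1", "a2", "m", "m", "x"),
    v = c("m", "m", "t1", "t2", "y")))
  signs <- networkEdges(net)
  signs$sign <- ifelse(signs$v == "t1" | signs$u == "t1", -1L, 1L)

  res <- reconstructPhenotype(net, signs, anchors = c("a1", "a2"),
                              terminals = c(t1 = 1L, t2 = 0L),
                              minPaths = 1)
  expect_equal(sort(res$scores$terminal), c("t1", "t2"))
  expect_equal(res$scores$score[res$scores$terminal == "t1"], 1)
  expect_equal(res$scores$score[res$scores$terminal == "t2"], 0)
  expect_equal(res$auprc, 1)

  ## single anchor: aggregation is the identity
  res1 <- reconstructPhenotype(net, signs, anchors = "a1",
                               terminals = c(t1 = 1L, t2 = 0L),
                               minPaths = 1)
  expect_equal(res1$scores$nAnchors, c(1L, 1L))

  ## unreachable terminal is excluded with a message
  expect_message(
    res2 <- reconstructPhenotype(net, signs, anchors = "a1",
                                 terminals = c(t1 = 1L, t2 = 0L,
                                               y = 1L),
                                 minPaths = 1),
    "excluded")
  expect_false("y" %in% res2$scores$terminal)

  expect_error(reconstructPhenotype(net, signs, character(0),
                                    c(t1 = 1L)),
               "empty anchor")
})
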
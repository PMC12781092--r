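test_that("delta profiles subtract elementwise and police node sets", {
  net <- assembleBaseNetwork(data.frame(u = c("a", "b"),
                                        v = c("b", "c")))
  full <- propagate(net, "a")
  d0 <- deltaProfile(full, full)
  expect_true(all(d0@delta == 0))

  ## removing the bridge disconnects c: delta at c equals the full score
  pd <- defectivePropagate(net, "a", c("b", "c"))
  d <- deltaProfile(full, pd)
  expect_equal(d@delta[["c"]], full@scores[["c"]])

  other <- propagate(net, "b")
  expect_error(deltaProfile(full, other), "different genes")

  ## three-node path: delta matches the hand difference of two oracles
  oracleDelta <- densePropagationOracle(net, "a") -
    densePropagationOracle(net, "a", drop = c("b", "c"))
  expect_lt(max(abs(d@delta - oracleDelta)), 1e-8)
})

test_that("edge features average deltas over present targets", {
  d <- stats::setNames(c(0.2, 0.4, 0), c("a", "b", "c"))
  expect_message(z <- edgeFeature(d, character(0)), "empty")
  expect_equal(z, 0)
  expect_equal(edgeFeature(d, c("a", "b")), 0.3)
  ## absent targets are excluded from numerator and denominator
  expect_equal(edgeFeature(d, c("a", "zz")), 0.2)
  ## linearity in the scaling constant
  expect_equal(edgeFeature(d, c("a", "b"), A = 2),
               2 * edgeFeature(d, c("a", "b"), A = 1))
  expect_equal(edgeFeature(stats::setNames(numeric(3), names(d)),
                           c("a", "b")), 0)
})

test_that("the feature matrix has 2n ordered columns and exact entries", {
  net <- randomTestNetwork(20, 45, seed = 9)
  nodes <- networkNodes(net)
  sigs <- toySignatures(
    k1 = list(up = nodes[3:5], down = nodes[6:7]),
    k2 = list(up = nodes[8], down = nodes[9:11]),
    k3 = list(up = nodes[12:13], down = nodes[14]))
  ## rename knockouts to actual nodes
  names(sigs@signatures) <- nodes[c(1, 2, 15)]
  ed <- networkEdges(net)[1:5, c("u", "v")]
  fm <- buildFeatureMatrix(net, sigs, ed)
  expect_equal(dim(featureValues(fm)), c(5L, 6L))
  ks <- knockouts(sigs)
  expect_equal(colnames(featureValues(fm)),
               as.vector(rbind(paste0(ks, "+"), paste0(ks, "-"))))

  ## entries match a naive per-entry recomputation through the public ops
  cfg <- propagationConfig()
  for (i in 1:2) for (j in seq_along(ks)) {
    full <- propagate(net, ks[j], cfg)
    def <- defectivePropagate(net, ks[j], c(ed$u[i], ed$v[i]), cfg)
    d <- deltaProfile(full, def)
    expect_identical(featureValues(fm)[i, 2 * j - 1],
                     edgeFeature(d, upTargets(sigs, ks[j])))
    expect_identical(featureValues(fm)[i, 2 * j],
                     edgeFeature(d, downTargets(sigs, ks[j])))
  }

  expect_error(buildFeatureMatrix(net, sigs,
                                  data.frame(u = "zz", v = "qq")),
               "absent")
})

test_that("cached and uncached feature matrices are bit-identical", {
  net <- randomTestNetwork(20, 40, seed = 11)
  nodes <- networkNodes(net)
  sigs <- toySignatures(a = list(up = nodes[5:8], down = nodes[9:10]))
  names(sigs@signatures) <- nodes[1]
  ed <- networkEdges(net)[1:6, c("u", "v")]
  fm1 <- buildFeatureMatrix(net, sigs, ed, cache = TRUE)
  fm2 <- buildFeatureMatrix(net, sigs, ed, cache = FALSE)
  expect_identical(featureValues(fm1), featureValues(fm2))
})

test_that("an edge with no knockout in its component has a zero row", {
  ## two components; knockout lives in the first
  df <- data.frame(u = c("a", "b", "x"), v = c("b", "c", "y"))
  net <- assembleBaseNetwork(df)
  sigs <- toySignatures(a = list(up = "c", down = "b"))
  fm <- buildFeatureMatrix(net, sigs, data.frame(u = "x", v = "y"))
  expect_true(all(featureValues(fm) == 0))
})

test_that("k-less exclusion removes exactly two columns and is pure", {
  net <- randomTestNetwork(15, 30, seed = 2)
  nodes <- networkNodes(net)
  sigs <- toySignatures(x = list(up = nodes[4], down = nodes[5]),
                        y = list(up = nodes[6], down = nodes[7]),
                        z = list(up = nodes[8], down = nodes[9]))
  names(sigs@signatures) <- nodes[1:3]
  ed <- networkEdges(net)[1:4, c("u", "v")]
  fm <- buildFeatureMatrix(net, sigs, ed)
  less <- klessColumns(fm, nodes[2])
  expect_equal(ncol(featureValues(less)), 4L)
  expect_equal(nrow(featureValues(less)), 4L)
  expect_false(any(grepl(nodes[2], colnames(featureValues(less)),
                         fixed = TRUE)))
  ## remaining columns keep their original values
  keep <- setdiff(colnames(featureValues(fm)),
                  paste0(nodes[2], c("+", "-")))
  expect_identical(featureValues(less)[, keep],
                   featureValues(fm)[, keep])
  expect_error(klessColumns(fm, "nope"), "not a knockout")

  masked <- maskSignatureGenes(sigs, c(nodes[2], nodes[6]))
  expect_equal(knockouts(masked), nodes[c(1, 3)])
  expect_equal(upTargets(masked, nodes[1]), nodes[4])
})

test_that("feature matrices persist as TSV with edge keys", {
  net <- assembleBaseNetwork(data.frame(u = c("a", "b"),
                                        v = c("b", "c")))
  sigs <- toySignatures(a = list(up = "c", down = character(0)))
  fm <- suppressMessages(
    buildFeatureMatrix(net, sigs, data.frame(u = "a", v = "b")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureMatrix(fm, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# edge\ta\\+\ta-$")
  expect_match(lines[2], "^a\\|b\t")
})
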
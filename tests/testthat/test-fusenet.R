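test_that("Manhattan array distance matches hand values and is symmetric", {
  ac <- rbind(c(2, 3), c(2, 5), c(0, 0), c(3, 4))
  expect_equal(manhattanDistance(ac, 1, 2), 2)
  expect_equal(manhattanDistance(ac, 3, 4), 7)
  set.seed(1)
  for (i in 1:20) {
    p <- sample(4, 2)
    expect_equal(manhattanDistance(ac, p[1], p[2]),
                 manhattanDistance(ac, p[2], p[1]))
  }
  expect_error(manhattanDistance(ac, 2, 2), "itself")
})

test_that("candidate pairs capture hex neighbors and boundary cases", {
  x <- default_fixture()
  xs <- x[, inTissue(x)]
  pairs <- candidatePairs(xs, NULL, aMax = 2)
  ac <- arrayCoords(xs)
  # an interior spot of a Visium-parity grid: its 6 hex neighbors all sit at
  # array Manhattan distance 2, plus the two spots two rows straight
  # up/down, which share that distance; aMax = 2 therefore yields 8
  interior <- which(ac[, 1] > min(ac[, 1]) + 1 & ac[, 1] < max(ac[, 1]) - 1 &
                    ac[, 2] > min(ac[, 2]) + 2 & ac[, 2] < max(ac[, 2]) - 2)
  i <- interior[1]
  partners <- c(pairs$v[pairs$u == i], pairs$u[pairs$v == i])
  expect_identical(length(partners), 8L)
  hex <- which((abs(ac[, 1] - ac[i, 1]) == 1 & abs(ac[, 2] - ac[i, 2]) == 1) |
               (ac[, 1] == ac[i, 1] & abs(ac[, 2] - ac[i, 2]) == 2))
  expect_true(all(hex %in% partners))
  # aMax = 0 leaves only T edges
  tNet <- edge_network(ncol(xs), u = 1, v = 2, w = 0.5, role = "T")
  only_t <- candidatePairs(xs, tNet, aMax = 0)
  expect_identical(nrow(only_t), 1L)
  # corner spot of a square grid with aMax = 1 has 2 candidates
  sq <- expand.grid(0:3, 0:3)
  colnames(sq) <- c("row", "col")
  p1 <- candidatePairs(as.matrix(sq), NULL, aMax = 1)
  corner <- which(sq$row == 0 & sq$col == 0)
  expect_identical(sum(p1$u == corner) + sum(p1$v == corner), 2L)
})

test_that("fusion computes (H + T I(T>0)) / (2A) on hand examples", {
  ac <- rbind(c(0, 0), c(0, 2), c(1, 1), c(5, 5))
  barcodes <- c("b01", "b02", "b03", "b04")
  hNet <- SimilarityNetwork(
    data.frame(u = c(1, 1, 2), v = c(2, 3, 3), w = c(0.5, 0.5, 0)),
    barcodes, role = "H")
  tNet <- SimilarityNetwork(data.frame(u = 1, v = 2, w = 0.3),
                            barcodes, role = "T")
  pairs <- data.frame(u = c(1, 1, 2), v = c(2, 3, 3))
  s <- fuseNetworks(hNet, tNet, ac, pairs)
  e <- networkEdges(s)
  key <- paste(e$u, e$v)
  expect_equal(e$w[key == "1 2"], 0.8 / 4)      # H=0.5, T=0.3, A=2
  expect_equal(e$w[key == "1 3"], 0.5 / (2 * 2))# T absent: indicator zeroes it
  expect_equal(e$w[key == "2 3"], 0)            # H=0, T=0
  # a candidate pair without an H value is an error
  expect_error(
    fuseNetworks(hNet, tNet, ac, rbind(pairs, data.frame(u = 1, v = 4))),
    "histological")
})

test_that("fusion is monotone in H and T and antitone in A", {
  fuse1 <- function(h, t, a) {
    ac <- rbind(c(0, 0), c(0, a))
    hN <- SimilarityNetwork(data.frame(u = 1, v = 2, w = h),
                            c("b1", "b2"), "H")
    tN <- if (t > 0)
      SimilarityNetwork(data.frame(u = 1, v = 2, w = t), c("b1", "b2"), "T")
    else NULL
    networkEdges(fuseNetworks(hN, tN, ac, data.frame(u = 1, v = 2)))$w
  }
  expect_gt(fuse1(0.9, 0.3, 2), fuse1(0.5, 0.3, 2))
  expect_gt(fuse1(0.5, 0.6, 2), fuse1(0.5, 0.3, 2))
  expect_gt(fuse1(0.5, 0.3, 1), fuse1(0.5, 0.3, 2))
})

test_that("min-max normalization maps weights onto [0, 1] as stated", {
  n3 <- edge_network(4, u = c(1, 1, 2), v = c(2, 3, 4), w = c(0.1, 0.3, 0.5),
                     role = "S")
  e <- networkEdges(minmaxNormalize(n3))
  expect_equal(sort(e$w), c(0.5, 1))            # {0, .5, 1}; zero edge dropped
  expect_identical(nrow(e), 2L)
  already <- edge_network(3, u = c(1, 2), v = c(2, 3), w = c(0, 1), role = "S")
  expect_equal(networkEdges(minmaxNormalize(already))$w, 1)  # 0-edge dropped
  flat <- edge_network(3, u = c(1, 2), v = c(2, 3), w = c(0.4, 0.4),
                       role = "S")
  expect_warning(nf <- minmaxNormalize(flat), "equal")
  expect_equal(networkEdges(nf)$w, c(1, 1))
})

test_that("the fused network on the fixture connects every in-tissue spot", {
  x <- default_fixture()
  res <- cached("net_clean",
                suppressWarnings(buildFusedNetwork(x, seed = 1L)))
  net <- res$network
  e <- networkEdges(net)
  deg <- tabulate(c(e$u[e$w > 0], e$v[e$w > 0]), nbins = net@nSpots)
  expect_true(all(deg >= 1))
  expect_equal(max(e$w), 1)
  expect_true(all(e$w > 0 & e$w <= 1))
})

test_that("sparse and dense fusion give identical partitions on a small sample", {
  spec <- syntheticSpec(nRows = 10L, nCols = 12L, nRegions = 2L,
                        nGenes = 80L, seed = 3L, marginSpots = 1L)
  x <- makeTissue(spec)
  res_sparse <- suppressWarnings(
    clusterSpots(x, nClusters = 2L, seed = 1L, aMax = 2))
  res_dense <- suppressWarnings(
    clusterSpots(x, nClusters = 2L, seed = 1L, aMax = Inf))
  expect_equal(adjustedRandIndex(clusterLabels(res_sparse$partition),
                                 clusterLabels(res_dense$partition)), 1)
})
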
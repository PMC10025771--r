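test_that("log-normalization reproduces direct evaluation and invariances", {
  counts <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "b1"))
  ln <- logNormalize(counts)
  expect_equal(as.vector(ln), c(log(2501), log(2501), log(5001)),
               tolerance = 1e-9)
  # all-zero gene rows stay zero; doubling a spot's counts changes nothing
  counts2 <- cbind(b1 = c(4, 0, 8), b2 = c(8, 0, 16))
  ln2 <- logNormalize(counts2)
  expect_equal(ln2[2, ], c(b1 = 0, b2 = 0))
  expect_equal(ln2[, 1], ln2[, 2], tolerance = 1e-12)
  expect_error(logNormalize(cbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("HVG ranking recovers planted variable genes", {
  set.seed(5)
  n_spots <- 60
  region <- rep(1:3, each = n_spots / 3)
  # flat genes span a range of depths to anchor the mean-variance trend;
  # markers are region-bimodal with their mean inside that range
  mu <- matrix(rep(c(4, 6, 9, 14, 20, 30, 12), length.out = 10), 10, n_spots)
  mu[1, ] <- 4; mu[1, region == 1] <- 28
  mu[2, ] <- 4; mu[2, region == 2] <- 28
  mu[3, ] <- 4; mu[3, region == 3] <- 28
  counts <- matrix(rpois(length(mu), mu), nrow(mu),
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  colnames(counts) <- sprintf("s%02d", seq_len(n_spots))
  ln <- logNormalize(counts)
  expect_setequal(selectHVG(ln, 3), 1:3)
  expect_warning(all_g <- selectHVG(ln, 50), "all genes")
  expect_setequal(all_g, 1:10)
  # order-equivariance under gene permutation
  perm <- sample(10)
  hv_perm <- selectHVG(ln[perm, , drop = FALSE], 3)
  expect_setequal(perm[hv_perm], 1:3)
})

test_that("gene scaling standardizes rows and respects clipping", {
  set.seed(2)
  m <- matrix(rnorm(200, 5, 2), 4, 50)
  z <- scaleGenes(m, clip = Inf)
  expect_equal(rowMeans(z), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(z, 1, sd), rep(1, 4), tolerance = 1e-6)
  zc <- scaleGenes(cbind(m, 1e3), clip = 10)
  expect_lte(max(abs(zc)), 10)
})

test_that("PCA embedding is exact on low-rank input and deterministic", {
  set.seed(4)
  base <- matrix(rnorm(40), 20, 2)
  load <- matrix(rnorm(10), 2, 5)
  X <- t(base %*% load)                           # 5 genes x 20 spots, rank 2
  colnames(X) <- sprintf("s%02d", 1:20)
  expect_warning(pcs <- pcaEmbed(X, nPCs = 5), "reduced")
  v <- apply(pcs, 2, var)
  expect_lt(sum(v[3:4]) / sum(v), 1e-10)
  # duplicated spots share a PC row
  Xd <- cbind(X, X[, 1, drop = FALSE])
  colnames(Xd) <- c(colnames(X), "dup")
  p2 <- suppressWarnings(pcaEmbed(Xd, nPCs = 3))
  expect_equal(p2["s01", ], p2["dup", ], tolerance = 1e-8)
  expect_identical(pcaEmbed(X, nPCs = 2), pcaEmbed(X, nPCs = 2))
})

test_that("PCA scores preserve pairwise geometry of the centered data", {
  set.seed(8)
  X <- t(matrix(rnorm(12 * 4), 12, 4) %*% matrix(rnorm(4 * 6), 4, 6))
  colnames(X) <- sprintf("s%02d", 1:12)            # 6 genes x 12 spots, rank 4
  pcs <- pcaEmbed(X, nPCs = 5)
  Y <- sweep(t(X), 2, colMeans(t(X)))
  # with all informative components kept, score distances = data distances
  expect_equal(as.matrix(dist(pcs)), as.matrix(dist(Y)), tolerance = 1e-8)
})

test_that("SNN Jaccard weights behave on identical spots and separated blobs", {
  set.seed(6)
  blob1 <- matrix(rnorm(40, 0, 0.1), 20, 2)
  blob2 <- matrix(rnorm(40, 50, 0.1), 20, 2)
  pcs <- rbind(blob1, blob2)
  rownames(pcs) <- sprintf("s%02d", 1:40)
  net <- snnGraph(pcs, k = 10, prune = 0)
  e <- networkEdges(net)
  cross <- (e$u <= 20) != (e$v <= 20)
  expect_false(any(cross))           # disjoint neighbor sets: Jaccard 0
  expect_true(all(e$w >= 0 & e$w <= 1))
  # duplicated points share the full neighbor set -> weight 1
  pcs2 <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10), d = c(10, 10.1))
  net2 <- snnGraph(pcs2, k = 2, prune = 0)
  e2 <- networkEdges(net2)
  expect_equal(e2$w[e2$u == 1 & e2$v == 2], 1)
  expect_warning(snnGraph(pcs2, k = 10), "reduced")
})

test_that("SNN keeps well-separated regions internally connected with little leakage", {
  # strong markers: regions clearly separated in expression space
  spec <- syntheticSpec(nRows = 12L, nCols = 14L, nRegions = 3L,
                        nGenes = 120L, markersPerRegion = 20L,
                        markerMean = 25, imageMeans = c(90, 140, 190),
                        marginSpots = 1L, seed = 6L)
  x <- makeTissue(spec)
  xs <- x[, inTissue(x)]
  expr <- suppressWarnings(
    exprNetwork(SummarizedExperiment::assay(xs, "counts"), nHVG = 120))
  e <- networkEdges(expr$network)
  region <- S4Vectors::metadata(x)$region[inTissue(x)]
  cross <- region[e$u] != region[e$v]
  expect_lt(sum(e$w[cross]) / sum(e$w), 0.05)
  # each region's subgraph is connected
  for (r in unique(region)) {
    members <- which(region == r)
    sub <- e[e$u %in% members & e$v %in% members & e$w > 0, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(sub$u, members), to = match(sub$v, members)),
      directed = FALSE, vertices = data.frame(name = seq_along(members)))
    expect_true(igraph::is_connected(g))
  }
})
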
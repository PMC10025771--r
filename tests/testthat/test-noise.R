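test_that("Gaussian kernel matches direct density evaluation", {
  cfg <- NoiseConfig(sigma1 = 4, sigma2 = 4, rho = 0)
  expect_equal(gaussianKernel(c(5, 5), c(5, 5), cfg), 1 / (2 * pi * 16),
               tolerance = 1e-9)
  expect_equal(gaussianKernel(c(4, 0), c(0, 0), cfg),
               exp(-0.5) / (2 * pi * 16), tolerance = 1e-9)
  # symmetric in its arguments; decreasing in distance
  set.seed(2)
  for (i in 1:20) {
    a <- runif(2, 0, 10); b <- runif(2, 0, 10)
    expect_equal(gaussianKernel(a, b, cfg), gaussianKernel(b, a, cfg))
  }
  expect_gt(gaussianKernel(c(1, 0), c(0, 0), cfg),
            gaussianKernel(c(2, 0), c(0, 0), cfg))
  # rho enters through the covariance; |rho| = 1 is rejected up front
  expect_warning(c2 <- NoiseConfig(rho = 1), "clamped")
  expect_equal(c2@rho, 0.99)
})

test_that("diffusion flux follows the total-count difference", {
  expect_equal(diffusionFlux(rep(1, 60), rep(1, 100), phi = 0.3), 12)
  expect_equal(diffusionFlux(c(5, 5), c(7, 3), phi = 0.8), 0)
  expect_equal(diffusionFlux(c(0, 1), c(50, 9), phi = 0), 0)
})

test_that("diffusion conserves mass, fixes phi = 0, and leaks monotonically", {
  x <- default_fixture()
  C <- SummarizedExperiment::assay(x, "counts")
  total <- sum(C)
  off <- !inTissue(x)
  blank <- vapply(seq(0.1, 0.9, by = 0.1), function(phi) {
    xd <- simulateDiffusion(x, NoiseConfig(phi = phi))
    Cd <- SummarizedExperiment::assay(xd, "counts")
    expect_lt(abs(sum(Cd) - total) / total, 1e-9)
    expect_gte(min(Cd), 0)
    sum(Cd[, off]) / sum(Cd)
  }, numeric(1))
  expect_true(all(diff(blank) > 0))
  x0 <- simulateDiffusion(x, NoiseConfig(phi = 0))
  expect_equal(as.matrix(SummarizedExperiment::assay(x0, "counts")),
               as.matrix(C))
  expect_equal(blank[1] > 0, TRUE)
  expect_error(NoiseConfig(phi = 1.2), "phi")
})

test_that("uniform tissue does not diffuse", {
  counts <- matrix(5, 3, 9, dimnames = list(paste0("g", 1:3), NULL))
  x <- tiny_spot_experiment(counts, nrows = 3)
  xd <- simulateDiffusion(x, NoiseConfig(phi = 0.5))
  expect_equal(as.matrix(SummarizedExperiment::assay(xd, "counts")),
               as.matrix(SummarizedExperiment::assay(x, "counts")))
})

test_that("diffusion blurs planted markers' spatial enrichment monotonically", {
  x <- default_fixture()
  mk <- S4Vectors::metadata(x)$marker_genes
  it <- inTissue(x)
  N <- knnAdjacency(x[, it], k = 6)
  score <- vapply(c(0, 0.1, 0.3), function(phi) {
    xd <- if (phi == 0) x else simulateDiffusion(x, NoiseConfig(phi = phi))
    keep <- Matrix::colSums(
      SummarizedExperiment::assay(xd, "counts")[, it]) > 0
    ln <- logNormalize(SummarizedExperiment::assay(xd, "counts")[, it][, keep])
    es <- enrichmentScore(as.matrix(ln), N[keep, keep])
    mean(es[mk])
  }, numeric(1))
  # enrichment decays as diffusion grows until the outflow saturates
  expect_true(all(diff(score) < 0))
  # and every diffused state scores below the clean one
  expect_true(all(score[-1] < score[1]))
})

test_that("dropout zeroes exactly floor(DR * entries) under a seed contract", {
  x <- default_fixture()
  nEntries <- prod(dim(x))
  for (dr in c(0.1, 0.5, 0.9)) {
    xd <- simulateDropout(x, NoiseConfig(dropoutRate = dr, seed = 4L))
    mask <- S4Vectors::metadata(xd)$dropout_mask
    expect_identical(length(mask), as.integer(floor(dr * nEntries)))
    expect_true(all(as.matrix(
      SummarizedExperiment::assay(xd, "counts"))[mask] == 0))
  }
  same <- simulateDropout(x, NoiseConfig(dropoutRate = 0.3, seed = 4L))
  again <- simulateDropout(x, NoiseConfig(dropoutRate = 0.3, seed = 4L))
  other <- simulateDropout(x, NoiseConfig(dropoutRate = 0.3, seed = 5L))
  expect_identical(S4Vectors::metadata(same)$dropout_mask,
                   S4Vectors::metadata(again)$dropout_mask)
  expect_false(identical(S4Vectors::metadata(same)$dropout_mask,
                         S4Vectors::metadata(other)$dropout_mask))
  # DR = 0 is the identity
  x0 <- simulateDropout(x, NoiseConfig(dropoutRate = 0))
  expect_equal(as.matrix(SummarizedExperiment::assay(x0, "counts")),
               as.matrix(SummarizedExperiment::assay(x, "counts")))
})

test_that("degrade chains the two processes and is the identity at zero noise", {
  x <- default_fixture()
  x0 <- degrade(x, NoiseConfig(phi = 0, dropoutRate = 0))
  expect_equal(as.matrix(SummarizedExperiment::assay(x0, "counts")),
               as.matrix(SummarizedExperiment::assay(x, "counts")))
  xboth <- degrade(x, NoiseConfig(phi = 0.3, dropoutRate = 0.5, seed = 2L))
  expect_identical(length(S4Vectors::metadata(xboth)$dropout_mask),
                   as.integer(floor(0.5 * prod(dim(x)))))
  xdiff <- degrade(x, NoiseConfig(phi = 0.3, dropoutRate = 0))
  expect_lt(abs(sum(SummarizedExperiment::assay(xdiff, "counts")) -
                sum(SummarizedExperiment::assay(x, "counts"))) /
            sum(SummarizedExperiment::assay(x, "counts")), 1e-9)
})
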
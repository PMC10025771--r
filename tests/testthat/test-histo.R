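test_that("grayscale conversion uses BT.601 luminance weights", {
  white <- array(255, dim = c(2, 2, 3))
  expect_equal(toGrayscale(white)@pixels, matrix(255, 2, 2))
  red <- array(0, dim = c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(toGrayscale(red)@pixels[1, 1], 0.299 * 255)
  gray <- matrix(runif(12, 0, 255), 3, 4)
  expect_identical(toGrayscale(gray)@pixels, gray)
  expect_error(toGrayscale(array(0, dim = c(2, 2, 2))), "RGB")
})

test_that("foreground mixture recovers a well-separated bimodal split", {
  set.seed(42)
  n <- 120
  truth <- matrix(rep(c(TRUE, FALSE), each = n * n / 2), n, n)
  px <- matrix(0, n, n)
  px[truth] <- rnorm(sum(truth), 60, 12)
  px[!truth] <- rnorm(sum(!truth), 230, 12)
  img <- foregroundMask(HistoImage(px))
  midpoint <- px < 145
  expect_gt(mean(img@foreground == midpoint), 0.99)
  expect_gt(mean(img@foreground == truth), 0.99)
  # inverting intensities flips the mask (darker component is foreground)
  inv <- foregroundMask(HistoImage(255 - px))
  expect_gt(mean(inv@foreground == !img@foreground), 0.99)
})

test_that("constant image yields an all-foreground mask with a warning", {
  expect_warning(img <- foregroundMask(HistoImage(matrix(128, 10, 10))),
                 "constant")
  expect_true(all(img@foreground))
})

test_that("MRF segmentation labels a noise-free two-tone image exactly", {
  px <- matrix(50, 40, 40)
  px[, 21:40] <- 200
  img <- HistoImage(px, foreground = matrix(TRUE, 40, 40))
  f <- mrfSegment(img, K = 2, beta = 1, seed = 1)
  lab <- f@labels
  expect_identical(length(unique(lab[px == 50])), 1L)
  expect_identical(length(unique(lab[px == 200])), 1L)
  expect_false(lab[1, 1] == lab[1, 40])
})

test_that("MRF denoises beyond its K-means initialization", {
  set.seed(7)
  n <- 80
  truth <- matrix(1L, n, n)
  truth[, (n / 2 + 1):n] <- 2L
  px <- matrix(rnorm(n * n, c(50, 200)[truth], 20), n, n)
  outliers <- sample(n * n, round(0.01 * n * n))
  px[outliers] <- sample(c(0, 255), length(outliers), replace = TRUE)
  img <- HistoImage(px, foreground = matrix(TRUE, n, n))
  # beta on the scale of the outliers' emission log-likelihood gap
  f <- mrfSegment(img, K = 2, beta = 10, seed = 1)
  agree <- function(lab) {            # align labels to truth
    a <- mean(lab == truth)
    max(a, 1 - a)
  }
  mrf_agree <- agree(f@labels)
  km_agree <- agree(attr(f, "init"))
  expect_gte(mrf_agree, 0.99)
  expect_gt(mrf_agree, km_agree)
})

test_that("beta = 0 reduces to hard Gaussian-mixture assignment", {
  set.seed(3)
  px <- matrix(rnorm(900, rep(c(60, 180), each = 450), 15), 30, 30)
  img <- HistoImage(px, foreground = matrix(TRUE, 30, 30))
  f <- mrfSegment(img, K = 2, beta = 0, maxIter = 50, seed = 1)
  emis <- vapply(1:2, function(k)
    dnorm(as.vector(px), f@clusterMeans[k], sqrt(f@clusterVars[k]),
          log = TRUE), numeric(900))
  expect_identical(as.vector(f@labels), max.col(emis, ties.method = "first"))
})

test_that("EM iterations never increase the Potts energy", {
  set.seed(9)
  px <- matrix(rnorm(1600, rep(c(70, 170), each = 800), 20), 40, 40)
  img <- HistoImage(px, foreground = matrix(TRUE, 40, 40))
  energies <- vapply(1:4, function(iters) {
    f <- mrfSegment(img, K = 3, beta = 1, maxIter = iters, seed = 1)
    mrfEnergy(f, img)
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-8))
})

test_that("segmentation is deterministic under a fixed seed and guards K", {
  px <- matrix(rep(c(10, 90, 200), length.out = 400), 20, 20)
  img <- HistoImage(px, foreground = matrix(TRUE, 20, 20))
  f1 <- mrfSegment(img, K = 3, beta = 0.5, seed = 5)
  f2 <- mrfSegment(img, K = 3, beta = 0.5, seed = 5)
  expect_identical(f1@labels, f2@labels)
  expect_warning(fr <- mrfSegment(img, K = 10, seed = 1), "reduced")
  expect_identical(fr@K, 3L)
  expect_error(mrfSegment(img, K = 1), "K must be")
  empty <- HistoImage(px, foreground = matrix(FALSE, 20, 20))
  expect_error(mrfSegment(empty, K = 2), "foreground")
})

test_that("spot label distributions live on the simplex with known geometry", {
  # 40x40 image: left half label 1, right half label 2
  lab <- matrix(1L, 40, 40)
  lab[, 21:40] <- 2L
  field <- new("PixelLabelField", labels = lab, K = 4L,
               clusterMeans = 1:4 * 50, clusterVars = rep(1, 4),
               beta = 1, nIter = 1L)
  counts <- matrix(1, 2, 3)
  pos <- data.frame(barcode = c("in1", "straddle", "bg"),
                    in_tissue = 1L, array_row = 0:2, array_col = 0L,
                    pxl_row = c(20, 20, 20), pxl_col = c(8, 19.5, 300))
  pos$pxl_col[3] <- 35                       # will be moved onto background
  x <- SpotExperiment(counts, pos, spotDiameter = 10)
  lab[, 30:40] <- 0L                         # background area under spot 3
  field@labels <- lab
  w <- spotLabelDistribution(field, x)
  expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-9)
  expect_equal(w[1, ], c(1, 0, 0, 0))        # fully inside label 1
  npix <- sum(lab[15:26, 15:25] > 0)         # straddling spot: ~half/half
  expect_lte(abs(w[2, 1] - w[2, 2]), 2 / max(1, npix) + 0.1)
  expect_equal(w[3, ], rep(0.25, 4))         # pure background: uniform
  expect_identical(attr(w, "noForeground"), c(FALSE, FALSE, TRUE))
})

test_that("symmetric KL matches hand-derived values and is symmetric", {
  expect_equal(symmetricKL(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-9)
  L <- symmetricKL(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(L, 0.6 * log(4), tolerance = 1e-6)
  set.seed(1)
  for (i in 1:100) {
    a <- stats::runif(5); a <- a / sum(a)
    b <- stats::runif(5); b <- b / sum(b)
    expect_equal(symmetricKL(a, b), symmetricKL(b, a), tolerance = 1e-12)
    expect_gte(symmetricKL(a, b), 0)
  }
  expect_error(symmetricKL(c(0.5, 0.5), c(1, 0, 0)), "equal length")
})

test_that("histological network applies the 1 - min(1, L) transform", {
  w <- rbind(a = c(0.8, 0.2), b = c(0.2, 0.8), c = c(0.8, 0.2),
             d = c(0.999, 0.001))
  pairs <- data.frame(u = c(1, 1, 2), v = c(3, 2, 4))
  net <- histoNetwork(w, pairs)
  e <- networkEdges(net)
  key <- paste(e$u, e$v)
  expect_equal(e$w[key == "1 3"], 1, tolerance = 1e-9)        # L = 0
  expect_equal(e$w[key == "1 2"], 1 - 0.6 * log(4), tolerance = 1e-6)
  expect_equal(e$w[key == "2 4"], 0, tolerance = 1e-6)        # L > 1 clamps
  expect_true(all(e$w >= 0 & e$w <= 1))
})
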
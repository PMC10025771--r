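## Simulators for the two dominant noise processes of capture-based spatial
## transcriptomics: molecular diffusion during permeabilization (Fick's first
## law with a bivariate Gaussian spatial kernel) and dropout (uniformly
## zeroed expression entries).

#' Bivariate Gaussian spatial kernel
#'
#' Density of a centered bivariate normal with covariance built from
#' (sigma1, sigma2, rho), evaluated at the displacement u - u0 (array
#' units): (2 pi)^-1 |Sigma|^-1/2 exp(-1/2 d' Sigma^-1 d). Strictly
#' decreasing in Mahalanobis distance and symmetric in its two arguments.
#'
#' @param u,u0 coordinate matrices (rows = points, columns = row/col) or
#'   length-2 vectors; recycled against each other.
#' @param cfg a \linkS4class{NoiseConfig} supplying sigma1, sigma2, rho.
#' @return numeric vector of kernel values.
#' @export
gaussianKernel <- function(u, u0, cfg) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  if (is.null(dim(u0))) u0 <- matrix(u0, ncol = 2)
  s1 <- cfg@sigma1; s2 <- cfg@sigma2; rho <- cfg@rho
  det_ <- s1^2 * s2^2 * (1 - rho^2)
  if (det_ <= 0) stop("kernel covariance is not positive definite")
  d1 <- u[, 1] - u0[, 1]
  d2 <- u[, 2] - u0[, 2]
  q <- (d1^2 / s1^2 - 2 * rho * d1 * d2 / (s1 * s2) + d2^2 / s2^2) /
    (1 - rho^2)
  exp(-q / 2) / (2 * pi * sqrt(det_))
}

#' Diffusion flux between two spots
#'
#' J = phi * (||C_u0||_1 - ||C_u||_1): proportional to the total-UMI
#' difference, positive when the source holds more material than the target.
#'
#' @param cU,cU0 count vectors of the target and source spot.
#' @param phi diffusion rate.
#' @return numeric(1) flux (sign gives direction).
#' @export
diffusionFlux <- function(cU, cU0, phi) {
  phi * (sum(cU0) - sum(cU))
}

#' Simulate permeabilization diffusion
#'
#' Every spot sheds material toward nearby spots with lower total counts.
#' For a source u0 and lower-count target u, the raw pair transfer is
#' J(u, u0) * k_G(u, u0) * C_u0 (flux times spatial kernel times the
#' source's gene composition), computed from the ORIGINAL counts so pair
#' ordering is irrelevant. Because the raw flux carries count units, the
#' summed outflow of a spot can exceed its content; the total outflow
#' fraction is therefore passed through the saturating map
#' 1 - exp(-raw fraction), which agrees with the raw sum when transfers are
#' small, never overdraws a spot, and keeps the transferred mass strictly
#' increasing in \code{phi}. Off-tissue spots take part as targets (they
#' hold no material, so they are never sources), which is how blank-area
#' UMIs arise. Mass is conserved exactly; output counts are real-valued
#' unless \code{round = TRUE}.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param cfg a \linkS4class{NoiseConfig}; \code{phi = 0} returns the input
#'   unchanged.
#' @param truncation pairs farther apart (Euclidean, array units) than this
#'   multiple of max(sigma1, sigma2) are skipped.
#' @param round round the diffused counts to integers (breaks exact mass
#'   conservation; default off).
#' @return a \linkS4class{SpotExperiment} with diffused counts.
#' @export
simulateDiffusion <- function(x, cfg, truncation = 3, round = FALSE) {
  stopifnot(is(x, "SpotExperiment"), is(cfg, "NoiseConfig"))
  phi <- cfg@phi
  counts <- SummarizedExperiment::assay(x, "counts")
  if (phi == 0) return(x)
  ac <- arrayCoords(x)
  n <- ncol(counts)
  totals <- Matrix::colSums(counts)
  maxd <- truncation * max(cfg@sigma1, cfg@sigma2)
  d <- as.matrix(stats::dist(ac))
  idx <- which(upper.tri(d) & d <= maxd, arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  # orient every pair source -> target (higher total -> lower total)
  hi <- ifelse(totals[a] >= totals[b], a, b)
  lo <- ifelse(totals[a] >= totals[b], b, a)
  keep <- totals[hi] > totals[lo]
  src <- hi[keep]; tgt <- lo[keep]
  kg <- gaussianKernel(ac[tgt, , drop = FALSE], ac[src, , drop = FALSE], cfg)
  s <- phi * (totals[src] - totals[tgt]) * kg    # raw per-pair fraction
  rawOut <- as.numeric(tapply(s, factor(src, levels = seq_len(n)), sum))
  rawOut[is.na(rawOut)] <- 0
  outFrac <- 1 - exp(-rawOut)
  # redistribution matrix: rows are sources, row-stochastic by construction
  share <- as.numeric(s / rawOut[src])
  M <- Matrix::sparseMatrix(i = src, j = tgt, x = outFrac[src] * share,
                            dims = c(n, n))
  Matrix::diag(M) <- 1 - outFrac
  newCounts <- as(counts %*% M, "CsparseMatrix")
  if (round) newCounts <- Matrix::drop0(base::round(newCounts))
  dimnames(newCounts) <- dimnames(counts)
  SummarizedExperiment::assay(x, "counts", withDimnames = FALSE) <- newCounts
  x
}

#' Simulate dropout
#'
#' Zeroes floor(dropoutRate * entries) uniformly sampled entries of the
#' count matrix (without replacement), reproducibly under the config seed.
#' The linear indices of the zeroed entries are stored in
#' \code{metadata(x)$dropout_mask} for evaluation.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param cfg a \linkS4class{NoiseConfig}; uses \code{dropoutRate} and
#'   \code{seed}.
#' @return a \linkS4class{SpotExperiment} with dropout applied.
#' @export
simulateDropout <- function(x, cfg) {
  stopifnot(is(x, "SpotExperiment"), is(cfg, "NoiseConfig"))
  dr <- cfg@dropoutRate
  counts <- SummarizedExperiment::assay(x, "counts")
  nEntries <- prod(dim(counts))
  m <- floor(dr * nEntries)
  if (m == 0) {
    S4Vectors::metadata(x)$dropout_mask <- integer(0)
    return(x)
  }
  set.seed(cfg@seed)
  mask <- sample.int(nEntries, m)
  dense <- as.matrix(counts)
  dense[mask] <- 0
  newCounts <- as(as(as(dense, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(newCounts) <- dimnames(counts)
  SummarizedExperiment::assay(x, "counts", withDimnames = FALSE) <- newCounts
  S4Vectors::metadata(x)$dropout_mask <- mask
  x
}
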
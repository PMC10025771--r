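## Histopathological feature extraction.
##
## The H&E slide is reduced to grayscale, tissue foreground is separated from
## the bright slide background by a two-component Gaussian mixture on the
## intensity histogram, and foreground pixels are grouped into K intensity
## clusters by a Markov random field: Gaussian emissions per cluster plus a
## Potts smoothness term over the 8-pixel neighborhood, fitted by
## hard-assignment EM (iterated conditional modes alternating with closed-form
## Gaussian updates). Each spot is then summarized by the label distribution
## of the foreground pixels it covers, and spots are compared by symmetric
## Kullback-Leibler divergence.

#' Convert an image to grayscale
#'
#' RGB input is collapsed with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114); grayscale input passes through unchanged.
#'
#' @param x a height x width intensity matrix or height x width x 3 RGB array.
#' @param maxval intensity ceiling of the input (255 or 1).
#' @return A \linkS4class{HistoImage}.
#' @export
toGrayscale <- function(x, maxval = 255) {
  nd <- length(dim(x))
  if (nd == 2L) {
    return(new("HistoImage", pixels = as.matrix(x), maxval = maxval))
  }
  if (nd != 3L || dim(x)[3] < 3L)
    stop("expected a 2-D matrix or a height x width x 3 RGB array")
  px <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  px <- matrix(px, dim(x)[1], dim(x)[2])
  new("HistoImage", pixels = px, maxval = maxval)
}

#' Segment tissue foreground by a two-component Gaussian mixture
#'
#' Fits a two-component univariate Gaussian mixture to the intensity
#' distribution and marks pixels assigned to the darker component as
#' foreground: stained tissue absorbs light while bare slide is bright. A
#' constant image yields an all-foreground mask with a warning.
#'
#' @param img a \linkS4class{HistoImage}.
#' @param maxFitPixels intensities are subsampled to at most this many values
#'   for the mixture fit; all pixels are then classified with the fitted
#'   parameters.
#' @return The image with its \code{foreground} slot filled.
#' @export
foregroundMask <- function(img, maxFitPixels = 50000L) {
  stopifnot(is(img, "HistoImage"))
  y <- as.vector(img@pixels)
  if (stats::sd(y) == 0) {
    warning("constant-intensity image: marking all pixels foreground")
    img@foreground <- matrix(TRUE, nrow(img@pixels), ncol(img@pixels))
    return(img)
  }
  ys <- if (length(y) > maxFitPixels) {
    # deterministic stride subsample keeps the fit reproducible
    y[seq(1L, length(y), length.out = maxFitPixels)]
  } else y
  fit <- mclust::Mclust(ys, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sd2 <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd2) == 1L) sd2 <- rep(sd2, 2L)
  pro <- fit$parameters$pro
  ll <- vapply(1:2, function(k)
    log(pro[k]) + stats::dnorm(y, mu[k], pmax(sd2[k], 1e-6), log = TRUE),
    numeric(length(y)))
  dark <- which.min(mu)
  img@foreground <- matrix(ll[, dark] >= ll[, -dark],
                           nrow(img@pixels), ncol(img@pixels))
  img
}

## 8 (or 4 / 24) neighborhood offsets
.nb_offsets <- function(order = 8L) {
  o4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  o8 <- rbind(o4, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  if (order == 4L) return(o4)
  if (order == 8L) return(o8)
  if (order == 24L) {
    g <- as.matrix(expand.grid(dr = -2:2, dc = -2:2))
    return(g[!(g[, 1] == 0 & g[, 2] == 0), , drop = FALSE])
  }
  stop("neighborhood order must be 4, 8, or 24")
}

## per-foreground-pixel count of like-labeled neighbors for every label:
## returns n_fg x K matrix
.neighbor_label_counts <- function(lab, fgIdx, K, offsets) {
  H <- nrow(lab); W <- ncol(lab)
  n <- length(fgIdx)
  N <- matrix(0, n, K)
  rr <- ((fgIdx - 1L) %% H) + 1L
  cc <- ((fgIdx - 1L) %/% H) + 1L
  for (s in seq_len(nrow(offsets))) {
    r2 <- rr + offsets[s, 1]
    c2 <- cc + offsets[s, 2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- integer(n)
    nb[ok] <- lab[cbind(r2[ok], c2[ok])]
    hit <- which(nb > 0L)
    if (length(hit))
      N[cbind(hit, nb[hit])] <- N[cbind(hit, nb[hit])] + 1
  }
  N
}

.emission_loglik <- function(y, mu, v) {
  K <- length(mu)
  out <- matrix(0, length(y), K)
  for (k in seq_len(K))
    out[, k] <- -0.5 * log(2 * pi * v[k]) - (y - mu[k])^2 / (2 * v[k])
  out
}

#' MRF segmentation of the image foreground
#'
#' Labels are initialized by 1-D K-means on the foreground intensities, then
#' refined by iterated conditional modes: each pixel takes the label
#' maximizing its Gaussian emission log-likelihood plus \code{beta} times the
#' number of like-labeled neighbors, with updates scheduled over a 4-coloring
#' of the lattice so every accepted move lowers the Potts energy. After each
#' sweep the cluster means and variances are re-estimated in closed form
#' (variances floored at 1e-4); clusters left empty are re-seeded at the
#' pixel with the lowest current likelihood. Iteration stops when fewer than
#' \code{tol} of the foreground pixels change label, or at \code{maxIter}.
#'
#' @param img a \linkS4class{HistoImage} with a foreground mask (computed
#'   with \code{\link{foregroundMask}} if absent).
#' @param K number of pixel clusters (reduced with a warning if the image has
#'   fewer distinct foreground intensities).
#' @param beta Potts smoothness weight; 0 recovers a plain hard-assignment
#'   Gaussian mixture.
#' @param neighborhood 4, 8 or 24; 8 is the default lattice neighborhood.
#' @param maxIter maximum ICM/EM sweeps.
#' @param tol stop when the fraction of label changes falls below this.
#' @param maxSide images with a longer side are block-averaged down to at
#'   most this many pixels before segmentation (labels are returned at the
#'   working resolution together with the downscale factor).
#' @param seed RNG seed (the procedure is deterministic given the seed).
#' @return A \linkS4class{PixelLabelField}; the attribute \code{"downscale"}
#'   records the integer block size used (1 = native resolution) and
#'   \code{"init"} the K-means initialization label matrix. Note that
#'   \code{beta} trades off against the Gaussian emission precision: on 8-bit
#'   intensities with within-cluster variance around v, pairwise smoothing
#'   only overrides an outlying pixel once \code{beta} times the neighbor
#'   count is comparable to the emission log-likelihood gap (roughly
#'   (intensity gap)^2 / 2v).
#' @export
mrfSegment <- function(img, K = 50L, beta = 1.0, neighborhood = 8L,
                       maxIter = 30L, tol = 0.001, maxSide = 2000L,
                       seed = 1L) {
  stopifnot(is(img, "HistoImage"))
  if (K < 2L) stop("K must be >= 2")
  if (is.null(img@foreground)) img <- foregroundMask(img)
  factor <- max(1L, as.integer(ceiling(max(dim(img@pixels)) / maxSide)))
  px <- img@pixels
  fg <- img@foreground
  if (factor > 1L) {
    px <- .block_mean(px, factor)
    fg <- .block_mean((fg + 0), factor) >= 0.5
  }
  fgIdx <- which(fg)
  if (!length(fgIdx)) stop("empty foreground: nothing to segment")
  y <- px[fgIdx]
  K <- as.integer(K)
  ndist <- length(unique(y))
  if (K > ndist) {
    warning("K reduced from ", K, " to ", ndist,
            " distinct foreground intensities")
    K <- ndist
  }
  if (K < 2L) stop("fewer than 2 distinct foreground intensities")
  set.seed(seed)

  # 1-D K-means init with spread (unique-quantile) centers: deterministic
  ys <- sort(unique(y))
  centers <- ys[unique(as.integer(round(seq(1, length(ys), length.out = K))))]
  km <- stats::kmeans(y, centers = matrix(centers, ncol = 1), iter.max = 50L)
  labv <- km$cluster

  offsets <- .nb_offsets(as.integer(neighborhood))
  H <- nrow(px); W <- ncol(px)
  lab <- matrix(0L, H, W)
  lab[fgIdx] <- labv
  init <- lab
  rr <- ((fgIdx - 1L) %% H) + 1L
  cc <- ((fgIdx - 1L) %/% H) + 1L
  phase <- (rr %% 2L) * 2L + (cc %% 2L)          # 4-coloring of the lattice

  mu <- v <- numeric(K)
  update_params <- function(labv, y) {
    for (k in seq_len(K)) {
      yk <- y[labv == k]
      if (!length(yk)) { mu[k] <<- NA; v[k] <<- NA; next }
      mu[k] <<- mean(yk)
      v[k] <<- max(stats::var(yk), 1e-4)
      if (is.na(v[k])) v[k] <<- 1e-4              # singleton cluster
    }
    # re-seed empty clusters at the worst-explained pixel
    emis <- .emission_loglik(y, ifelse(is.na(mu), mean(y), mu),
                             ifelse(is.na(v), 1e-4, v))
    for (k in which(is.na(mu))) {
      best <- apply(emis, 1, max)
      worst <- which.min(best)
      mu[k] <<- y[worst]; v[k] <<- 1e-4
    }
  }
  update_params(labv, y)

  it <- 0L
  repeat {
    it <- it + 1L
    emis <- .emission_loglik(y, mu, v)
    old <- labv
    for (p in 0:3) {
      sel <- which(phase == p)
      if (!length(sel)) next
      Nc <- .neighbor_label_counts(lab, fgIdx, K, offsets)
      score <- emis[sel, , drop = FALSE] + beta * Nc[sel, , drop = FALSE]
      newl <- max.col(score, ties.method = "first")
      labv[sel] <- newl
      lab[fgIdx[sel]] <- newl
    }
    changed <- mean(labv != old)
    update_params(labv, y)
    if (changed < tol || it >= maxIter) break
  }

  field <- new("PixelLabelField", labels = lab, K = K, clusterMeans = mu,
               clusterVars = v, beta = beta, nIter = it)
  attr(field, "downscale") <- factor
  attr(field, "init") <- init
  field
}

.block_mean <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / f); W2 <- ceiling(W / f)
  # pad by edge replication to a multiple of f, then average f x f blocks
  mp <- m[pmin(rep(seq_len(H2 * f)), H), pmin(rep(seq_len(W2 * f)), W)]
  dim(mp) <- c(f, H2, f, W2)
  apply(mp, c(2, 4), mean)
}

#' Potts-model energy of a label field
#'
#' Negative pseudo-likelihood: minus the summed Gaussian emission
#' log-likelihood minus beta times the number of like-labeled neighbor pairs
#' (each pair counted once). Used to verify that ICM sweeps never increase
#' the energy.
#'
#' @param field a \linkS4class{PixelLabelField}.
#' @param img the segmented \linkS4class{HistoImage} (at the field's working
#'   resolution).
#' @param neighborhood 4, 8 or 24.
#' @return numeric(1) energy.
#' @export
mrfEnergy <- function(field, img, neighborhood = 8L) {
  lab <- field@labels
  fgIdx <- which(lab > 0L)
  y <- img@pixels[fgIdx]
  labv <- lab[fgIdx]
  emis <- .emission_loglik(y, field@clusterMeans, field@clusterVars)
  e_data <- sum(emis[cbind(seq_along(fgIdx), labv)])
  Nc <- .neighbor_label_counts(lab, fgIdx, field@K,
                               .nb_offsets(as.integer(neighborhood)))
  e_pair <- sum(Nc[cbind(seq_along(fgIdx), labv)]) / 2
  -(e_data + field@beta * e_pair)
}

#' Spot-level pixel label distributions
#'
#' For every spot, counts the MRF labels of the foreground pixels within
#' radius \code{spotDiameter/2} (Euclidean, in working-resolution pixels) of
#' the spot center and normalizes to a probability vector. Spots covering no
#' foreground pixel receive the uniform distribution and are flagged.
#'
#' @param field a \linkS4class{PixelLabelField} from \code{\link{mrfSegment}}.
#' @param x the \linkS4class{SpotExperiment} the image belongs to.
#' @param spots optional integer/logical index of spots to summarize
#'   (default: all).
#' @return a spots x K matrix on the probability simplex, rownames =
#'   barcodes, with a logical attribute \code{"noForeground"} flagging the
#'   uniform-fallback spots.
#' @export
spotLabelDistribution <- function(field, x, spots = seq_len(ncol(x))) {
  stopifnot(is(field, "PixelLabelField"), is(x, "SpotExperiment"))
  f <- attr(field, "downscale")
  if (is.null(f)) f <- 1L
  lab <- field@labels
  K <- field@K
  pc <- pixelCoords(x)[spots, , drop = FALSE] / f
  radius <- spotDiameter(x) / (2 * f)
  if (!is.finite(radius) || radius <= 0)
    stop("spotDiameter must be a positive number")
  H <- nrow(lab); W <- ncol(lab)
  n <- nrow(pc)
  w <- matrix(0, n, K, dimnames = list(rownames(pc), NULL))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    r0 <- pc[i, 1]; c0 <- pc[i, 2]
    rs <- max(1L, floor(r0 + 1 - radius)):min(H, ceiling(r0 + 1 + radius))
    cs <- max(1L, floor(c0 + 1 - radius)):min(W, ceiling(c0 + 1 + radius))
    sub <- lab[rs, cs, drop = FALSE]
    dr <- (rs - 1) - r0
    dc <- (cs - 1) - c0
    inside <- outer(dr^2, dc^2, "+") <= radius^2
    labs <- sub[inside & sub > 0L]
    if (!length(labs)) {
      w[i, ] <- 1 / K
      flagged[i] <- TRUE
    } else {
      tab <- tabulate(labs, nbins = K)
      w[i, ] <- tab / sum(tab)
    }
  }
  attr(w, "noForeground") <- flagged
  w
}

#' Symmetric Kullback-Leibler divergence between label distributions
#'
#' The average of the two directed KL divergences (natural log). Both
#' distributions are mixed with \code{eps} pseudo-mass and renormalized
#' before the logs, so zero entries stay finite.
#'
#' @param wu,wv probability vectors of equal length.
#' @param eps pseudo-probability added to every entry.
#' @return numeric(1) >= 0; 0 iff the distributions coincide.
#' @export
symmetricKL <- function(wu, wv, eps = 1e-10) {
  if (length(wu) != length(wv))
    stop("distributions must have equal length")
  wu <- (wu + eps) / sum(wu + eps)
  wv <- (wv + eps) / sum(wv + eps)
  (sum(wu * log(wu / wv)) + sum(wv * log(wv / wu))) / 2
}

#' Histopathological similarity network
#'
#' Edge weights are \code{H = 1 - min(1, L)} where L is the symmetric KL
#' divergence between the two spots' label distributions: identical
#' distributions give weight 1, divergence >= 1 gives weight 0.
#'
#' @param w spots x K label-distribution matrix from
#'   \code{\link{spotLabelDistribution}}.
#' @param pairs data.frame with integer columns u, v of spot index pairs
#'   (indices into the rows of \code{w}); no self-pairs.
#' @param eps KL pseudo-probability.
#' @return A \linkS4class{SimilarityNetwork} with role "H".
#' @export
histoNetwork <- function(w, pairs, eps = 1e-10) {
  stopifnot(all(pairs$u != pairs$v))
  K <- ncol(w)
  wn <- (w + eps) / (rowSums(w) + K * eps)
  lw <- log(wn)
  # L(u,v) = 0.5 * sum (wu - wv) (log wu - log wv), vectorized over pairs
  du <- wn[pairs$u, , drop = FALSE] - wn[pairs$v, , drop = FALSE]
  dl <- lw[pairs$u, , drop = FALSE] - lw[pairs$v, , drop = FALSE]
  L <- rowSums(du * dl) / 2
  SimilarityNetwork(data.frame(u = pairs$u, v = pairs$v,
                               w = 1 - pmin(1, L)),
                    barcodes = rownames(w), role = "H")
}
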
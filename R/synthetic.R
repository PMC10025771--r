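## Fully self-contained Visium-like fixtures: a textured grayscale slide, a
## hex (Visium parity) or square spot grid with an off-tissue margin, planted
## expression regions, and ground-truth labels. The count model is the
## simplest one exhibiting the sparsity and depth variation the method must
## tolerate: per-spot depth factors from a negative binomial, Poisson
## sampling around region-marker means over a flat background. Image
## textures are intensity-shifted Gaussian noise fields whose per-region
## distributions overlap, so segmentation is genuinely exercised.

#' Construct a SyntheticSpec
#'
#' Defaults describe the standard fixture: a 20 x 25 hex grid (500 spots,
#' off-tissue margin 2), 4 Voronoi regions, 200 genes of which 10 per region
#' are markers with mean count 5 over a background of 1, negative-binomial
#' depth factors (size 10 around mean 100), region image intensities
#' (80, 120, 160, 200) with noise sd 18 on a bright (235) slide.
#'
#' @param nRows,nCols spot grid size.
#' @param grid "hex" (Visium row/col parity) or "square".
#' @param nRegions,nGenes,markersPerRegion,markerMean,backgroundMean count
#'   model; see \linkS4class{SyntheticSpec}.
#' @param depthSize,depthMean negative-binomial depth parameters.
#' @param imageMeans,imageSd per-region image intensity model (0-255).
#' @param marginSpots off-tissue margin width in spots.
#' @param seed RNG seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nRows = 20L, nCols = 25L, grid = "hex",
                          nRegions = 4L, nGenes = 200L,
                          markersPerRegion = 10L, markerMean = 5,
                          backgroundMean = 1, depthSize = 10,
                          depthMean = 100,
                          imageMeans = seq(80, 200, length.out = nRegions),
                          imageSd = 18, marginSpots = 2L, seed = 0L) {
  new("SyntheticSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      grid = grid, nRegions = as.integer(nRegions),
      nGenes = as.integer(nGenes),
      markersPerRegion = as.integer(markersPerRegion),
      markerMean = markerMean, backgroundMean = backgroundMean,
      depthSize = depthSize, depthMean = depthMean, imageMeans = imageMeans,
      imageSd = imageSd, marginSpots = as.integer(marginSpots),
      seed = as.integer(seed))
}

#' Generate a synthetic tissue sample
#'
#' Emits a \linkS4class{SpotExperiment} with (1) a grayscale image in which
#' each planted region carries its own noisy intensity distribution on a
#' bright slide background, (2) the spot grid with array and pixel
#' coordinates and an off-tissue margin, (3) Poisson counts with
#' region-marker means and negative-binomial depth variation (off-tissue
#' spots are empty), and (4) ground-truth region labels in
#' \code{metadata(x)$region} (NA off tissue). Marker genes are the first
#' \code{nRegions * markersPerRegion} rows, region by region. Fully
#' deterministic given the spec seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir optional path: when given, the sample is also written as a
#'   Visium-style directory via \code{\link{writeVisium}}.
#' @return A \linkS4class{SpotExperiment}.
#' @export
makeTissue <- function(spec = syntheticSpec(), dir = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed)
  nR <- spec@nRows; nC <- spec@nCols
  hex <- spec@grid == "hex"
  grid <- expand.grid(r = seq_len(nR) - 1L, c = seq_len(nC) - 1L)
  array_row <- grid$r
  # Visium parity: array_col shares the parity of array_row, step 2 per
  # column; square grids use plain columns
  array_col <- if (hex) 2L * grid$c + (grid$r %% 2L) else grid$c
  sy <- 10; sx <- if (hex) 6 else 12
  margin_px <- 18
  pxl_row <- margin_px + array_row * sy
  pxl_col <- margin_px + array_col * sx
  n <- nrow(grid)
  m <- spec@marginSpots
  in_tissue <- grid$r >= m & grid$r < nR - m & grid$c >= m & grid$c < nC - m

  # Voronoi regions from centers sampled among in-tissue spots (pixel space)
  it_idx <- which(in_tissue)
  centers <- it_idx[sample.int(length(it_idx), spec@nRegions)]
  d2c <- outer(pxl_row, pxl_row[centers], function(a, b) (a - b)^2) +
    outer(pxl_col, pxl_col[centers], function(a, b) (a - b)^2)
  region_all <- max.col(-d2c, ties.method = "first")
  region <- ifelse(in_tissue, region_all, NA_integer_)

  # image: bright slide, per-region textured tissue under the in-tissue spots
  H <- 2 * margin_px + (nR - 1) * sy
  W <- 2 * margin_px + max(array_col) * sx
  img <- matrix(stats::rnorm(H * W, 235, 8), H, W)
  rgrid <- matrix(0L, H, W)          # pixel-level region id, 0 = slide
  rad <- 1.1 * max(sx * (1 + hex), sy) / 2 + 1
  for (i in it_idx) {
    rs <- max(1, round(pxl_row[i] + 1 - rad)):min(H, round(pxl_row[i] + 1 + rad))
    cs <- max(1, round(pxl_col[i] + 1 - rad)):min(W, round(pxl_col[i] + 1 + rad))
    rgrid[rs, cs] <- region_all[i]
  }
  tis <- which(rgrid > 0L)
  img[tis] <- stats::rnorm(length(tis), spec@imageMeans[rgrid[tis]],
                           spec@imageSd)
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)

  # counts: Poisson around depth-scaled region means
  nMark <- spec@nRegions * spec@markersPerRegion
  geneIds <- sprintf("gene%04d", seq_len(spec@nGenes))
  mu <- matrix(spec@backgroundMean, spec@nGenes, n)
  for (rg in seq_len(spec@nRegions)) {
    gsel <- ((rg - 1L) * spec@markersPerRegion + 1L):(rg * spec@markersPerRegion)
    mu[gsel, which(in_tissue & region == rg)] <- spec@markerMean
  }
  depth <- stats::rnbinom(n, size = spec@depthSize, mu = spec@depthMean) /
    spec@depthMean
  depth[depth == 0] <- 1 / spec@depthMean        # no empty in-tissue spot
  counts <- matrix(stats::rpois(spec@nGenes * n, t(t(mu) * depth)),
                   spec@nGenes, n)
  counts[, !in_tissue] <- 0L
  # guard: every in-tissue spot must carry at least one count
  empty <- which(in_tissue & colSums(counts) == 0)
  if (length(empty)) counts[1L, empty] <- 1L

  pos <- data.frame(
    barcode = sprintf("SPOT-%04d", seq_len(n)),
    in_tissue = as.integer(in_tissue),
    array_row = array_row, array_col = array_col,
    pxl_row = pxl_row, pxl_col = pxl_col)
  x <- SpotExperiment(counts, pos, geneIds = geneIds,
                      image = HistoImage(img, maxval = 255),
                      spotDiameter = 9)
  S4Vectors::metadata(x)$region <- region
  S4Vectors::metadata(x)$marker_genes <- geneIds[seq_len(nMark)]
  if (!is.null(dir)) writeVisium(x, dir)
  x
}

#' Apply both noise processes to a sample
#'
#' Chains \code{\link{simulateDiffusion}} and \code{\link{simulateDropout}}
#' under one config; with \code{phi = 0} and \code{dropoutRate = 0} the
#' input is returned unchanged.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param cfg a \linkS4class{NoiseConfig}.
#' @return a \linkS4class{SpotExperiment}; \code{metadata(x)$dropout_mask}
#'   records the zeroed entries when dropout was applied.
#' @export
degrade <- function(x, cfg) {
  x <- simulateDiffusion(x, cfg)
  if (cfg@dropoutRate > 0) x <- simulateDropout(x, cfg)
  x
}
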
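## Reading and writing Visium-style sample directories.
##
## A sample directory holds: matrix.mtx(.gz) + barcodes.tsv(.gz) +
## features.tsv(.gz), a tissue positions CSV in either Space Ranger dialect
## (headered "tissue_positions.csv" or legacy headerless
## "tissue_positions_list.csv"; 6 columns either way), an optional grayscale
## PNG of the slide, and an optional scalefactors JSON.

.find_file <- function(dir, stems) {
  for (stem in stems) for (f in c(stem, paste0(stem, ".gz"))) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else file(path)
}

.read_tsv_col <- function(path, col = 1L) {
  # read.table transparently decompresses .gz paths
  utils::read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[[col]]
}

.read_positions <- function(path) {
  con <- .open_maybe_gz(path)
  open(con, "r")
  first <- readLines(con, n = 1L)
  close(con)
  headered <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(path, header = headered, stringsAsFactors = FALSE)
  if (ncol(pos) != 6L)
    stop("positions file must have 6 columns, found ", ncol(pos))
  colnames(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                     "pxl_row", "pxl_col")
  pos
}

#' Read a Visium-style sample directory
#'
#' Loads the MatrixMarket count matrix with its barcode/feature TSVs, the
#' tissue positions table (both Space Ranger dialects, plain or gzipped), and
#' optionally a grayscale slide image plus scale-factor metadata. Spot order
#' follows the positions table; spots present in the matrix but absent from
#' the positions table are dropped with a warning, while positions barcodes
#' missing from the matrix are an error. When the directory carries only a
#' downsampled ("hires") image, pixel coordinates are rescaled onto it using
#' the JSON scale factor.
#'
#' @param dir path to the sample directory.
#' @param loadImage logical; read the slide image when present.
#' @return A \linkS4class{SpotExperiment}.
#' @export
readVisium <- function(dir, loadImage = TRUE) {
  mtx <- .find_file(dir, "matrix.mtx")
  if (is.null(mtx)) stop("missing matrix.mtx(.gz) in ", dir)
  posf <- .find_file(dir, c("tissue_positions.csv", "tissue_positions_list.csv"))
  if (is.null(posf)) stop("missing tissue positions CSV in ", dir)
  bcf <- .find_file(dir, "barcodes.tsv")
  ftf <- .find_file(dir, "features.tsv")
  if (is.null(bcf) || is.null(ftf))
    stop("missing barcodes.tsv(.gz) or features.tsv(.gz) in ", dir)

  con <- .open_maybe_gz(mtx)
  counts <- Matrix::readMM(con)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  barcodes <- .read_tsv_col(bcf, 1L)
  genes <- .read_tsv_col(ftf, 1L)
  if (ncol(counts) != length(barcodes) || nrow(counts) != length(genes))
    stop("matrix dimensions (", nrow(counts), " x ", ncol(counts),
         ") disagree with features/barcodes (", length(genes), " x ",
         length(barcodes), ")")
  colnames(counts) <- barcodes
  rownames(counts) <- genes

  pos <- .read_positions(posf)
  missing_in_mtx <- setdiff(pos$barcode, barcodes)
  if (length(missing_in_mtx))
    stop(length(missing_in_mtx), " positions barcode(s) absent from the ",
         "count matrix (e.g., ", missing_in_mtx[1], ")")
  extra <- setdiff(barcodes, pos$barcode)
  if (length(extra))
    warning(length(extra), " matrix spot(s) absent from the positions ",
            "table were dropped")
  counts <- counts[, pos$barcode, drop = FALSE]

  diam <- NA_real_
  scalef <- 1
  sj <- file.path(dir, "scalefactors_json.json")
  if (file.exists(sj)) {
    sf <- jsonlite::read_json(sj)
    if (!is.null(sf$spot_diameter_fullres))
      diam <- as.numeric(sf$spot_diameter_fullres)
    if (isTRUE(sf$image_is_hires) && !is.null(sf$tissue_hires_scalef))
      scalef <- as.numeric(sf$tissue_hires_scalef)
  }
  if (scalef != 1) {
    pos$pxl_row <- pos$pxl_row * scalef
    pos$pxl_col <- pos$pxl_col * scalef
    if (!is.na(diam)) diam <- diam * scalef
  }

  img <- NULL
  if (loadImage) {
    imgf <- .find_file(dir, c("tissue_image.png", "tissue_hires_image.png"))
    if (!is.null(imgf)) {
      px <- png::readPNG(imgf)
      if (length(dim(px)) == 3L) px <- px[, , seq_len(min(3L, dim(px)[3]))]
      img <- toGrayscale(px * 255, maxval = 255)
    }
  }
  SpotExperiment(counts, pos, geneIds = genes, image = img,
                 spotDiameter = diam)
}

#' Write a SpotExperiment as a Visium-style directory
#'
#' Emits matrix.mtx, barcodes.tsv, features.tsv, a headered
#' tissue_positions.csv, scalefactors_json.json, and (when an image is
#' attached) tissue_image.png, so the output can be re-read with
#' \code{\link{readVisium}}.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeVisium <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  counts <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(x), file.path(dir, "features.tsv"))
  cd <- SummarizedExperiment::colData(x)
  pos <- data.frame(barcode = colnames(x),
                    in_tissue = as.integer(cd$in_tissue),
                    array_row = cd$array_row, array_col = cd$array_col,
                    pxl_row_in_fullres = cd$pxl_row,
                    pxl_col_in_fullres = cd$pxl_col)
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spot_diameter_fullres = spotDiameter(x)),
                       file.path(dir, "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = NA)
  img <- histoImage(x)
  if (!is.null(img))
    png::writePNG(img@pixels / img@maxval, file.path(dir, "tissue_image.png"))
  invisible(dir)
}

#' Write clustering and enhancement results
#'
#' Writes \code{clusters.csv} (barcode, cluster) for the partition and, when
#' an enhanced expression matrix is supplied, \code{enhanced.mtx} with
#' \code{enhanced_genes.tsv} / \code{enhanced_barcodes.tsv}.
#'
#' @param partition an \linkS4class{SCPartition}.
#' @param enhanced optional gene x spot numeric matrix over the same barcodes.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeResults <- function(partition, enhanced = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  utils::write.csv(data.frame(barcode = partition@barcodes,
                              cluster = partition@labels),
                   file.path(dir, "clusters.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(enhanced)) {
    if (!identical(colnames(enhanced), partition@barcodes))
      stop("enhanced matrix barcodes do not match the partition")
    Matrix::writeMM(as(as(as(enhanced, "dMatrix"), "generalMatrix"),
                       "CsparseMatrix"),
                    file.path(dir, "enhanced.mtx"))
    writeLines(rownames(enhanced), file.path(dir, "enhanced_genes.tsv"))
    writeLines(colnames(enhanced), file.path(dir, "enhanced_barcodes.tsv"))
  }
  invisible(dir)
}

#' Read back an enhanced matrix written by writeResults
#'
#' @param dir directory previously written by \code{\link{writeResults}}.
#' @return a dense gene x spot matrix with dimnames.
#' @export
readEnhanced <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "enhanced.mtx")))
  rownames(m) <- readLines(file.path(dir, "enhanced_genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "enhanced_barcodes.tsv"))
  m
}
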
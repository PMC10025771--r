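# Shared fixtures, built in code. Expensive objects are cached for the
# duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_fixture <- function() cached("fixture", makeTissue())

# a tiny SpotExperiment on a square grid with given counts
tiny_spot_experiment <- function(counts, nrows = NULL, image = NULL,
                                 diameter = 4) {
  n <- ncol(counts)
  if (is.null(nrows)) nrows <- 1L
  ncols <- ceiling(n / nrows)
  g <- expand.grid(r = seq_len(nrows) - 1L, c = seq_len(ncols) - 1L)[seq_len(n), ]
  pos <- data.frame(barcode = sprintf("b%02d", seq_len(n)),
                    in_tissue = 1L, array_row = g$r, array_col = g$c,
                    pxl_row = 10 + g$r * 10, pxl_col = 10 + g$c * 10)
  SpotExperiment(counts, pos, image = image, spotDiameter = diameter)
}

# network from an explicit weighted edge list over n spots
edge_network <- function(n, u, v, w, role = "Sstar") {
  SimilarityNetwork(data.frame(u = u, v = v, w = w),
                    barcodes = sprintf("b%02d", seq_len(n)), role = role)
}

# two K-cliques (sizes s each, unit weights) joined by one weak bridge
two_clique_network <- function(s = 5L, bridge = 0.05) {
  idx <- function(members) {
    p <- t(utils::combn(members, 2))
    data.frame(u = p[, 1], v = p[, 2], w = 1)
  }
  e <- rbind(idx(seq_len(s)), idx(s + seq_len(s)),
             data.frame(u = s, v = s + 1L, w = bridge))
  edge_network(2L * s, e$u, e$v, e$w)
}

# random connected weighted graph on n nodes (complete, positive weights)
random_complete_network <- function(n) {
  p <- t(utils::combn(n, 2))
  edge_network(n, p[, 1], p[, 2], stats::runif(nrow(p), 0.1, 1))
}
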
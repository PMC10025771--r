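## Spatial cluster identification on the fused network.
##
## Random-walk community detection: with P = D^-1 S the transition matrix of
## the fused graph, two spots are compared by the degree-weighted Euclidean
## distance between their t-step transition-probability profiles,
## W(u,v) = || D^-1/2 P^t_{u.} - D^-1/2 P^t_{v.} ||_2. Communities start as
## singletons and adjacent pairs are merged greedily by the smallest increase
## in mean squared profile distance (Ward increments, Lance-Williams
## updates); the merge tree is cut either at a requested cluster count or at
## the step maximizing modularity Q.

.dense_weights <- function(net) {
  n <- net@nSpots
  W <- matrix(0, n, n)
  e <- net@edges
  W[cbind(e$u, e$v)] <- e$w
  W[cbind(e$v, e$u)] <- e$w
  W
}

#' Transition matrix of a similarity network
#'
#' P = D^-1 S with D the diagonal weighted-degree matrix. Isolated spots are
#' first attached to their nearest spot in array coordinates with the
#' smallest positive edge weight (with a warning), so every row is
#' stochastic.
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @param coords optional array-coordinate matrix used to rescue isolated
#'   spots; without it an isolated spot is an error.
#' @return list with \code{P} (row-stochastic matrix) and \code{d} (weighted
#'   degree vector).
#' @export
transitionMatrix <- function(net, coords = NULL) {
  if (!nrow(net@edges)) stop("empty network")
  W <- .dense_weights(net)
  d <- rowSums(W)
  iso <- which(d == 0)
  if (length(iso)) {
    if (is.null(coords))
      stop(length(iso), " isolated spot(s); supply coords to attach them")
    warning(length(iso), " isolated spot(s) attached to their nearest ",
            "spatial neighbor")
    wmin <- min(net@edges$w[net@edges$w > 0])
    for (i in iso) {
      dd <- abs(coords[, 1] - coords[i, 1]) + abs(coords[, 2] - coords[i, 2])
      dd[i] <- Inf
      j <- which.min(dd)
      W[i, j] <- W[j, i] <- wmin
    }
    d <- rowSums(W)
  }
  list(P = W / d, d = d)
}

#' Random-walk profile distance
#'
#' Degree-weighted Euclidean distance between the t-step transition
#' profiles of two spots. Vectorized over pairs.
#'
#' @param P row-stochastic transition matrix.
#' @param d weighted degree vector.
#' @param t number of random-walk steps (>= 1).
#' @param u,v spot indices (recycled).
#' @return numeric vector of distances.
#' @export
walktrapDistance <- function(P, d, t, u, v) {
  R <- walktrapProfiles(P, d, t)
  sqrt(rowSums((R[u, , drop = FALSE] - R[v, , drop = FALSE])^2))
}

#' t-step degree-weighted walk profiles
#'
#' Rows are D^-1/2-weighted t-step transition probability vectors; the
#' pairwise Euclidean distances of these rows are the random-walk distances.
#'
#' @inheritParams walktrapDistance
#' @return an n x n matrix of weighted profiles.
#' @export
walktrapProfiles <- function(P, d, t) {
  stopifnot(t >= 1)
  Pt <- P
  if (t > 1) for (s in seq_len(t - 1)) Pt <- Pt %*% P
  sweep(Pt, 2, sqrt(d), "/")
}

#' Random-walk agglomerative clustering
#'
#' Clusters the spots of a fused network by agglomerative merging under the
#' random-walk profile distance: starting from singletons, the adjacent pair
#' of communities whose merge least increases the mean squared
#' profile-to-centroid distance is merged (ties broken by the smallest
#' involved spot index). Disconnected components are agglomerated
#' independently and their merges interleaved by merge cost. The tree is cut
#' at \code{nClusters} when given, otherwise at the partition maximizing
#' modularity Q along the merge sequence. Clusters smaller than
#' \code{minSize} are finally absorbed into the neighboring cluster with the
#' largest total connecting weight (\code{minSize = 0} disables this).
#'
#' @param net a normalized fused \linkS4class{SimilarityNetwork} ("Sstar").
#' @param t random-walk step count (default 4).
#' @param nClusters optional fixed number of clusters.
#' @param minSize smallest admissible cluster (default 5 spots).
#' @param coords optional array coordinates forwarded to
#'   \code{\link{transitionMatrix}} for isolated spots.
#' @return An \linkS4class{SCPartition} (method "walktrap"); attribute
#'   \code{"Q"} holds the modularity of the returned partition before
#'   small-cluster absorption.
#' @export
walktrapCluster <- function(net, t = 4L, nClusters = NULL, minSize = 5L,
                            coords = NULL) {
  n <- net@nSpots
  if (!is.null(nClusters) && nClusters > n)
    stop("nClusters exceeds the number of spots")
  tm <- transitionMatrix(net, coords)
  R <- walktrapProfiles(tm$P, tm$d, t)

  edges <- net@edges[net@edges$w > 0, , drop = FALSE]
  labels <- seq_len(n)                 # community of each spot (rep = min id)
  sizes <- rep(1L, n)                  # by community representative
  cent <- R                            # community centroids
  # all-pairs merge cost (Ward increment on walk profiles, scaled by 1/n)
  sq <- rowSums(R^2)
  D <- (outer(sq, sq, "+") - 2 * tcrossprod(R)) / (2 * n)
  diag(D) <- Inf
  Adj <- matrix(FALSE, n, n)           # community adjacency
  Adj[cbind(edges$u, edges$v)] <- TRUE
  Adj[cbind(edges$v, edges$u)] <- TRUE

  active <- rep(TRUE, n)
  lab_seq <- list()
  n_comm <- n
  while (n_comm > 1L) {
    cand <- D
    cand[!Adj] <- Inf
    pick <- which.min(cand)            # column-major: ties go to smallest ids
    if (!is.finite(cand[pick])) break  # only disconnected communities remain
    b <- ((pick - 1L) %/% n) + 1L
    a <- ((pick - 1L) %% n) + 1L
    if (a > b) { tmp <- a; a <- b; b <- tmp }   # merge into the smaller id
    na <- sizes[a]; nb <- sizes[b]; dab <- D[a, b]
    others <- which(active); others <- others[others != a & others != b]
    if (length(others)) {
      nx <- sizes[others]
      # Lance-Williams update for Ward increments
      D[a, others] <- D[others, a] <-
        ((na + nx) * D[a, others] + (nb + nx) * D[b, others] - nx * dab) /
        (na + nb + nx)
    }
    cent[a, ] <- (na * cent[a, ] + nb * cent[b, ]) / (na + nb)
    sizes[a] <- na + nb
    active[b] <- FALSE
    Adj[a, ] <- Adj[a, ] | Adj[b, ]
    Adj[, a] <- Adj[, a] | Adj[, b]
    Adj[a, a] <- FALSE
    Adj[b, ] <- FALSE; Adj[, b] <- FALSE
    D[b, ] <- Inf; D[, b] <- Inf
    labels[labels == b] <- a
    n_comm <- n_comm - 1L
    lab_seq[[length(lab_seq) + 1L]] <- labels
  }

  # choose the cut
  pick_partition <- function(labs) {
    SCPartition(labs, barcodes = net@barcodes, method = "walktrap")
  }
  if (!is.null(nClusters)) {
    counts <- vapply(lab_seq, function(l) length(unique(l)), integer(1))
    if (nClusters == n) {
      part <- pick_partition(seq_len(n))
    } else {
      hit <- which(counts == nClusters)
      if (!length(hit))
        stop("the merge tree has no level with ", nClusters, " clusters")
      part <- pick_partition(lab_seq[[hit[1]]])
    }
    q <- modularityQ(net, part)
  } else {
    qs <- vapply(lab_seq, function(l)
      modularityQ(net, pick_partition(l)), numeric(1))
    q0 <- modularityQ(net, pick_partition(seq_len(n)))   # all singletons
    if (!length(qs) || max(qs) <= q0) {
      part <- pick_partition(seq_len(n)); q <- q0
    } else {
      part <- pick_partition(lab_seq[[which.max(qs)]]); q <- max(qs)
    }
  }
  if (minSize > 0L) part <- .absorb_small(part, net, minSize)
  attr(part, "Q") <- q
  part
}

## merge clusters below minSize into the neighbor with max connecting weight
.absorb_small <- function(part, net, minSize) {
  labs <- part@labels
  e <- net@edges
  repeat {
    tab <- table(labs)
    small <- names(tab)[tab < minSize]
    if (!length(small) || length(tab) == 1L) break
    cl <- as.integer(small[1])
    link <- tapply(
      c(e$w[labs[e$u] == cl & labs[e$v] != cl],
        e$w[labs[e$v] == cl & labs[e$u] != cl]),
      c(labs[e$v][labs[e$u] == cl & labs[e$v] != cl],
        labs[e$u][labs[e$v] == cl & labs[e$u] != cl]),
      sum)
    if (!length(link)) break           # disconnected small cluster: keep it
    labs[labs == cl] <- as.integer(names(link)[which.max(link)])
  }
  SCPartition(labs, barcodes = part@barcodes, method = part@method,
              truth = part@truth)
}

#' Expression-only Louvain baseline
#'
#' Louvain community detection on the transcriptomic SNN graph alone; the
#' contrast partner used to show what the image and spatial modalities add.
#'
#' @param tNet a \linkS4class{SimilarityNetwork} with role "T".
#' @param seed RNG seed (Louvain visits vertices in random order).
#' @param resolution Louvain resolution parameter.
#' @return An \linkS4class{SCPartition} (method "louvain-expression").
#' @export
louvainBaseline <- function(tNet, seed = 1L, resolution = 1) {
  e <- tNet@edges[tNet@edges$w > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$u, to = e$v, weight = e$w), directed = FALSE,
    vertices = data.frame(name = seq_len(tNet@nSpots)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)[as.character(seq_len(tNet@nSpots))]
  SCPartition(as.integer(memb), barcodes = tNet@barcodes,
              method = "louvain-expression")
}
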
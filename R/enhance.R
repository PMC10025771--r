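## Gene expression enhancement on the fused network.
##
## Each spot's expression is reinforced with that of its immediate network
## neighbors, E*_u = E_u + sum_v S*_{u,v} E_v, optionally renormalized to a
## weighted average (the default, keeping values depth-comparable). False
## zeros are repaired by repeatedly replacing each zero entry with the plain
## mean of its currently nonzero neighbors; the quality of a repair is the
## dropout recovery score 1 - symmetric KL between the per-gene expression
## profiles before and after.

.sparse_weight_matrix <- function(net) {
  e <- net@edges[net@edges$w > 0, , drop = FALSE]
  Matrix::sparseMatrix(i = c(e$u, e$v), j = c(e$v, e$u), x = c(e$w, e$w),
                       dims = c(net@nSpots, net@nSpots))
}

#' Neighborhood smoothing of expression
#'
#' Adds to each spot the S*-weighted expression of its network neighbors.
#' With \code{average = TRUE} (default) the sum is divided by
#' 1 + sum of incident weights, making the result a convex combination of
#' the closed neighborhood; \code{average = FALSE} gives the raw additive
#' form. Spots without neighbors are returned unchanged.
#'
#' @param E gene x spot matrix (log-normalized layer recommended) whose
#'   columns match the network's spots.
#' @param net a normalized fused \linkS4class{SimilarityNetwork} ("Sstar").
#' @param average divide by (1 + total neighbor weight)?
#' @return a gene x spot matrix of the same shape.
#' @export
smoothExpression <- function(E, net, average = TRUE) {
  if (ncol(E) != net@nSpots)
    stop("expression matrix has ", ncol(E), " spots but the network has ",
         net@nSpots)
  W <- .sparse_weight_matrix(net)
  Es <- as.matrix(E %*% W) + as.matrix(E)
  if (average)
    Es <- sweep(Es, 2, 1 + Matrix::colSums(W), "/")
  dimnames(Es) <- dimnames(as.matrix(E))
  Es
}

#' Iterative neighbor-mean dropout filling
#'
#' Per gene, every zero entry is replaced by the unweighted mean of its
#' neighbors' currently nonzero values; rounds repeat until every fillable
#' zero is filled, nothing changes, or \code{maxRounds} is reached. Entries
#' with no reachable nonzero neighbor stay zero. Deeper holes need more
#' rounds, so the round count grows with the dropout rate.
#'
#' @param E gene x spot matrix containing dropout zeros.
#' @param net the fused \linkS4class{SimilarityNetwork} defining adjacency
#'   (any positive weight makes two spots neighbors; fill means are
#'   unweighted).
#' @param maxRounds cap on fill rounds.
#' @param targets optional linear indices of the entries regarded as missing
#'   (e.g., the recorded dropout mask). Default: every zero entry. An empty
#'   target set makes the function the identity.
#' @return the filled matrix, with attributes \code{"rounds"} (rounds used)
#'   and \code{"unfilled"} (count of target entries that could not be
#'   filled).
#' @export
fillDropout <- function(E, net, maxRounds = 100L, targets = NULL) {
  if (ncol(E) != net@nSpots)
    stop("expression matrix does not match the network")
  A <- .sparse_weight_matrix(net)
  A@x[] <- 1                                    # unweighted adjacency
  E <- as.matrix(E)
  miss <- matrix(FALSE, nrow(E), ncol(E))
  if (is.null(targets)) miss[E == 0] <- TRUE else miss[targets] <- TRUE
  miss <- miss & E == 0                         # only zeros can be missing
  rounds <- 0L
  while (any(miss) && rounds < maxRounds) {
    nzmat <- (E > 0) + 0
    denom <- as.matrix(nzmat %*% A)             # nonzero neighbors per entry
    fillable <- miss & denom > 0
    if (!any(fillable)) break
    numer <- as.matrix(E %*% A)
    E[fillable] <- numer[fillable] / denom[fillable]
    miss <- miss & !fillable
    rounds <- rounds + 1L
  }
  attr(E, "rounds") <- rounds
  attr(E, "unfilled") <- sum(miss)
  E
}

#' Dropout recovery score
#'
#' For each gene, the spot-wise expression vectors before and after an
#' operation are normalized to probability distributions (with \code{eps}
#' pseudo-mass) and compared by symmetric KL divergence; the score is
#' 1 - divergence, so identical profiles score exactly 1 and the score is
#' symmetric in its two arguments. Genes that are all-zero in either matrix
#' get NA.
#'
#' @param before,after gene x spot matrices of equal shape.
#' @param genes optional subset of rows (indices or names).
#' @param eps pseudo-mass shared with \code{\link{symmetricKL}}.
#' @return named numeric vector, one score per gene.
#' @export
recoveryScore <- function(before, after, genes = NULL, eps = 1e-10) {
  before <- as.matrix(before); after <- as.matrix(after)
  if (!identical(dim(before), dim(after)))
    stop("matrices must have the same shape")
  if (!is.null(genes)) {
    before <- before[genes, , drop = FALSE]
    after <- after[genes, , drop = FALSE]
  }
  out <- vapply(seq_len(nrow(before)), function(g) {
    b <- before[g, ]; a <- after[g, ]
    if (sum(b) == 0 || sum(a) == 0) return(NA_real_)
    1 - symmetricKL(b / sum(b), a / sum(a), eps = eps)
  }, numeric(1))
  names(out) <- rownames(before)
  out
}
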
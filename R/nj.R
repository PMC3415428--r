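# Neighbor joining and BioNJ from a distance matrix. Both variants use the
# standard Q-criterion agglomeration; BioNJ adds the one-parameter
# variance-weighted update of Gascuel (lambda from the variance matrix,
# initialised to the distances themselves). Ties in Q are broken on the
# lexicographically smallest pair of cluster representative labels
# (representative = smallest member label), negative branch lengths are
# clamped to zero with the deficit moved to the sister branch.

#' Neighbor-joining / BioNJ tree from a distance matrix
#'
#' @param D Symmetric numeric matrix with labelled dimnames and zero
#'   diagonal; at least 3 labels.
#' @param variant `"NJ"` or `"BioNJ"`.
#' @return An unrooted [ape::phylo] tree (trifurcating root node). The
#'   agglomeration order is attached as attribute `joins`, a list of
#'   representative-label pairs usable as a progressive-merge guide.
#' @export
nj_tree <- function(D, variant = c("NJ", "BioNJ")) {
  variant <- match.arg(variant)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D)) || is.null(colnames(D))) stop("D must be labelled")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n0 <- nrow(D)
  if (n0 < 3L) stop("need at least 3 labels")
  labs <- rownames(D)
  if (any(grepl("[(),:;\\s]", labs, perl = TRUE))) {
    stop("labels must not contain Newick metacharacters or whitespace")
  }
  frag <- labs                 # newick fragment per active cluster
  rep_lab <- labs              # lexicographic representative per cluster
  V <- D                       # BioNJ variance matrix
  active <- seq_len(n0)
  joins <- list()

  clamp <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    c(bi, bj)
  }

  while (length(active) > 3L) {
    n <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1L] < ties[, 2L], , drop = FALSE]
    reps <- cbind(pmin(rep_lab[active[ties[, 1L]]], rep_lab[active[ties[, 2L]]]),
                  pmax(rep_lab[active[ties[, 1L]]], rep_lab[active[ties[, 2L]]]))
    pick <- order(reps[, 1L], reps[, 2L])[1L]
    i <- active[ties[pick, 1L]]
    j <- active[ties[pick, 2L]]
    ii <- ties[pick, 1L]; jj <- ties[pick, 2L]
    dij <- D[i, j]
    bi <- dij / 2 + (R[ii] - R[jj]) / (2 * (n - 2))
    bj <- dij - bi
    bb <- clamp(bi, bj)
    bi <- bb[1L]; bj <- bb[2L]
    others <- setdiff(active, c(i, j))
    if (variant == "BioNJ") {
      vij <- V[i, j]
      lambda <- if (vij > 1e-12 && length(others) > 0L) {
        0.5 + sum(V[j, others] - V[i, others]) / (2 * (n - 2) * vij)
      } else 0.5
      lambda <- min(1, max(0, lambda))
      d_new <- lambda * (D[i, others] - bi) + (1 - lambda) * (D[j, others] - bj)
      v_new <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
        lambda * (1 - lambda) * vij
    } else {
      d_new <- (D[i, others] + D[j, others] - dij) / 2
      v_new <- d_new
    }
    # reuse slot i for the merged cluster
    D[i, others] <- d_new; D[others, i] <- d_new; D[i, i] <- 0
    V[i, others] <- v_new; V[others, i] <- v_new; V[i, i] <- 0
    joins[[length(joins) + 1L]] <- c(rep_lab[i], rep_lab[j])
    frag[i] <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }

  a <- active[1L]; b <- active[2L]; c0 <- active[3L]
  ba <- (D[a, b] + D[a, c0] - D[b, c0]) / 2
  bb <- (D[a, b] + D[b, c0] - D[a, c0]) / 2
  bc <- (D[a, c0] + D[b, c0] - D[a, b]) / 2
  ba <- max(0, ba); bb <- max(0, bb); bc <- max(0, bc)
  # record the remaining joins for guide use: closest pair first, lexicographic
  pairs <- list(c(a, b), c(a, c0), c(b, c0))
  dists <- c(D[a, b], D[a, c0], D[b, c0])
  keys <- vapply(pairs, function(p) paste(sort(rep_lab[p]), collapse = "\r"),
                 character(1))
  best <- order(dists, keys)[1L]
  p1 <- pairs[[best]]
  p3 <- setdiff(c(a, b, c0), p1)
  joins[[length(joins) + 1L]] <- c(rep_lab[p1[1L]], rep_lab[p1[2L]])
  joins[[length(joins) + 1L]] <- c(min(rep_lab[p1]), rep_lab[p3])

  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[a], ba, frag[b], bb,
                 frag[c0], bc)
  tr <- ape::read.tree(text = nwk)
  attr(tr, "joins") <- joins
  tr
}
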
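# Bootstrap support by column resampling and low-support collapse.

# Canonical bipartition keys of a tree's internal edges: each internal
# (non-root) node contributes the tip set of its clade, represented by the
# side NOT containing the reference tip so that the key is rooting-invariant.
.split_keys <- function(tree, all_tips) {
  ref <- sort(all_tips)[1L]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(n_tip))
  keys <- character()
  for (nd in internal) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
    if (length(side) >= 2L && length(side) <= length(all_tips) - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
  }
  unique(keys)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree with `builder` on each replicate, and labels each internal node of
#' the original tree with the percentage of replicates containing its
#' bipartition. Trivial bipartitions get `NA`.
#'
#' @param aln An [alignment()].
#' @param builder Function `alignment -> phylo`; defaults to BioNJ on
#'   Poisson-corrected distances.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return The original tree with numeric `node.label` supports in
#'   `[0, 100]`.
#' @export
bootstrap_support <- function(aln, builder = NULL, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(builder)) {
    builder <- function(a) nj_tree(distance_matrix(a, "poisson"), "BioNJ")
  }
  set.seed(as.integer(seed))
  tree <- builder(aln)
  mat <- .aln_matrix(aln)
  L <- ncol(mat)
  counts <- integer()
  ok_reps <- 0L
  all_tips <- sort(names(aln$rows))
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_rows <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(rep_rows) <- names(aln$rows)
    rep_aln <- structure(list(rows = rep_rows, kind = aln$kind),
                         class = "alignment")
    rep_tree <- tryCatch(builder(rep_aln), error = function(e) NULL)
    if (is.null(rep_tree)) next
    ok_reps <- ok_reps + 1L
    for (key in .split_keys(rep_tree, all_tips)) {
      counts[key] <- (if (key %in% names(counts)) counts[key] else 0L) + 1L
    }
  }
  if (ok_reps == 0L) stop("all bootstrap replicates failed")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  ref <- all_tips[1L]
  supports <- rep(NA_real_, n_node)
  for (nd in (n_tip + 1L):(n_tip + n_node)) {
    if (nd == n_tip + 1L) next      # root of the unrooted representation
    tips <- ape::extract.clade(tree, nd)$tip.label
    side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
    if (length(side) < 2L || length(side) > length(all_tips) - 2L) next
    key <- paste(sort(side), collapse = "\r")
    cnt <- if (key %in% names(counts)) counts[[key]] else 0L
    supports[nd - n_tip] <- 100 * cnt / ok_reps
  }
  tree$node.label <- supports
  tree
}

# phylo -> nested list (label/length/support/children), for tree surgery.
.phylo_to_clade <- function(tree) {
  n_tip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  build <- function(node, edge_idx) {
    len <- if (has_len && !is.na(edge_idx)) tree$edge.length[edge_idx] else NA_real_
    if (node <= n_tip) {
      list(label = tree$tip.label[node], length = len, children = NULL,
           support = NA_real_)
    } else {
      sup <- if (!is.null(tree$node.label)) {
        suppressWarnings(as.numeric(tree$node.label[node - n_tip]))
      } else NA_real_
      ch <- lapply(kids[[as.character(node)]], function(e) {
        build(tree$edge[e, 2L], e)
      })
      list(label = NULL, length = len, children = ch, support = sup)
    }
  }
  build(n_tip + 1L, NA_integer_)
}

.clade_to_newick <- function(clade) {
  fmt <- function(cl) {
    body <- if (is.null(cl$children)) {
      cl$label
    } else {
      sup <- if (!is.na(cl$support)) format(cl$support, digits = 10) else ""
      paste0("(", paste(vapply(cl$children, fmt, character(1)), collapse = ","),
             ")", sup)
    }
    if (!is.na(cl$length)) paste0(body, ":", format(cl$length, digits = 10)) else body
  }
  paste0(fmt(clade), ";")
}

#' Collapse low-support branches into polytomies
#'
#' Contracts every internal edge whose child support is below `threshold`
#' (missing supports are kept). The contracted edge's length is added to the
#' edges of the node's children, so root-to-tip path lengths are preserved.
#' The leaf set is unchanged.
#'
#' @param tree A [ape::phylo] with numeric supports in `node.label`.
#' @param threshold Support threshold (default 40).
#' @return The collapsed [ape::phylo] (possibly multifurcating).
#' @export
collapse_low_support <- function(tree, threshold = 40) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) stop("tree has no support labels")
  clade <- .phylo_to_clade(tree)
  contract <- function(cl) {
    if (is.null(cl$children)) return(cl)
    cl$children <- lapply(cl$children, contract)
    new_children <- list()
    for (ch in cl$children) {
      if (!is.null(ch$children) && !is.na(ch$support) && ch$support < threshold) {
        for (g in ch$children) {
          if (!is.na(ch$length) && !is.na(g$length)) g$length <- g$length + ch$length
          new_children[[length(new_children) + 1L]] <- g
        }
      } else {
        new_children[[length(new_children) + 1L]] <- ch
      }
    }
    cl$children <- new_children
    cl
  }
  ape::read.tree(text = .clade_to_newick(contract(clade)))
}
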
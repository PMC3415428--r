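# Birth-death simulation of a gene family along a rooted species tree.
# One gene enters at the root; on each branch a lineage duplicates with
# exponential waiting at dup_rate and is lost at loss_rate; surviving
# lineages speciate at internal species nodes. Event counts are recorded
# for all events, including those in subtrees that later go extinct.

#' Simulate a gene family along a species tree
#'
#' @param species_tree Rooted binary [ape::phylo] with branch lengths.
#' @param dup_rate,loss_rate Events per unit branch length (>= 0).
#' @param seed Integer seed. Families with zero surviving genes are
#'   resampled with an incremented seed; the number of resamples is
#'   reported in the result.
#' @return Object of class `gene_family_sim` with elements `species_tree`,
#'   `gene_tree` (an [ape::phylo], or `NULL` when a single gene survives),
#'   `gene_leaves`, `leaf_to_species`, `true_duplications`, `true_losses`,
#'   `rates`, `seed`, `resampled`.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed) {
  stopifnot(inherits(species_tree, "phylo"))
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!ape::is.binary(species_tree)) stop("species tree must be binary")
  if (is.null(species_tree$edge.length)) stop("species tree needs branch lengths")

  n_tip <- length(species_tree$tip.label)
  kids <- split(seq_len(nrow(species_tree$edge)), species_tree$edge[, 1L])

  attempt <- function(seed_i) {
    set.seed(as.integer(seed_i))
    env <- new.env()
    env$dups <- 0L
    env$losses <- 0L
    env$copy_no <- stats::setNames(rep(0L, n_tip), species_tree$tip.label)

    sim_species_node <- function(node) {
      if (node <= n_tip) {
        sp <- species_tree$tip.label[node]
        env$copy_no[sp] <- env$copy_no[sp] + 1L
        return(list(label = paste0(sp, "_g", env$copy_no[sp]),
                    length = 0, children = NULL))
      }
      ch <- lapply(kids[[as.character(node)]], function(e) {
        sim_branch(species_tree$edge[e, 2L], species_tree$edge.length[e])
      })
      ch <- ch[!vapply(ch, is.null, logical(1))]
      if (length(ch) == 0L) return(NULL)
      if (length(ch) == 1L) return(ch[[1L]])
      list(label = NULL, length = 0, children = ch)
    }

    sim_branch <- function(node, t_remaining) {
      rate <- dup_rate + loss_rate
      wait <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (wait >= t_remaining) {
        cl <- sim_species_node(node)
        if (!is.null(cl)) cl$length <- cl$length + t_remaining
        return(cl)
      }
      if (stats::runif(1L) < dup_rate / rate) {
        env$dups <- env$dups + 1L
        left <- sim_branch(node, t_remaining - wait)
        right <- sim_branch(node, t_remaining - wait)
        surv <- Filter(Negate(is.null), list(left, right))
        if (length(surv) == 0L) return(NULL)
        if (length(surv) == 1L) {
          cl <- surv[[1L]]
          cl$length <- cl$length + wait
          return(cl)
        }
        return(list(label = NULL, length = wait, children = surv))
      }
      env$losses <- env$losses + 1L
      NULL
    }

    root <- n_tip + 1L
    clade <- sim_species_node(root)
    list(clade = clade, dups = env$dups, losses = env$losses)
  }

  resampled <- 0L
  res <- attempt(seed)
  while (is.null(res$clade)) {
    resampled <- resampled + 1L
    res <- attempt(as.integer(seed) + resampled)
  }
  leaves <- .clade_leaves(res$clade)
  gene_tree <- if (length(leaves) >= 2L) {
    ape::read.tree(text = .clade_to_newick(.strip_support(res$clade)))
  } else NULL
  leaf_to_species <- stats::setNames(sub("_g[0-9]+$", "", leaves), leaves)
  structure(list(
    species_tree = species_tree, gene_tree = gene_tree, gene_leaves = leaves,
    leaf_to_species = leaf_to_species,
    true_duplications = res$dups, true_losses = res$losses,
    rates = c(duplication = dup_rate, loss = loss_rate),
    seed = as.integer(seed), resampled = resampled
  ), class = "gene_family_sim")
}

.clade_leaves <- function(clade) {
  if (is.null(clade$children)) return(clade$label)
  unlist(lapply(clade$children, .clade_leaves))
}

# .clade_to_newick (bootstrap.R) expects a `support` element on every node.
.strip_support <- function(clade) {
  clade$support <- NA_real_
  if (!is.null(clade$children)) {
    clade$children <- lapply(clade$children, .strip_support)
  }
  clade
}

#' @export
print.gene_family_sim <- function(x, ...) {
  cat("Gene family simulation (seed ", x$seed, "): ", length(x$gene_leaves),
      " surviving gene(s), ", x$true_duplications, " duplication(s), ",
      x$true_losses, " loss(es)", sep = "")
  if (x$resampled > 0L) cat(" [resampled ", x$resampled, "x]", sep = "")
  cat("\n")
  invisible(x)
}
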
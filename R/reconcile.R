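# Duplication-loss reconciliation of a rooted gene tree against a rooted
# species tree by LCA mapping, with losses counted and attributed to the
# species branches where the lineage disappeared.

# Parent vector and root-relative depths of a rooted phylo.
.tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n_tip + 1L
  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  ord <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # breadth-first: edges of ape trees can be in any order, iterate until fixed
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; c0 <- tree$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[c0])) {
        depth[c0] <- depth[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  list(n_tip = n_tip, root = root, parent = parent, depth = depth, kids = kids)
}

.lca <- function(idx, a, b) {
  while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  while (a != b) { a <- idx$parent[a]; b <- idx$parent[b] }
  a
}

#' Human-readable label of a species-tree node
#'
#' Tip label for tips; the node label when present, otherwise the sorted
#' tip labels of the clade joined with `"+"`.
#'
#' @param species_tree A rooted [ape::phylo].
#' @param node Node id.
#' @export
species_node_label <- function(species_tree, node) {
  n_tip <- length(species_tree$tip.label)
  if (node <= n_tip) return(species_tree$tip.label[node])
  if (!is.null(species_tree$node.label)) {
    lb <- species_tree$node.label[node - n_tip]
    if (!is.na(lb) && nzchar(lb)) return(lb)
  }
  paste(sort(ape::extract.clade(species_tree, node)$tip.label), collapse = "+")
}

#' LCA duplication-loss reconciliation
#'
#' Maps every gene-tree node to the LCA of its children's species images; a
#' node is a duplication iff its image equals the image of either child.
#' Losses are counted along each gene edge by the depth-difference formula
#' and attributed to the species branch (identified by its child node) where
#' the lost lineage would have branched off.
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param species_tree Rooted binary [ape::phylo]; polytomies are rejected.
#' @param leaf_map Named character vector: gene tip label -> species tip
#'   label.
#' @return Object of class `reconciliation` with `node_map` (gene node ->
#'   species node), `events` (per internal gene node), `losses` (data frame
#'   per species branch), `total_duplications`, `total_losses`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!ape::is.binary(gene_tree)) stop("gene tree must be binary")
  if (!ape::is.binary(species_tree)) stop("species tree has polytomies; resolve it first")
  gi <- .tree_index(gene_tree)
  si <- .tree_index(species_tree)
  sp_of <- match(leaf_map, species_tree$tip.label)
  names(sp_of) <- names(leaf_map)
  g_tips <- gene_tree$tip.label
  if (!all(g_tips %in% names(leaf_map))) {
    stop("unmapped gene leaf: ", setdiff(g_tips, names(leaf_map))[1L])
  }
  if (anyNA(sp_of[g_tips])) {
    bad <- g_tips[is.na(sp_of[g_tips])][1L]
    stop("gene leaf '", bad, "' maps to unknown species '", leaf_map[bad], "'")
  }

  n_gnode <- gi$n_tip + gene_tree$Nnode
  M <- rep(NA_integer_, n_gnode)
  M[seq_len(gi$n_tip)] <- sp_of[g_tips]
  post <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    p <- post[e, 1L]
    c0 <- post[e, 2L]
    M[p] <- if (is.na(M[p])) M[c0] else .lca(si, M[p], M[c0])
  }

  internal <- (gi$n_tip + 1L):n_gnode
  events <- vapply(internal, function(v) {
    ch <- gi$kids[[as.character(v)]]
    if (M[v] == M[ch[1L]] || M[v] == M[ch[2L]]) "duplication" else "speciation"
  }, character(1))
  names(events) <- internal

  loss_counts <- integer()
  for (v in seq_len(n_gnode)) {
    u <- gi$parent[v]
    if (is.na(u)) next
    a <- M[u]; b <- M[v]
    is_dup <- events[[as.character(u)]] == "duplication"
    # walk the species path b -> a, collecting lost sibling branches
    path <- b
    while (path[length(path)] != a) path <- c(path, si$parent[path[length(path)]])
    d <- length(path) - 1L
    if (d == 0L) next
    steps <- rev(path)                  # a = q0, ..., qd = b
    # q0 = a contributes a loss only below a duplication
    idx <- if (is_dup) seq_len(d) else if (d >= 2L) 2:d else integer()
    for (m in idx) {
      q <- steps[m]
      on_path <- steps[m + 1L]
      sib <- setdiff(si$kids[[as.character(q)]], on_path)
      for (s in sib) {
        key <- as.character(s)
        loss_counts[key] <- (if (key %in% names(loss_counts)) loss_counts[key] else 0L) + 1L
      }
    }
  }
  losses <- if (length(loss_counts) > 0L) {
    data.frame(species_node = as.integer(names(loss_counts)),
               label = vapply(as.integer(names(loss_counts)),
                              function(s) species_node_label(species_tree, s),
                              character(1)),
               count = as.integer(loss_counts), stringsAsFactors = FALSE)
  } else {
    data.frame(species_node = integer(), label = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    node_map = M, events = events, losses = losses,
    total_duplications = sum(events == "duplication"),
    total_losses = sum(losses$count),
    gene_tree = gene_tree, species_tree = species_tree
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("DL reconciliation: ", x$total_duplications, " duplication(s), ",
      x$total_losses, " loss(es)\n", sep = "")
  invisible(x)
}

#' Compare inferred with true events for a simulated family
#'
#' Reconciles the simulated gene tree against its species tree and reports
#' inferred versus true duplication/loss counts. With full sampling and no
#' losses the LCA inference is exact; with losses it is a parsimony lower
#' bound.
#'
#' @param sim A [simulate_gene_family()] result.
#' @return List with `inferred_duplications`, `inferred_losses`,
#'   `true_duplications`, `true_losses`, `n_genes`.
#' @export
recover_events <- function(sim) {
  stopifnot(inherits(sim, "gene_family_sim"))
  if (is.null(sim$gene_tree)) {
    return(list(inferred_duplications = 0L, inferred_losses = NA_integer_,
                true_duplications = sim$true_duplications,
                true_losses = sim$true_losses, n_genes = length(sim$gene_leaves)))
  }
  rec <- lca_reconcile(sim$gene_tree, sim$species_tree, sim$leaf_to_species)
  list(inferred_duplications = rec$total_duplications,
       inferred_losses = rec$total_losses,
       true_duplications = sim$true_duplications,
       true_losses = sim$true_losses,
       n_genes = length(sim$gene_leaves))
}

#' Bundled defensin gene-family fixture
#'
#' A nine-taxon species tree (the honey bee plus eight ants) and a defensin
#' gene tree in which two species (*C. floridanus*, *S. invicta*) carry two
#' gene copies and all others carry one. The topology is configuration built
#' to exercise the duplication-at-the-root pattern: the reconciliation
#' places one duplication at the LCA of the bee and the ants, and every
#' single-copy species shows at least one loss.
#'
#' @return `defensin_species_tree()` / `defensin_gene_tree()` return
#'   [ape::phylo] trees; `defensin_leaf_map()` the gene-to-species map.
#' @export
defensin_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(Apis_mellifera:3,(Harpegnathos_saltator:2.5,(Linepithema_humile:2,",
    "(Pogonomyrmex_barbatus:1.5,(Solenopsis_invicta:1.2,",
    "(Myrmica_scabrinodis:1,(Lasius_niger:0.8,(Camponotus_floridanus:0.5,",
    "Formica_aquilonia:0.5):0.3):0.2):0.2):0.3):0.5):0.5):0.5);"))
}

#' @rdname defensin_species_tree
#' @export
defensin_gene_tree <- function() {
  ape::read.tree(text = paste0(
    "((Apis_mellifera_def1:3,(Harpegnathos_saltator_def1:2.5,",
    "(Solenopsis_invicta_def1:1.2,(Myrmica_scabrinodis_def1:1,",
    "(Lasius_niger_def1:0.8,(Camponotus_floridanus_def1:0.5,",
    "Formica_aquilonia_def1:0.5):0.3):0.2):0.2):0.5):0.5):0.5,",
    "(Linepithema_humile_def2:2,(Pogonomyrmex_barbatus_def2:1.5,",
    "(Solenopsis_invicta_def2:1.2,Camponotus_floridanus_def2:1.2):0.3):0.5):1):0.5;"))
}

#' @rdname defensin_species_tree
#' @export
defensin_leaf_map <- function() {
  tips <- defensin_gene_tree()$tip.label
  stats::setNames(sub("_def[12]$", "", tips), tips)
}

#' Reconciliation report for the defensin gene family
#'
#' Reconciles a defensin-type gene tree (two species with two copies, the
#' rest with one) against the species tree and reports where the duplication
#' maps and which species lost a copy. Defaults to the bundled fixture.
#'
#' @param gene_tree,species_tree,leaf_map Trees and map; defaults to the
#'   bundled defensin fixture.
#' @return List of class `defensin_scenario` with the `reconciliation`, the
#'   duplication node images (`duplication_images`), the per-species loss
#'   table and a `narrative` character vector.
#' @export
defensin_scenario <- function(gene_tree = defensin_gene_tree(),
                              species_tree = defensin_species_tree(),
                              leaf_map = defensin_leaf_map()) {
  rec <- lca_reconcile(gene_tree, species_tree, leaf_map)
  dup_nodes <- as.integer(names(rec$events)[rec$events == "duplication"])
  dup_images <- vapply(dup_nodes, function(v) {
    species_node_label(species_tree, rec$node_map[v])
  }, character(1))
  narrative <- c(
    sprintf("%d duplication event(s); %d loss event(s).",
            rec$total_duplications, rec$total_losses),
    vapply(seq_along(dup_nodes), function(i) {
      sprintf("Duplication at gene node %d maps to species ancestor [%s].",
              dup_nodes[i], dup_images[i])
    }, character(1)),
    if (nrow(rec$losses) > 0L) {
      vapply(seq_len(nrow(rec$losses)), function(i) {
        sprintf("Loss of %d cop%s on the branch to [%s].", rec$losses$count[i],
                if (rec$losses$count[i] == 1L) "y" else "ies", rec$losses$label[i])
      }, character(1))
    }
  )
  structure(list(reconciliation = rec, duplication_nodes = dup_nodes,
                 duplication_images = dup_images, losses = rec$losses,
                 narrative = narrative), class = "defensin_scenario")
}

#' @export
print.defensin_scenario <- function(x, ...) {
  cat(x$narrative, sep = "\n")
  invisible(x)
}
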
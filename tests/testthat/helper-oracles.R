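# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as direct formulations (enumeration, closed forms,
# brute-force scans) independent of the implementation paths they check.

# ---- random architecture specs ---------------------------------------------

random_arch_spec <- function(seed, n_introns = NULL) {
  set.seed(seed)
  signal_len <- sample(10:25, 1)
  pro_len <- sample(10:40, 1)
  hld_len <- sample(30:120, 1)
  hd_len <- sample(20:150, 1)
  n_repeats <- sample(0:10, 1)
  cleavage <- sample(c("RR", "KR", "RK"), 1)
  p_len <- signal_len + pro_len + 2L + hld_len + 2L +
    n_repeats * (4L + hd_len + 2L)
  if (is.null(n_introns)) n_introns <- sample(0:2, 1)
  introns <- list()
  if (n_introns > 0) {
    # keep internal exons longer than the splice-mapping anchor (20 nt)
    repeat {
      offs <- sort(sample(seq_len(3L * p_len - 1L), n_introns))
      if (n_introns == 1L || min(diff(offs)) >= 30L) break
    }
    introns <- lapply(offs, function(o) {
      len <- sample(50:900, 1)
      if (o %% 3L == 0L) list(after_codon = o %/% 3L, length = len)
      else list(within_codon = o %/% 3L + 1L, phase = o %% 3L, length = len)
    })
  }
  architecture_spec(signal_len, pro_len, hld_len, hd_len, n_repeats,
                    spacer_motif = "EAEP", cleavage_motif = cleavage,
                    introns = introns,
                    utr5_len = sample(20:100, 1), utr3_len = sample(20:100, 1))
}

# ---- simple seeded nucleotide evolution ------------------------------------

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

mutate_nt <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (h in hit) x[h] <- sample(setdiff(c("A", "C", "G", "T"), x[h]), 1)
  paste(x, collapse = "")
}

nt_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}

# ---- exhaustive affine-alignment score oracle ------------------------------
# Memoised suffix recursion over (i, j, previous-move) with gap cost
# open + L * extend; independent of the iterative Gotoh implementation.

oracle_align_score <- function(a, b, S, gap_open = 10, gap_extend = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  na <- length(x); nb <- length(y)
  memo <- new.env()
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, S[x[i], y[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= na) {
      cost <- gap_extend + if (prev == "u") 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, "u"))
    }
    if (j <= nb) {
      cost <- gap_extend + if (prev == "l") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, "l"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# ---- brute-force tandem-repeat presence oracle -----------------------------
# TRUE iff some period d in range has two adjacent copies at >= min_identity,
# scanning every window.

oracle_has_tandem <- function(seq, min_period = 30, max_period = 600,
                              min_identity = 0.8) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  for (d in min_period:min(max_period, n %/% 2)) {
    eq <- x[1:(n - d)] == x[(d + 1):n]
    if (length(eq) < d) next
    cs <- cumsum(eq)
    wins <- cs[d:length(eq)] - c(0, cs)[1:(length(eq) - d + 1)]
    if (max(wins) / d >= min_identity) return(TRUE)
  }
  FALSE
}

# ---- brute-force duplication-loss minimiser --------------------------------
# Enumerates every valid mapping of gene internal nodes to species nodes
# (each node mapped to an ancestor-or-self of the join of its children's
# images) and minimises duplications + losses under the subtree event rule.

oracle_dl <- function(gene_tree, species_tree, leaf_map) {
  st_idx <- local({
    n_tip <- length(species_tree$tip.label)
    parent <- rep(NA_integer_, n_tip + species_tree$Nnode)
    parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
    depth <- rep(NA_integer_, length(parent))
    depth[n_tip + 1] <- 0L
    repeat {
      done <- TRUE
      for (e in seq_len(nrow(species_tree$edge))) {
        p <- species_tree$edge[e, 1]; c0 <- species_tree$edge[e, 2]
        if (!is.na(depth[p]) && is.na(depth[c0])) { depth[c0] <- depth[p] + 1L; done <- FALSE }
      }
      if (done) break
    }
    list(n_tip = n_tip, parent = parent, depth = depth)
  })
  ancestors_incl <- function(v) {
    out <- v
    while (!is.na(st_idx$parent[v])) { v <- st_idx$parent[v]; out <- c(out, v) }
    out
  }
  is_anc <- function(a, d) a %in% ancestors_incl(d)   # a ancestor-or-self of d
  join <- function(a, b) {
    aa <- ancestors_incl(a)
    for (v in ancestors_incl(b)) if (v %in% aa) return(v)
  }
  n_gtip <- length(gene_tree$tip.label)
  g_parent <- rep(NA_integer_, n_gtip + gene_tree$Nnode)
  g_parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  g_kids <- split(gene_tree$edge[, 2], gene_tree$edge[, 1])
  post <- unique(ape::reorder.phylo(gene_tree, "postorder")$edge[, 1])
  M0 <- rep(NA_integer_, length(g_parent))
  M0[seq_len(n_gtip)] <- match(leaf_map[gene_tree$tip.label], species_tree$tip.label)

  cost_of <- function(M) {
    dups <- 0L; losses <- 0L
    for (v in post) {
      ch <- g_kids[[as.character(v)]]
      # speciation iff both children map strictly below M[v] into different
      # child subtrees of M[v]
      spec <- FALSE
      if (M[ch[1]] != M[v] && M[ch[2]] != M[v]) {
        up <- function(d) { while (st_idx$parent[d] != M[v]) d <- st_idx$parent[d]; d }
        spec <- up(M[ch[1]]) != up(M[ch[2]])
      }
      if (!spec) dups <- dups + 1L
    }
    for (v in seq_along(M)) {
      u <- g_parent[v]
      if (is.na(u)) next
      d <- st_idx$depth[M[v]] - st_idx$depth[M[u]]
      is_dup <- {
        ch <- g_kids[[as.character(u)]]
        spec <- FALSE
        if (M[ch[1]] != M[u] && M[ch[2]] != M[u]) {
          up <- function(dd) { while (st_idx$parent[dd] != M[u]) dd <- st_idx$parent[dd]; dd }
          spec <- up(M[ch[1]]) != up(M[ch[2]])
        }
        !spec
      }
      losses <- losses + max(0L, d - 1L + as.integer(is_dup))
    }
    c(dups = dups, losses = losses)
  }

  best <- NULL
  recurse <- function(i, M) {
    if (i > length(post)) {
      cc <- cost_of(M)
      tot <- sum(cc)
      if (is.null(best) || tot < sum(best)) best <<- cc
      return(invisible(NULL))
    }
    v <- post[i]
    ch <- g_kids[[as.character(v)]]
    base <- join(M[ch[1]], M[ch[2]])
    for (cand in ancestors_incl(base)) {
      M[v] <- cand
      recurse(i + 1, M)
    }
  }
  recurse(1, M0)
  best
}

# Random gene/species tree pair with random (possibly multi-copy) sampling.
random_dl_instance <- function(seed, max_species = 6) {
  set.seed(seed)
  n_sp <- sample(3:max_species, 1)
  st <- ape::rtree(n_sp, tip.label = paste0("s", seq_len(n_sp)))
  n_genes <- sample(2:n_sp, 1)
  gt <- ape::rtree(n_genes, tip.label = paste0("g", seq_len(n_genes)))
  species_of <- sample(st$tip.label, n_genes, replace = TRUE)
  list(gene_tree = gt, species_tree = st,
       leaf_map = stats::setNames(species_of, gt$tip.label))
}

# ---- closed-form expected duplications (loss rate 0) -----------------------

expected_duplications <- function(species_tree, dup_rate) {
  n_tip <- length(species_tree$tip.label)
  parent <- rep(NA_integer_, n_tip + species_tree$Nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  elen <- stats::setNames(species_tree$edge.length, species_tree$edge[, 2])
  total <- 0
  for (e in seq_len(nrow(species_tree$edge))) {
    child <- species_tree$edge[e, 2]
    n_in <- 1
    v <- parent[child]
    while (!is.na(parent[v])) {
      n_in <- n_in * exp(dup_rate * elen[[as.character(v)]])
      v <- parent[v]
    }
    total <- total + n_in * (exp(dup_rate * elen[[as.character(child)]]) - 1)
  }
  total
}

# ---- bipartition helpers ---------------------------------------------------

tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n_tip <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n_tip))
  keys <- character()
  for (nd in internal) {
    cl <- ape::extract.clade(tree, nd)$tip.label
    side <- if (ref %in% cl) setdiff(tips, cl) else cl
    if (length(side) >= 2 && length(side) <= n_tip - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

has_split <- function(tree, tip_set) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  side <- if (ref %in% tip_set) sort(setdiff(tips, tip_set)) else sort(tip_set)
  paste(side, collapse = "|") %in% tree_splits(tree)
}
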
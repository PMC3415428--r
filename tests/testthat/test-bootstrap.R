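make_two_clade_alignment <- function(seed, n_per = 4, len = 300) {
  set.seed(seed)
  anc <- random_nt(len)
  a_root <- mutate_nt(anc, 0.15)
  b_root <- mutate_nt(anc, 0.15)
  rows <- c(
    vapply(1:n_per, function(i) mutate_nt(a_root, 0.01), character(1)),
    vapply(1:n_per, function(i) mutate_nt(b_root, 0.01), character(1))
  )
  names(rows) <- c(paste0("A", 1:n_per), paste0("B", 1:n_per))
  alignment(rows, "nucleotide")
}

test_that("bootstrap supports are deterministic in the seed and bounded", {
  aln <- make_two_clade_alignment(1)
  t1 <- bootstrap_support(aln, n_reps = 30, seed = 5)
  t2 <- bootstrap_support(aln, n_reps = 30, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(t1$node.label, t2$node.label)
  sup <- t1$node.label[!is.na(t1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("a deep split between clades earns high support", {
  for (seed in 1:10) {
    aln <- make_two_clade_alignment(seed)
    tr <- bootstrap_support(aln, n_reps = 100, seed = seed)
    expect_true(has_split(tr, paste0("A", 1:4)))
    # support of the A-vs-B bipartition
    n_tip <- length(tr$tip.label)
    found <- NA_real_
    for (nd in (n_tip + 2L):(n_tip + tr$Nnode)) {
      cl <- sort(ape::extract.clade(tr, nd)$tip.label)
      if (identical(cl, sort(paste0("A", 1:4))) ||
          identical(cl, sort(paste0("B", 1:4)))) {
        found <- tr$node.label[nd - n_tip]
      }
    }
    expect_gte(found, 95)
  }
})

test_that("collapsing removes exactly the weak bipartitions", {
  aln <- make_two_clade_alignment(2)
  tr <- bootstrap_support(aln, n_reps = 100, seed = 9)

  keep_all <- collapse_low_support(tr, threshold = 0)
  expect_identical(sort(tree_splits(keep_all)), sort(tree_splits(tr)))

  col <- collapse_low_support(tr, threshold = 40)
  expect_true(all(tree_splits(col) %in% tree_splits(tr)))
  expect_identical(sort(col$tip.label), sort(tr$tip.label))

  star <- collapse_low_support(tr, threshold = 101)
  expect_identical(length(tree_splits(star)), 0L)
  expect_identical(sort(star$tip.label), sort(tr$tip.label))

  # contracted edge lengths are pushed onto child edges: tip depths preserved
  dd0 <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  dd1 <- ape::node.depth.edgelength(star)[seq_along(star$tip.label)]
  names(dd0) <- tr$tip.label
  names(dd1) <- star$tip.label
  expect_equal(dd1[names(dd0)], dd0, tolerance = 1e-8)
})
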
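test_that("congruent gene trees reconcile with zero events", {
  s <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  g <- ape::read.tree(text = "((a_g:1,b_g:1):1,(c_g:1,d_g:1):1);")
  lm <- stats::setNames(c("a", "b", "c", "d"), c("a_g", "b_g", "c_g", "d_g"))
  r <- lca_reconcile(g, s, lm)
  expect_identical(r$total_duplications, 0L)
  expect_identical(r$total_losses, 0L)
  expect_true(all(r$events == "speciation"))
})

test_that("the textbook four-leaf duplication is placed at the root", {
  g <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  s <- ape::read.tree(text = "(a:1,b:1);")
  lm <- stats::setNames(c("a", "b", "a", "b"), c("a1", "b1", "a2", "b2"))
  r <- lca_reconcile(g, s, lm)
  expect_identical(r$total_duplications, 1L)
  expect_identical(r$total_losses, 0L)
  root <- length(g$tip.label) + 1L
  expect_identical(unname(r$events[as.character(root)]), "duplication")
  expect_identical(r$node_map[root], length(s$tip.label) + 1L)
})

test_that("reconciliation rejects malformed inputs", {
  s <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  g <- ape::read.tree(text = "(a_g:1,b_g:1);")
  expect_error(lca_reconcile(g, s, stats::setNames("a", "a_g")),
               "unmapped gene leaf")
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(lca_reconcile(g, poly, stats::setNames(c("a", "b"),
                                                      c("a_g", "b_g"))),
               "polytomies|rooted")
})

test_that("LCA reconciliation matches the brute-force minimiser", {
  for (seed in 1:40) {
    inst <- random_dl_instance(seed)
    mine <- lca_reconcile(inst$gene_tree, inst$species_tree, inst$leaf_map)
    oracle <- oracle_dl(inst$gene_tree, inst$species_tree, inst$leaf_map)
    expect_identical(mine$total_duplications, as.integer(oracle[["dups"]]))
    expect_identical(mine$total_losses, as.integer(oracle[["losses"]]))
  }
})

test_that("event recovery from simulations behaves as theory predicts", {
  sp <- ape::read.tree(
    text = "((a:1,b:1):0.5,(c:0.7,(d:0.4,e:0.4):0.3):0.8);")
  sim0 <- simulate_gene_family(sp, 0, 0.3, 21)
  r0 <- recover_events(sim0)
  expect_identical(r0$inferred_duplications, 0L)

  for (sd in 1:50) {
    sim <- simulate_gene_family(sp, 0.25, 0.25, sd)
    r <- recover_events(sim)
    if (!is.null(sim$gene_tree)) {
      expect_lte(r$inferred_duplications, r$true_duplications)
    }
  }
})

test_that("the defensin fixture places the duplication at the bee+ant LCA", {
  sc <- defensin_scenario()
  rec <- sc$reconciliation
  expect_identical(rec$total_duplications, 1L)
  st <- defensin_species_tree()
  root_label <- species_node_label(st, length(st$tip.label) + 1L)
  expect_identical(sc$duplication_images, root_label)
  # every single-copy species lost a copy on its own terminal branch
  single <- setdiff(st$tip.label, c("Camponotus_floridanus", "Solenopsis_invicta"))
  expect_true(all(single %in% sc$losses$label))
  expect_true(all(sc$losses$count[sc$losses$label %in% single] >= 1L))

  # with every species reduced to a single copy (species-congruent gene
  # tree) the duplication signal disappears
  gt1 <- st
  gt1$tip.label <- paste0(st$tip.label, "_def1")
  lm1 <- stats::setNames(st$tip.label, gt1$tip.label)
  r1 <- lca_reconcile(gt1, st, lm1)
  expect_identical(r1$total_duplications, 0L)
  expect_identical(r1$total_losses, 0L)
})

test_that("dropping a gene leaf never increases inferred duplications", {
  gt <- defensin_gene_tree()
  st <- defensin_species_tree()
  full <- lca_reconcile(gt, st, defensin_leaf_map())$total_duplications
  for (tip in gt$tip.label) {
    sub <- ape::drop.tip(gt, tip)
    r <- lca_reconcile(sub, st, defensin_leaf_map()[sub$tip.label])
    expect_lte(r$total_duplications, full)
  }
})
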
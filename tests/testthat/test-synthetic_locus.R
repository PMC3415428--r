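test_that("the default precursor locus reproduces the published dimensions", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  expect_identical(repeat_unit_nt(spec), 309L)
  expect_identical(nchar(b$protein_seq), 775L)
  expect_identical(nchar(b$cdna_seq), 2536L)
  expect_identical(nchar(b$genomic_seq), 3356L)
  expect_identical(intron_lengths(b$truth_gene_model), 820L)
  expect_identical(substr(b$protein_seq, 39L, 39L), "H")
  # the tandem region is an exact tiling of one 309-nt unit
  ann <- b$truth_annotation
  sp1 <- ann[ann$role == "spacer", ][1, ]
  m <- b$truth_gene_model
  nt0 <- m$cds_start_on_cdna + 3L * (sp1$start - 1L)
  unit <- substr(b$cdna_seq, nt0, nt0 + 309L - 1L)
  tiled <- paste(rep(unit, 6L), collapse = "")
  expect_identical(substr(b$cdna_seq, nt0, nt0 + 6L * 309L - 1L), tiled)
})

test_that("a repeat-free spec yields signal+pro+cleavage+HLD+cleavage only", {
  spec <- architecture_spec(19, 26, 108, 97, n_repeats = 0,
                            utr5_len = 40, utr3_len = 40)
  b <- generate_precursor_locus(spec, 7)
  expect_identical(nchar(b$protein_seq), 19L + 26L + 2L + 108L + 2L)
  expect_identical(b$truth_annotation$role,
                   c("signal", "pro", "cleavage", "HLD", "cleavage"))
  reps <- find_tandem_repeats(b$cdna_seq, min_period = 30, max_period = 200)
  expect_identical(nrow(reps), 0L)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  spec <- hymenoptaecin_spec()
  b1 <- generate_precursor_locus(spec, 123)
  b2 <- generate_precursor_locus(spec, 123)
  expect_identical(b1, b2)
  b3 <- generate_precursor_locus(spec, 124)
  expect_false(identical(b1$protein_seq, b3$protein_seq))
  expect_identical(nchar(b1$protein_seq), nchar(b3$protein_seq))
  expect_identical(b1$truth_annotation$end, b3$truth_annotation$end)
})

test_that("bundles satisfy the splice/translate round-trip invariant", {
  for (seed in 1:25) {
    b <- generate_precursor_locus(random_arch_spec(seed), seed)
    m <- b$truth_gene_model
    expect_identical(spliced_cdna(b$genomic_seq, m), b$cdna_seq)
    cds <- substr(b$cdna_seq, m$cds_start_on_cdna,
                  m$cds_start_on_cdna + m$cds_len_nt - 1L)
    expect_identical(translate_cds(cds), b$protein_seq)
    expect_identical(nchar(b$genomic_seq) - nchar(b$cdna_seq),
                     sum(intron_lengths(m)))
  }
})

test_that("intron placements outside the coding region are rejected", {
  expect_error(
    architecture_spec(19, 26, 108, 97, 6,
                      introns = list(list(after_codon = 10000, length = 100))),
    "outside the coding region")
  expect_error(
    architecture_spec(19, 26, 108, 97, 6,
                      introns = list(list(after_codon = 5, length = 100),
                                     list(within_codon = 5, phase = 3, length = 50))),
    "phase")
})

test_that("defensin loci reproduce the printed exon arithmetic", {
  d1 <- defensin1_fixture(1)
  expect_identical(nchar(d1$protein_seq), 102L)
  expect_identical(cds_exon_lengths(d1$truth_gene_model), c(64L, 229L, 13L))
  expect_identical(intron_lengths(d1$truth_gene_model), c(399L, 360L))
  expect_identical(nchar(d1$cdna_seq), 535L)

  d2 <- defensin2_fixture(1)
  expect_identical(nchar(d2$protein_seq), 97L)
  expect_identical(cds_exon_lengths(d2$truth_gene_model), c(97L, 194L))
  expect_identical(intron_lengths(d2$truth_gene_model), 1043L)
  expect_identical(nchar(d2$cdna_seq), 1238L)

  single <- generate_defensin_locus(3L, integer(), c(0L, 0L, 1L, 0L), seed = 2)
  expect_identical(nchar(single$protein_seq), 1L)
  expect_identical(nrow(single$truth_gene_model$introns), 0L)

  expect_error(generate_defensin_locus(c(64L, 230L, 13L), c(399L, 360L),
                                       c(17L, 40L, 44L, 1L), seed = 1),
               "not divisible by 3")
})

test_that("domain divergence mutates HDs but preserves motifs and truth", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  expect_identical(diverge_domains(b, 0, 1), b)

  idents <- numeric(0)
  for (seed in 1:20) {
    d <- diverge_domains(b, 0.05, seed)
    ann <- d$truth_annotation
    m <- d$truth_gene_model
    hd <- ann[ann$role == "HD", ]
    frags <- substring(d$cdna_seq, m$cds_start_on_cdna + 3L * (hd$start - 1L),
                       m$cds_start_on_cdna + 3L * hd$end - 1L)
    pw <- utils::combn(6, 2, function(ij) nt_identity(frags[ij[1]], frags[ij[2]]))
    idents <- c(idents, mean(pw))
    # motif columns untouched
    motif_rows <- ann[ann$role %in% c("spacer", "cleavage"), ]
    expect_identical(substring(d$protein_seq, motif_rows$start, motif_rows$end),
                     substring(b$protein_seq, motif_rows$start, motif_rows$end))
    expect_identical(d$truth_annotation$end, b$truth_annotation$end)
  }
  expect_lt(mean(idents), 1)
  expect_gt(mean(idents), 0.8)
})

test_that("gene-family simulation matches its closed-form expectation", {
  sp <- ape::read.tree(
    text = "((a:1,b:1):0.5,(c:0.7,(d:0.4,e:0.4):0.3):0.8);")
  sim0 <- simulate_gene_family(sp, 0, 0, 3)
  expect_identical(sim0$true_duplications, 0L)
  expect_identical(sim0$true_losses, 0L)
  gt0 <- sim0$gene_tree
  gt0$tip.label <- unname(sim0$leaf_to_species[gt0$tip.label])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gt0), ape::unroot(sp))), 0)

  expect_identical(simulate_gene_family(sp, 0.3, 0.2, 9),
                   simulate_gene_family(sp, 0.3, 0.2, 9))
  expect_error(simulate_gene_family(sp, -1, 0, 1), "non-negative")

  dups <- vapply(1:200, function(sd) {
    simulate_gene_family(sp, 0.3, 0, sd)$true_duplications
  }, integer(1))
  expected <- expected_duplications(sp, 0.3)
  se <- stats::sd(dups) / sqrt(length(dups))
  expect_lt(abs(mean(dups) - expected), 2 * se + 1e-9)
})
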
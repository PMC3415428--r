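test_that("pairwise alignment scores match the scoring definition", {
  # identical 10-mers: no gaps, diagonal BLOSUM62 sum
  s <- "MKVLAWTFYQ"
  pa <- pairwise_align(s, s)
  S <- ampstruct:::.subst_matrix("protein")
  expect_equal(pa$score, sum(diag(S[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  expect_false(any(grepl("-", pa$alignment$rows)))

  # a single unmatched residue costs one gap open + extend
  pg <- pairwise_align("A", "", kind = "nucleotide")
  expect_equal(pg$score, -10.5)
  expect_identical(unname(pg$alignment$rows), c("A", "-"))
})

test_that("pairwise alignment equals the exhaustive oracle on short pairs", {
  Sp <- ampstruct:::.subst_matrix("protein")
  Sn <- ampstruct:::.subst_matrix("nucleotide")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(17)
  for (i in 1:30) {
    a <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_align(a, b, kind = "protein")$score,
                 oracle_align_score(a, b, Sp), tolerance = 1e-9)
  }
  for (i in 1:20) {
    a <- random_nt(sample(2:8, 1))
    b <- random_nt(sample(2:8, 1))
    expect_equal(pairwise_align(a, b, kind = "nucleotide")$score,
                 oracle_align_score(a, b, Sn), tolerance = 1e-9)
  }
})

test_that("progressive MSA aligns equal-length substitution-only domains gaplessly", {
  b <- generate_precursor_locus(hymenoptaecin_spec(), 42)
  ann <- b$truth_annotation
  m <- b$truth_gene_model
  hd <- ann[ann$role == "HD", ]
  frags0 <- substring(b$cdna_seq, m$cds_start_on_cdna + 3L * (hd$start - 1L),
                      m$cds_start_on_cdna + 3L * hd$end - 1L)
  names(frags0) <- paste0("HD", 1:6)
  aln0 <- progressive_msa(frags0, kind = "nucleotide")
  expect_false(any(grepl("-", aln0$rows)))

  d <- diverge_domains(b, 0.05, 4)
  frags <- substring(d$cdna_seq, m$cds_start_on_cdna + 3L * (hd$start - 1L),
                     m$cds_start_on_cdna + 3L * hd$end - 1L)
  names(frags) <- paste0("HD", 1:6)
  aln <- progressive_msa(frags, kind = "nucleotide")
  # substitution-only divergence: truth-homologous columns stay aligned
  expect_false(any(grepl("-", aln$rows)))
  expect_identical(unname(nchar(aln$rows[1])), 291L)

  set.seed(8)
  shuf <- sample(frags)
  aln2 <- progressive_msa(shuf, kind = "nucleotide")
  expect_identical(aln$rows[sort(names(frags))], aln2$rows[sort(names(frags))])
})

test_that("block cleaning keeps conserved runs and enforces min_block", {
  rows <- c(a = "MKVLAWTFYQMKVLAWTFYQ", b = "MKVLAWTFYQMKVLAWTFYQ")
  aln <- alignment(rows, "protein")
  expect_identical(clean_blocks(aln)$rows, aln$rows)

  # a >50% gap column inside a conserved run splits it; short side dropped
  r2 <- c(a = "MKVLAW-TFYQQQ", b = "MKVLAW-TFYQQQ", c = "MKVLAWATFYQQQ")
  a2 <- alignment(r2, "protein")
  cleaned <- clean_blocks(a2, min_block = 5)
  expect_identical(unname(nchar(cleaned$rows[1])), 12L)
  expect_false(any(grepl("-", cleaned$rows)))

  r3 <- c(a = "MK-LAW", b = "MQ-LAW", c = "ACADEF")
  expect_error(clean_blocks(alignment(r3, "protein"), min_block = 5),
               "no blocks retained")

  for (seed in 1:5) {
    set.seed(seed)
    rows <- replicate(4, paste(sample(c("A", "C", "G", "T", "-"), 40,
                                      replace = TRUE, prob = c(.3, .3, .15, .15, .1)),
                               collapse = ""))
    names(rows) <- paste0("r", 1:4)
    aln <- tryCatch(alignment(rows, "nucleotide"), error = function(e) NULL)
    if (is.null(aln)) next
    cl <- tryCatch(clean_blocks(aln), error = function(e) NULL)
    if (!is.null(cl)) expect_lte(nchar(cl$rows[1]), nchar(aln$rows[1]))
  }
})

test_that("alignment distances follow the closed forms", {
  ident <- alignment(c(x = "MKVLAWTFYQ", y = "MKVLAWTFYQ"), "protein")
  expect_true(all(distance_matrix(ident, "p") == 0))

  two <- alignment(c(x = "AAAAAAAAAA", y = "AAAAAAAACC"), "protein")
  expect_equal(distance_matrix(two, "p")["x", "y"], 0.2)
  expect_equal(distance_matrix(two, "poisson")["x", "y"], -log(0.8))

  sat <- alignment(c(x = "AAAA", y = "CCCC"), "protein")
  expect_error(distance_matrix(sat, "poisson"), "saturated")

  set.seed(3)
  rows <- vapply(1:5, function(i) random_nt(60), character(1))
  names(rows) <- paste0("s", 1:5)
  D <- distance_matrix(alignment(rows, "nucleotide"), "p")
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})
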
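test_that("splice mapping recovers trivial and single-intron models", {
  seq1 <- random_nt(400)
  m0 <- splice_map(seq1, seq1)
  expect_identical(nrow(m0$exons), 1L)
  expect_identical(nrow(m0$introns), 0L)

  b <- generate_precursor_locus(hymenoptaecin_spec(), 42)
  m <- splice_map(b$genomic_seq, b$cdna_seq)
  expect_identical(nrow(m$exons), 2L)
  expect_identical(intron_lengths(m), 820L)
  expect_identical(m$exons, b$truth_gene_model$exons)

  expect_error(splice_map(random_nt(500), random_nt(100)),
               "first unmappable cDNA offset")
})

test_that("splice mapping equals the generator truth on random loci", {
  for (seed in 1:100) {
    b <- generate_precursor_locus(random_arch_spec(seed, n_introns = 2), seed)
    m <- splice_map(b$genomic_seq, b$cdna_seq)
    expect_identical(m$exons, b$truth_gene_model$exons)
    expect_identical(nchar(b$genomic_seq) - nchar(b$cdna_seq),
                     sum(intron_lengths(m)))
  }
})

test_that("intron reports carry the printed phases and interrupted codons", {
  d1 <- defensin1_fixture(1)
  r1 <- intron_report(d1$truth_gene_model, protein = d1$protein_seq)
  expect_identical(r1$phase, c("1", "2"))
  expect_identical(r1$codon, c(22L, 98L))
  expect_identical(r1$residue, c("E", "A"))
  expect_identical(r1$length, c(399L, 360L))

  d2 <- defensin2_fixture(1)
  r2 <- intron_report(d2$truth_gene_model, protein = d2$protein_seq)
  expect_identical(r2$phase, "1")
  expect_identical(r2$codon, 33L)
  expect_identical(r2$residue, "T")

  b <- generate_precursor_locus(hymenoptaecin_spec(), 42)
  rh <- intron_report(b$truth_gene_model, protein = b$protein_seq)
  expect_identical(rh$phase, "0")
  expect_identical(rh$interrupted_codon, "between 39|40")
  expect_identical(rh$residue, "H")
})

test_that("introns upstream of the CDS are reported as noncoding", {
  # one intron inside the 5' UTR: exons on cDNA (30, rest), CDS starts at 41
  cdna <- random_nt(300)
  intron <- paste0("GT", random_nt(96), "AG")
  genomic <- paste0(substr(cdna, 1, 30), intron, substr(cdna, 31, 300))
  model <- gene_model(rbind(c(1L, 30L), c(131L, 400L)),
                      cds_start_on_cdna = 41L, cds_len_nt = 240L)
  rep0 <- intron_report(model)
  expect_identical(rep0$phase, "noncoding")
})

test_that("coding protein length follows the printed exon sums", {
  d1 <- defensin1_fixture(1)
  expect_identical(coding_protein_length(d1$truth_gene_model), 102L)
  d2 <- defensin2_fixture(1)
  expect_identical(coding_protein_length(d2$truth_gene_model), 97L)

  empty <- gene_model(rbind(c(1L, 90L)), cds_start_on_cdna = 1L, cds_len_nt = 0L)
  expect_identical(coding_protein_length(empty), 0L)

  odd <- gene_model(rbind(c(1L, 90L)), cds_start_on_cdna = 1L, cds_len_nt = 80L)
  expect_error(coding_protein_length(odd), "not divisible by 3")
})
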
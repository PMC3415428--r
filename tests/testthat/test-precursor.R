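test_that("cleavage-site scanning is leftmost-greedy and non-overlapping", {
  b <- generate_precursor_locus(hymenoptaecin_spec(), 42)
  sites <- scan_cleavage_sites(b$protein_seq)
  expect_identical(nrow(sites), 8L)   # after pro, after HLD, after each HD
  # brute-force motif count agrees: sites found by the generator layout
  ann <- b$truth_annotation
  expect_identical(sites$start, ann$start[ann$role == "cleavage"])

  expect_identical(nrow(scan_cleavage_sites("MAAAA")), 0L)
  s <- scan_cleavage_sites("ARRRA")
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 2L)
  expect_identical(s$position, 3L)

  r <- scan_cleavage_sites("ARTTRAA", include_rxxr = TRUE)
  expect_identical(r$motif, "RTTR")
  expect_identical(r$position, 5L)
})

test_that("the default precursor parses into the published architecture", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  ann <- segment_precursor(b$protein_seq, spec)
  expect_identical(n_hd(ann), 6L)
  hd <- ann[ann$role == "HD", ]
  expect_true(all(hd$end - hd$start + 1L == 97L))
  expect_true(all(substring(b$protein_seq, hd$start, hd$start) == "Q"))
  hld <- ann[ann$role == "HLD", ]
  expect_identical(hld$end - hld$start + 1L, 108L)
  expect_identical(substr(b$protein_seq, hld$start, hld$start), "G")

  one <- architecture_spec(19, 26, 108, 97, n_repeats = 1)
  b1 <- generate_precursor_locus(one, 5)
  expect_identical(n_hd(segment_precursor(b1$protein_seq, one)), 1L)

  expect_error(segment_precursor("MAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
                                 architecture_spec(10, 10, 5, 5, 0)),
               "expected dibasic cleavage motif")
})

test_that("the parser inverts the generator over random architectures", {
  for (seed in 1:40) {
    spec <- random_arch_spec(seed)
    b <- generate_precursor_locus(spec, seed + 1000)
    ann <- segment_precursor(b$protein_seq, spec)
    expect_identical(as.data.frame(ann), as.data.frame(b$truth_annotation))
  }
})

test_that("segment-to-cDNA mapping follows the 3x rule and translates back", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  ann <- segment_precursor(b$protein_seq, spec)
  cds_start <- b$truth_gene_model$cds_start_on_cdna
  mapped <- map_segments_to_cdna(ann, cds_start, nchar(b$cdna_seq))
  hd <- mapped[mapped$role == "HD", ]
  expect_true(all(hd$nt_end - hd$nt_start + 1L == 291L))
  # spacer + HD + cleavage = one 309-nt repeat unit
  i_sp <- which(mapped$role == "spacer")[1]
  expect_identical(mapped$nt_end[i_sp + 2L] - mapped$nt_start[i_sp] + 1L, 309L)

  for (seed in 1:10) {
    bb <- generate_precursor_locus(random_arch_spec(seed), seed)
    aa <- segment_precursor(bb$protein_seq, bb$spec)
    mm <- map_segments_to_cdna(aa, bb$truth_gene_model$cds_start_on_cdna)
    for (i in seq_len(nrow(mm))) {
      frag <- substr(bb$cdna_seq, mm$nt_start[i], mm$nt_end[i])
      expect_identical(translate_cds(frag),
                       substr(bb$protein_seq, mm$start[i], mm$end[i]))
    }
  }

  expect_error(map_segments_to_cdna(ann, cds_start, cdna_len = 100L),
               "outside the cDNA")
})
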
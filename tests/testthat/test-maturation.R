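test_that("endoprotease cutting splits after dibasic sites and conserves residues", {
  p <- "AAKRNNNRRCC"
  fr <- endoprotease_cut(p, scan_cleavage_sites(p))
  expect_identical(fr$sequence, c("AAKR", "NNNRR", "CC"))
  expect_identical(paste(fr$sequence, collapse = ""), p)

  no <- endoprotease_cut("MAAAA", scan_cleavage_sites("MAAAA"))
  expect_identical(no$sequence, "MAAAA")

  set.seed(2)
  for (i in 1:100) {
    prot <- paste(sample(c("A", "C", "G", "K", "R", "Q", "S"), 60,
                         replace = TRUE), collapse = "")
    fr <- endoprotease_cut(prot, scan_cleavage_sites(prot))
    expect_identical(paste(fr$sequence, collapse = ""), prot)
  }
})

test_that("trimming rules match the stated enzyme specificities", {
  expect_identical(carboxypeptidase_trim("AAQGRR"), "AAQG")
  expect_identical(carboxypeptidase_trim("AAQG"), "AAQG")
  expect_identical(carboxypeptidase_trim("AKRKR"), "AKR")        # at most 2
  expect_identical(carboxypeptidase_trim("AKRKR", max_trim = Inf), "A")

  expect_identical(dipeptidyl_trim("EAEPQAB"), "QAB")
  expect_identical(dipeptidyl_trim("QAEPX"), "QAEPX")
  expect_identical(dipeptidyl_trim("EPEAEAXYZ"), "XYZ")
  # the EANP spacer variant is only partially removable under the default set
  expect_identical(dipeptidyl_trim("EANPQ"), "NPQ")
  expect_identical(dipeptidyl_trim("EANPQ", dipeptides = c("EA", "NP")), "Q")
})

test_that("maturation of the default precursor releases the published peptides", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  suppressMessages(peps <- mature_peptides(b$protein_seq, spec))
  expect_identical(nrow(peps), 7L)
  expect_identical(peps$length[1], 108L)
  expect_identical(peps$n_term[1], "G")
  expect_true(all(peps$length[-1] == 97L))
  expect_true(all(peps$n_term[-1] == "Q"))
  expect_true(all(peps$pyroglutamate_capable[-1]))
  expect_false(peps$pyroglutamate_capable[1])
  # provenance: the peptide sequences sit at their stated precursor intervals
  expect_identical(substring(b$protein_seq, peps$start, peps$end), peps$sequence)
  # no peptide retains a C-terminal basic pair
  expect_false(any(grepl("[RK][RK]$", peps$sequence)))

  acct <- maturation_accounting(peps)
  expect_identical(sum(acct[c("signal", "pro_fragment", "c_terminal_trim",
                              "n_terminal_trim", "peptides_total")]),
                   acct[["total_in"]])

  solo <- architecture_spec(19, 26, 108, 97, n_repeats = 0)
  bs <- generate_precursor_locus(solo, 3)
  suppressMessages(ps <- mature_peptides(bs$protein_seq, solo))
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$length, 108L)
})

test_that("maturation is idempotent on already-mature peptides", {
  spec <- hymenoptaecin_spec()
  b <- generate_precursor_locus(spec, 42)
  suppressMessages(peps <- mature_peptides(b$protein_seq, spec))
  for (s in peps$sequence) {
    expect_identical(nrow(scan_cleavage_sites(s)), 0L)
    expect_identical(carboxypeptidase_trim(s), s)
    expect_identical(dipeptidyl_trim(s), s)
  }
})

test_that("peptide count equals 1 + n_repeats across random architectures", {
  for (seed in 1:30) {
    spec <- random_arch_spec(seed)
    b <- generate_precursor_locus(spec, seed + 500)
    suppressMessages(peps <- mature_peptides(b$protein_seq, spec))
    expect_identical(nrow(peps), 1L + spec$n_repeats)
    expect_identical(peps$length[1], spec$hld_len)
    if (spec$n_repeats > 0) {
      expect_true(all(peps$length[-1] == spec$hd_len))
    }
  }
})
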
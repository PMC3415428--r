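# Seeded synthetic-locus generation. A locus bundle carries genomic sequence,
# cDNA, precursor protein and the truth records (gene model + precursor
# annotation) that downstream stages are tested against.
#
# Two generator guards keep the construction consistent with its own grammar:
#  * drawn residues never extend a run of basic residues (no accidental
#    dibasic cleavage sites) and never sit immediately before a cleavage
#    motif as R/K (which would shift the leftmost-greedy site scan);
#  * the codon immediately downstream of each intron avoids G at the first
#    exon base where the residue permits, so the exon/intron boundary cannot
#    slide and exact splice mapping recovers the truth model.

.BASES <- c("A", "C", "G", "T")

.sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.rand_nt <- function(n) {
  if (n == 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Amino acids having at least one codon whose base `b` is not G.
.aa_ok_for_base <- function(b) {
  ok <- vapply(.AA20, function(a) {
    any(substr(.CODON_TABLE[[a]], b, b) != "G")
  }, logical(1))
  .AA20[ok]
}

# Sample a codon for `aa`; `avoid_g_at` lists base positions that should not
# be G (soft constraint: ignored when no codon satisfies it).
.sample_codon <- function(aa, avoid_g_at = integer()) {
  cods <- .CODON_TABLE[[aa]]
  if (length(avoid_g_at) > 0L) {
    keep <- rep(TRUE, length(cods))
    for (b in avoid_g_at) keep <- keep & substr(cods, b, b) != "G"
    if (any(keep)) cods <- cods[keep]
  }
  .sample_one(cods)
}

# Draw one residue given the previous residue, guards and an allowed set.
.draw_residue <- function(prev, pre_motif = FALSE, allowed = .AA20) {
  if (!is.na(prev) && prev %in% c("R", "K")) allowed <- setdiff(allowed, c("R", "K"))
  if (pre_motif) allowed <- setdiff(allowed, c("R", "K"))
  .sample_one(allowed)
}

#' Generate a synthetic multipeptide precursor locus
#'
#' Builds a precursor protein following the layout of `spec` (signal + pro +
#' cleavage + HLD + cleavage + n_repeats x (spacer + HD + cleavage)),
#' back-translates it with seeded uniform synonymous codon choice, adds UTRs
#' and GT..AG introns, and records the truth gene model and precursor
#' annotation. The repeat unit is drawn once and tiled, so the undiverged
#' cDNA carries an exact tandem repeat of `repeat_unit_nt(spec)` nt.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @return An object of class `locus_bundle` with elements `genomic_seq`,
#'   `cdna_seq`, `protein_seq`, `truth_gene_model`, `truth_annotation`,
#'   `spec`, `seed`.
#' @export
generate_precursor_locus <- function(spec, seed) {
  validate_architecture_spec(spec)
  set.seed(as.integer(seed))

  cm <- strsplit(spec$cleavage_motif, "")[[1L]]
  sp <- strsplit(spec$spacer_motif, "")[[1L]]
  prefix_len <- spec$signal_len + spec$pro_len + length(cm) + spec$hld_len + length(cm)
  unit_len <- length(sp) + spec$hd_len + length(cm)
  p_len <- prefix_len + spec$n_repeats * unit_len

  fixed <- spec$fixed_residues
  if (length(fixed) > 0L) {
    fpos <- as.integer(names(fixed))
    if (any(is.na(fpos)) || any(fpos < 1L) || any(fpos > prefix_len)) {
      stop("fixed_residues must name 1-based positions within the non-repeat prefix")
    }
  }

  # Intron-adjacent codon constraints: codon index -> base positions != G.
  offs <- intron_cds_offsets(spec)
  constr <- list()
  for (o in offs) {
    ci <- o %/% 3L + 1L
    b <- o %% 3L + 1L
    key <- as.character(ci)
    constr[[key]] <- union(constr[[key]], b)
  }
  # Map protein position -> constrained base positions (repeat tiles share
  # the unit template, so constraints inside repeats are unioned unit-locally).
  tmpl_constr_prefix <- list()   # prefix position -> bases
  tmpl_constr_unit <- list()     # unit-local position -> bases
  for (key in names(constr)) {
    ci <- as.integer(key)
    if (ci <= prefix_len) {
      k2 <- as.character(ci)
      tmpl_constr_prefix[[k2]] <- union(tmpl_constr_prefix[[k2]], constr[[key]])
    } else {
      loc <- as.character((ci - prefix_len - 1L) %% unit_len + 1L)
      tmpl_constr_unit[[loc]] <- union(tmpl_constr_unit[[loc]], constr[[key]])
    }
  }
  res_allowed <- function(bases) {
    if (is.null(bases)) return(.AA20)
    a <- .AA20
    for (b in bases) a <- intersect(a, .aa_ok_for_base(b))
    if (length(a) == 0L) .AA20 else a
  }

  # --- draw the protein template -------------------------------------------
  prepro_end <- spec$signal_len + spec$pro_len
  prefix_res <- character(prefix_len)
  prev <- NA_character_
  for (i in seq_len(prepro_end)) {
    key <- as.character(i)
    if (length(fixed) > 0L && key %in% names(fixed)) {
      prefix_res[i] <- fixed[[key]]
    } else {
      prefix_res[i] <- .draw_residue(prev, pre_motif = (i == prepro_end),
                                     allowed = res_allowed(tmpl_constr_prefix[[key]]))
    }
    prev <- prefix_res[i]
  }
  i0 <- prepro_end
  prefix_res[i0 + seq_along(cm)] <- cm
  i0 <- i0 + length(cm)
  hld_start <- i0 + 1L
  prefix_res[hld_start] <- spec$hld_first_residue
  prev <- spec$hld_first_residue
  for (i in if (spec$hld_len > 1L) seq(2L, spec$hld_len) else integer()) {
    pos <- i0 + i
    key <- as.character(pos)
    if (length(fixed) > 0L && key %in% names(fixed)) {
      prefix_res[pos] <- fixed[[key]]
    } else {
      prefix_res[pos] <- .draw_residue(prev, pre_motif = (i == spec$hld_len),
                                       allowed = res_allowed(tmpl_constr_prefix[[key]]))
    }
    prev <- prefix_res[pos]
  }
  i0 <- i0 + spec$hld_len
  prefix_res[i0 + seq_along(cm)] <- cm

  unit_res <- character(unit_len)
  unit_res[seq_along(sp)] <- sp
  u0 <- length(sp)
  unit_res[u0 + 1L] <- spec$hd_first_residue
  prev <- spec$hd_first_residue
  if (spec$hd_len > 1L) {
    for (i in seq(2L, spec$hd_len)) {
      pos <- u0 + i
      unit_res[pos] <- .draw_residue(prev, pre_motif = (i == spec$hd_len),
                                     allowed = res_allowed(tmpl_constr_unit[[as.character(pos)]]))
      prev <- unit_res[pos]
    }
  }
  unit_res[u0 + spec$hd_len + seq_along(cm)] <- cm

  protein <- c(prefix_res, rep(unit_res, spec$n_repeats))
  stopifnot(length(protein) == p_len)

  # --- back-translate -------------------------------------------------------
  codon_for <- function(res_vec, constr_map, offset0) {
    vapply(seq_along(res_vec), function(i) {
      .sample_codon(res_vec[i], avoid_g_at = constr_map[[as.character(i + offset0)]])
    }, character(1))
  }
  prefix_cod <- codon_for(prefix_res, tmpl_constr_prefix, 0L)
  unit_cod <- if (spec$n_repeats > 0L) {
    vapply(seq_along(unit_res), function(i) {
      .sample_codon(unit_res[i], avoid_g_at = tmpl_constr_unit[[as.character(i)]])
    }, character(1))
  } else character()
  cds <- paste(c(prefix_cod, rep(unit_cod, spec$n_repeats)), collapse = "")
  stop_codon <- .sample_one(.STOP_CODONS)
  utr5 <- .rand_nt(spec$utr5_len)
  utr3 <- .rand_nt(spec$utr3_len)
  cdna <- paste0(utr5, cds, stop_codon, utr3)

  intron_seqs <- vapply(intron_lengths_sorted(spec), function(L) {
    paste0("GT", .rand_nt(L - 4L), "AG")
  }, character(1))

  genomic <- .insert_introns(cdna, spec$utr5_len + offs, intron_seqs)
  model <- .truth_gene_model(nchar(cdna), spec$utr5_len + offs,
                             nchar(intron_seqs), spec$utr5_len + 1L,
                             3L * p_len)
  ann <- .precursor_layout(spec)

  bundle <- structure(list(
    genomic_seq = genomic, cdna_seq = cdna, protein_seq = paste(protein, collapse = ""),
    truth_gene_model = model, truth_annotation = ann, spec = spec,
    seed = as.integer(seed)
  ), class = "locus_bundle")
  .check_bundle(bundle)
  bundle
}

# Role-labelled residue intervals implied by a spec.
.precursor_layout <- function(spec) {
  cm <- nchar(spec$cleavage_motif)
  sp <- nchar(spec$spacer_motif)
  roles <- c("signal", "pro", "cleavage", "HLD", "cleavage",
             rep(c("spacer", "HD", "cleavage"), spec$n_repeats))
  lens <- c(spec$signal_len, spec$pro_len, cm, spec$hld_len, cm,
            rep(c(sp, spec$hd_len, cm), spec$n_repeats))
  ends <- cumsum(lens)
  precursor_annotation(data.frame(
    role = roles, start = ends - lens + 1L, end = ends,
    stringsAsFactors = FALSE
  ))
}

# Insert intron sequences after the given cDNA offsets (sorted).
.insert_introns <- function(cdna, cdna_offsets, intron_seqs) {
  if (length(cdna_offsets) == 0L) return(cdna)
  pieces <- character(2L * length(cdna_offsets) + 1L)
  prev <- 0L
  for (i in seq_along(cdna_offsets)) {
    pieces[2L * i - 1L] <- substr(cdna, prev + 1L, cdna_offsets[i])
    pieces[2L * i] <- intron_seqs[i]
    prev <- cdna_offsets[i]
  }
  pieces[length(pieces)] <- substr(cdna, prev + 1L, nchar(cdna))
  paste(pieces, collapse = "")
}

# Build the truth gene model from splice offsets on the cDNA.
.truth_gene_model <- function(cdna_len, cdna_offsets, intron_lens,
                              cds_start_on_cdna, cds_len_nt) {
  bounds <- c(0L, cdna_offsets, cdna_len)           # cDNA exon boundaries
  exon_lens <- diff(bounds)
  n_ex <- length(exon_lens)
  exons <- matrix(0L, nrow = n_ex, ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  g <- 0L
  for (i in seq_len(n_ex)) {
    exons[i, 1L] <- g + 1L
    exons[i, 2L] <- g + exon_lens[i]
    g <- g + exon_lens[i] + if (i < n_ex) intron_lens[i] else 0L
  }
  gene_model(exons, genomic_len = g,
             cds_start_on_cdna = cds_start_on_cdna, cds_len_nt = cds_len_nt)
}

.check_bundle <- function(bundle) {
  m <- bundle$truth_gene_model
  spliced <- spliced_cdna(bundle$genomic_seq, m)
  stopifnot(identical(spliced, bundle$cdna_seq))
  cds <- substr(bundle$cdna_seq, m$cds_start_on_cdna,
                m$cds_start_on_cdna + m$cds_len_nt - 1L)
  stopifnot(identical(translate_cds(cds), bundle$protein_seq))
  invisible(bundle)
}

#' @export
print.locus_bundle <- function(x, ...) {
  cat("Synthetic locus bundle (seed ", x$seed, ")\n", sep = "")
  cat("  genomic ", nchar(x$genomic_seq), " nt; cDNA ", nchar(x$cdna_seq),
      " nt; protein ", nchar(x$protein_seq), " aa; ",
      nrow(x$truth_gene_model$introns), " intron(s)\n", sep = "")
  invisible(x)
}

#' Generate a synthetic defensin-type locus
#'
#' Builds a simple prepropeptide gene from printed exon/intron sizes. Exon
#' lengths are interpreted as coding sequence without the stop codon (their
#' sum must be divisible by 3); the stop codon and UTRs are appended around
#' the CDS, so the first and last transcript exons extend into the UTRs.
#'
#' @param exon_lengths Coding exon lengths in nt (length = introns + 1).
#' @param intron_lengths Intron lengths in nt.
#' @param segment_lens Named or positional residue counts
#'   `(signal, pro, mature, extra_cterm)`; must sum to `sum(exon_lengths)/3`.
#' @param seed Integer seed.
#' @param utr5_len,utr3_len UTR lengths in nt.
#' @param fixed_residues Optional named residue pins (1-based positions).
#' @return A `locus_bundle` (its `truth_annotation` uses roles signal, pro,
#'   mature, trailing).
#' @export
generate_defensin_locus <- function(exon_lengths, intron_lengths, segment_lens,
                                    seed, utr5_len = 50L, utr3_len = 100L,
                                    fixed_residues = character()) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(exon_lengths) != length(intron_lengths) + 1L) {
    stop("need exactly one more exon than introns")
  }
  cds_nt <- sum(exon_lengths)
  if (cds_nt %% 3L != 0L) {
    stop("total coding length ", cds_nt, " nt is not divisible by 3")
  }
  p_len <- cds_nt %/% 3L
  segment_lens <- as.integer(segment_lens)
  if (length(segment_lens) != 4L || sum(segment_lens) != p_len) {
    stop("segment_lens must be 4 residue counts summing to ", p_len)
  }
  if (any(intron_lengths < 4L)) stop("introns must be at least 4 nt")
  set.seed(as.integer(seed))

  offs <- cumsum(exon_lengths)[seq_along(intron_lengths)]
  constr <- list()
  for (o in offs) {
    ci <- o %/% 3L + 1L
    b <- o %% 3L + 1L
    key <- as.character(ci)
    constr[[key]] <- union(constr[[key]], b)
  }
  res <- character(p_len)
  prev <- NA_character_
  for (i in seq_len(p_len)) {
    key <- as.character(i)
    if (length(fixed_residues) > 0L && key %in% names(fixed_residues)) {
      res[i] <- fixed_residues[[key]]
    } else {
      allowed <- .AA20
      if (!is.null(constr[[key]])) {
        for (b in constr[[key]]) allowed <- intersect(allowed, .aa_ok_for_base(b))
        if (length(allowed) == 0L) allowed <- .AA20
      }
      res[i] <- .sample_one(allowed)
    }
    prev <- res[i]
  }
  cods <- vapply(seq_len(p_len), function(i) {
    .sample_codon(res[i], avoid_g_at = constr[[as.character(i)]])
  }, character(1))
  cds <- paste(cods, collapse = "")
  cdna <- paste0(.rand_nt(utr5_len), cds, .sample_one(.STOP_CODONS), .rand_nt(utr3_len))
  intron_seqs <- vapply(intron_lengths, function(L) {
    paste0("GT", .rand_nt(L - 4L), "AG")
  }, character(1))
  genomic <- .insert_introns(cdna, utr5_len + offs, intron_seqs)
  model <- .truth_gene_model(nchar(cdna), utr5_len + offs, intron_lengths,
                             utr5_len + 1L, cds_nt)

  lens <- segment_lens[segment_lens > 0L]
  roles <- c("signal", "pro", "mature", "trailing")[segment_lens > 0L]
  ends <- cumsum(lens)
  ann <- precursor_annotation(data.frame(
    role = roles, start = ends - lens + 1L, end = ends, stringsAsFactors = FALSE
  ), validate_grammar = FALSE)

  bundle <- structure(list(
    genomic_seq = genomic, cdna_seq = cdna, protein_seq = paste(res, collapse = ""),
    truth_gene_model = model, truth_annotation = ann, spec = NULL,
    seed = as.integer(seed)
  ), class = "locus_bundle")
  .check_bundle(bundle)
  bundle
}

#' Bundled defensin gene fixtures
#'
#' `defensin1_fixture()`: three coding exons of 64, 229 and 13 nt separated by
#' 399- and 360-nt introns; 102-aa prepropeptide (17-aa signal, 40-aa pro,
#' 44-aa mature defensin, one trailing residue) with the phase-1 intron inside
#' codon 22 (Glu) and the phase-2 intron inside codon 98 (Ala); 535-nt mRNA.
#' `defensin2_fixture()`: two coding exons of 97 and 194 nt around a 1043-nt
#' phase-1 intron inside codon 33 (Thr); 97-aa prepropeptide (18/36/43);
#' 1238-nt mRNA.
#'
#' @param seed Integer seed.
#' @return A `locus_bundle`.
#' @export
defensin1_fixture <- function(seed = 1L) {
  generate_defensin_locus(
    exon_lengths = c(64L, 229L, 13L), intron_lengths = c(399L, 360L),
    segment_lens = c(signal = 17L, pro = 40L, mature = 44L, extra_cterm = 1L),
    seed = seed, utr5_len = 50L, utr3_len = 176L,
    fixed_residues = c("22" = "E", "98" = "A")
  )
}

#' @rdname defensin1_fixture
#' @export
defensin2_fixture <- function(seed = 1L) {
  generate_defensin_locus(
    exon_lengths = c(97L, 194L), intron_lengths = 1043L,
    segment_lens = c(signal = 18L, pro = 36L, mature = 43L, extra_cterm = 0L),
    seed = seed, utr5_len = 60L, utr3_len = 884L,
    fixed_residues = c("33" = "T")
  )
}

#' Diverge the repeated domains of a bundle
#'
#' Each HD is mutated independently at the nucleotide level, at the given
#' per-site substitution rate, within its own coding positions only: spacer
#' and cleavage-motif codons are untouched, substitutions creating stop
#' codons are redrawn, and the truth intervals are unchanged. Genomic
#' sequence, cDNA and protein are all updated consistently.
#'
#' @param bundle A precursor `locus_bundle`.
#' @param subst_rate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The diverged `locus_bundle`.
#' @export
diverge_domains <- function(bundle, subst_rate, seed) {
  stopifnot(inherits(bundle, "locus_bundle"), subst_rate >= 0, subst_rate < 1)
  if (subst_rate == 0) return(bundle)
  set.seed(as.integer(seed))
  m <- bundle$truth_gene_model
  cdna <- strsplit(bundle$cdna_seq, "")[[1L]]
  ann <- bundle$truth_annotation
  hds <- ann[ann$role == "HD", , drop = FALSE]
  for (r in seq_len(nrow(hds))) {
    nt0 <- m$cds_start_on_cdna + 3L * (hds$start[r] - 1L)
    nt1 <- m$cds_start_on_cdna + 3L * hds$end[r] - 1L
    hit <- which(stats::runif(nt1 - nt0 + 1L) < subst_rate)
    for (h in hit) {
      pos <- nt0 + h - 1L
      old <- cdna[pos]
      repeat {
        new <- .sample_one(setdiff(.BASES, old))
        cdna[pos] <- new
        cod0 <- pos - (pos - m$cds_start_on_cdna) %% 3L
        codon <- paste(cdna[cod0:(cod0 + 2L)], collapse = "")
        if (!codon %in% .STOP_CODONS) break
        cdna[pos] <- old
      }
    }
  }
  new_cdna <- paste(cdna, collapse = "")
  # Re-thread the mutated exonic sequence through the genomic coordinates.
  genomic <- strsplit(bundle$genomic_seq, "")[[1L]]
  cpos <- 1L
  for (e in seq_len(nrow(m$exons))) {
    len <- m$exons[e, "end"] - m$exons[e, "start"] + 1L
    genomic[m$exons[e, "start"]:m$exons[e, "end"]] <- cdna[cpos:(cpos + len - 1L)]
    cpos <- cpos + len
  }
  out <- bundle
  out$cdna_seq <- new_cdna
  out$genomic_seq <- paste(genomic, collapse = "")
  cds <- substr(new_cdna, m$cds_start_on_cdna, m$cds_start_on_cdna + m$cds_len_nt - 1L)
  out$protein_seq <- translate_cds(cds)
  out
}
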
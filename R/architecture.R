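# Declarative description of a multipeptide AMP precursor locus: segment
# lengths, processing motifs, tandem-repeat count and intron placements.
# The generator consumes it; the precursor parser uses it as its template.

.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
.STOP_CODONS <- .CODON_TABLE[["*"]]
.DIBASIC_MOTIFS <- c("RR", "KR", "RK")

#' Describe a multipeptide precursor architecture
#'
#' The protein layout implied by a spec is
#' `signal + pro + cleavage + HLD + cleavage + n_repeats x (spacer + HD + cleavage)`,
#' i.e. the hymenoptaecin-like domain (HLD) and each hymenoptaecin domain (HD)
#' end at a dibasic proprotein-convertase site, and each HD is preceded by a
#' spacer removed dipeptide-wise during maturation. The tandem-repeat unit on
#' the cDNA is `3 * (nchar(spacer_motif) + hd_len + nchar(cleavage_motif))` nt.
#'
#' Introns are given as `list(after_codon = k, length = L)` for a phase-0
#' intron after codon `k`, or `list(within_codon = k, phase = 1|2, length = L)`
#' for an intron inside codon `k`; placements must fall strictly inside the
#' coding region and not coincide.
#'
#' @param signal_len,pro_len,hld_len,hd_len Segment lengths in residues.
#' @param n_repeats Number of spacer+HD+cleavage repeat units (>= 0).
#' @param spacer_motif Spacer peptide preceding each HD (default `"EAEP"`).
#' @param cleavage_motif Dibasic site, one of `"RR"`, `"KR"`, `"RK"`.
#' @param hld_first_residue,hd_first_residue Fixed first residues of the HLD
#'   (default `"G"`) and of each HD (default `"Q"`).
#' @param introns List of intron placements (see Details).
#' @param utr5_len,utr3_len Untranslated-region lengths in nt.
#' @param fixed_residues Optional named character vector pinning residues at
#'   1-based protein positions, e.g. `c("39" = "H")`.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(signal_len, pro_len, hld_len, hd_len, n_repeats,
                              spacer_motif = "EAEP", cleavage_motif = "RR",
                              hld_first_residue = "G", hd_first_residue = "Q",
                              introns = list(), utr5_len = 50L, utr3_len = 100L,
                              fixed_residues = character()) {
  spec <- structure(list(
    signal_len = as.integer(signal_len), pro_len = as.integer(pro_len),
    hld_len = as.integer(hld_len), hd_len = as.integer(hd_len),
    n_repeats = as.integer(n_repeats),
    spacer_motif = spacer_motif, cleavage_motif = cleavage_motif,
    hld_first_residue = hld_first_residue, hd_first_residue = hd_first_residue,
    introns = introns,
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    fixed_residues = fixed_residues
  ), class = "architecture_spec")
  validate_architecture_spec(spec)
  spec
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("Precursor architecture: signal ", x$signal_len, " aa | pro ",
      x$pro_len, " aa | ", x$cleavage_motif, " | HLD ", x$hld_len,
      " aa | ", x$cleavage_motif, " | ", x$n_repeats, " x (",
      x$spacer_motif, " + HD ", x$hd_len, " aa + ", x$cleavage_motif, ")\n",
      sep = "")
  cat("Protein ", protein_length(x), " aa; repeat unit ", repeat_unit_nt(x),
      " nt; ", length(x$introns), " intron(s)\n", sep = "")
  invisible(x)
}

validate_architecture_spec <- function(spec) {
  with(spec, {
    if (any(c(signal_len, pro_len, hld_len, hd_len) <= 0L)) {
      stop("segment lengths must be positive")
    }
    if (n_repeats < 0L) stop("n_repeats must be >= 0")
    if (!cleavage_motif %in% .DIBASIC_MOTIFS) {
      stop("cleavage_motif must be one of ", paste(.DIBASIC_MOTIFS, collapse = ", "))
    }
    if (!grepl("^[A-Z]+$", spacer_motif)) stop("invalid spacer motif")
    if (utr5_len < 0L || utr3_len < 0L) stop("UTR lengths must be >= 0")
  })
  offs <- intron_cds_offsets(spec)
  cds_nt <- 3L * protein_length(spec)
  if (length(offs) > 0L) {
    if (any(offs < 1L) || any(offs > cds_nt - 1L)) {
      stop("intron placement falls outside the coding region (CDS ", cds_nt, " nt)")
    }
    if (anyDuplicated(offs)) stop("overlapping intron placements")
    lens <- vapply(spec$introns, function(i) as.integer(i$length), integer(1))
    if (any(lens < 4L)) stop("introns must be at least 4 nt (GT..AG)")
  }
  invisible(spec)
}

#' Protein length implied by an architecture spec
#' @param spec An `architecture_spec`.
#' @return Residue count of the full precursor.
#' @export
protein_length <- function(spec) {
  cm <- nchar(spec$cleavage_motif)
  sp <- nchar(spec$spacer_motif)
  spec$signal_len + spec$pro_len + cm + spec$hld_len + cm +
    spec$n_repeats * (sp + spec$hd_len + cm)
}

#' Tandem-repeat unit length on the cDNA in nt
#' @param spec An `architecture_spec`.
#' @export
repeat_unit_nt <- function(spec) {
  3L * (nchar(spec$spacer_motif) + spec$hd_len + nchar(spec$cleavage_motif))
}

# Coding-strand nt offsets (nt emitted before each intron), sorted.
intron_cds_offsets <- function(spec) {
  if (length(spec$introns) == 0L) return(integer())
  offs <- vapply(spec$introns, function(i) {
    if (!is.null(i$after_codon)) {
      3L * as.integer(i$after_codon)
    } else if (!is.null(i$within_codon)) {
      if (!i$phase %in% c(1L, 2L)) stop("within-codon intron phase must be 1 or 2")
      3L * (as.integer(i$within_codon) - 1L) + as.integer(i$phase)
    } else stop("intron needs 'after_codon' or 'within_codon' + 'phase'")
  }, integer(1))
  sort(offs)
}

# Intron lengths in the order of their sorted offsets.
intron_lengths_sorted <- function(spec) {
  if (length(spec$introns) == 0L) return(integer())
  offs <- vapply(spec$introns, function(i) {
    if (!is.null(i$after_codon)) 3L * as.integer(i$after_codon)
    else 3L * (as.integer(i$within_codon) - 1L) + as.integer(i$phase)
  }, integer(1))
  lens <- vapply(spec$introns, function(i) as.integer(i$length), integer(1))
  lens[order(offs)]
}

#' The default hymenoptaecin precursor architecture
#'
#' Nineteen-residue signal peptide, 26-residue propeptide, a 108-aa G-initial
#' hymenoptaecin-like domain and six 97-aa Q-initial hymenoptaecin domains,
#' each repeat unit `EAEP + HD + RR` (309 nt of coding sequence), with one
#' 820-nt phase-0 intron after codon 39 (a histidine). The UTR lengths place
#' the cDNA at 2536 nt and the gene at 3356 nt.
#'
#' @return An `architecture_spec`.
#' @export
hymenoptaecin_spec <- function() {
  architecture_spec(
    signal_len = 19L, pro_len = 26L, hld_len = 108L, hd_len = 97L,
    n_repeats = 6L, spacer_motif = "EAEP", cleavage_motif = "RR",
    hld_first_residue = "G", hd_first_residue = "Q",
    introns = list(list(after_codon = 39L, length = 820L)),
    utr5_len = 40L, utr3_len = 168L,
    fixed_residues = c("39" = "H")
  )
}
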
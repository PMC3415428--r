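# In-silico three-step proteolytic maturation of a multipeptide precursor:
# a KEX2-like endoprotease cuts C-terminal to dibasic sites, a KEX1-like
# carboxypeptidase removes the exposed basic residues, and a dipeptidyl
# aminopeptidase removes N-terminal E/D-A/P dipeptides from the
# spacer-bearing fragments.

#' Cut a protein C-terminal to its dibasic cleavage sites
#'
#' Fragments are split immediately after each site's last residue; their
#' concatenation restores the protein. Empty fragments (e.g. a trailing
#' fragment after a C-terminal site) are dropped with a message.
#'
#' @param protein Amino-acid string.
#' @param sites Data frame from [scan_cleavage_sites()].
#' @return Data frame with columns `sequence`, `start`, `end` (intervals on
#'   the input protein).
#' @export
endoprotease_cut <- function(protein, sites) {
  n <- nchar(protein)
  cuts <- sort(unique(sites$position))
  stopifnot(all(cuts >= 1L), all(cuts <= n))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  empty <- starts > ends
  if (any(empty)) {
    message("endoprotease_cut: dropped ", sum(empty), " empty fragment(s)")
    starts <- starts[!empty]
    ends <- ends[!empty]
  }
  data.frame(sequence = substring(protein, starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Carboxypeptidase trim of C-terminal basic residues
#'
#' Strips C-terminal arginine/lysine residues, at most `max_trim` (default 2,
#' matching removal of both residues of a dibasic site; use `Inf` for
#' unlimited trailing-basic trimming).
#'
#' @param fragment Amino-acid string.
#' @param max_trim Maximum residues removed.
#' @return The trimmed fragment.
#' @export
carboxypeptidase_trim <- function(fragment, max_trim = 2L) {
  n <- nchar(fragment)
  trimmed <- 0L
  while (n > 0L && trimmed < max_trim &&
         substr(fragment, n, n) %in% c("R", "K")) {
    n <- n - 1L
    trimmed <- trimmed + 1L
  }
  substr(fragment, 1L, n)
}

#' Dipeptidyl aminopeptidase trim of N-terminal spacer dipeptides
#'
#' Iteratively removes N-terminal dipeptides from the allowed set (default
#' `EA`, `EP`, `DA`, `DP`, i.e. E/D followed by A/P) until the first two
#' residues no longer match. The set is configurable; spacer variants such
#' as `EANP` are only removable when the user widens it.
#'
#' @param fragment Amino-acid string.
#' @param dipeptides Character vector of removable dipeptides.
#' @return The trimmed fragment.
#' @export
dipeptidyl_trim <- function(fragment, dipeptides = c("EA", "EP", "DA", "DP")) {
  while (nchar(fragment) >= 2L && substr(fragment, 1L, 2L) %in% dipeptides) {
    fragment <- substr(fragment, 3L, nchar(fragment))
  }
  fragment
}

#' Release mature peptides from a precursor protein
#'
#' Applies the three-step maturation after removing the signal peptide: the
#' endoprotease splits the proprotein at its dibasic sites, the fragment
#' C-terminal basics are trimmed, spacer dipeptides are removed from the
#' N-termini, and the propeptide-derived fragment is discarded. The first
#' returned peptide is HLD-derived, followed by the HD-derived peptides.
#'
#' @param protein Precursor amino-acid string.
#' @param spec An [architecture_spec()] the protein parses under.
#' @param dipeptides Allowed spacer dipeptides (see [dipeptidyl_trim()]).
#' @param max_trim Carboxypeptidase limit (see [carboxypeptidase_trim()]).
#' @return Data frame of class `mature_peptides` with columns `sequence`,
#'   `start`, `end` (1-based interval on the precursor), `length`, `n_term`,
#'   `pyroglutamate_capable` (TRUE iff the N-terminus is Q); the residue
#'   accounting of the run is attached as attribute `accounting`.
#' @export
mature_peptides <- function(protein, spec, dipeptides = c("EA", "EP", "DA", "DP"),
                            max_trim = 2L) {
  ann <- segment_precursor(protein, spec)   # parse failure propagates
  sig_len <- spec$signal_len
  body <- substr(protein, sig_len + 1L, nchar(protein))
  sites <- scan_cleavage_sites(body, motifs = .DIBASIC_MOTIFS)
  frags <- endoprotease_cut(body, sites)
  if (nrow(frags) < 1L) stop("maturation produced no fragments")
  # The first fragment is propeptide-derived (pro + its dibasic site).
  pro_frag <- frags$sequence[1L]
  frags <- frags[-1L, , drop = FALSE]
  seqs <- character(nrow(frags))
  starts <- integer(nrow(frags))
  ends <- integer(nrow(frags))
  c_trim <- 0L
  n_trim <- 0L
  for (i in seq_len(nrow(frags))) {
    s <- frags$sequence[i]
    s1 <- carboxypeptidase_trim(s, max_trim = max_trim)
    c_trim <- c_trim + nchar(s) - nchar(s1)
    s2 <- dipeptidyl_trim(s1, dipeptides = dipeptides)
    n_trim <- n_trim + nchar(s1) - nchar(s2)
    seqs[i] <- s2
    starts[i] <- sig_len + frags$start[i] + (nchar(s1) - nchar(s2))
    ends[i] <- sig_len + frags$end[i] - (nchar(s) - nchar(s1))
  }
  out <- data.frame(sequence = seqs, start = starts, end = ends,
                    length = nchar(seqs), n_term = substr(seqs, 1L, 1L),
                    stringsAsFactors = FALSE)
  out$pyroglutamate_capable <- out$n_term == "Q"
  accounting <- c(
    total_in = nchar(protein), signal = sig_len, pro_fragment = nchar(pro_frag),
    c_terminal_trim = c_trim, n_terminal_trim = n_trim,
    peptides_total = sum(out$length)
  )
  structure(out, class = c("mature_peptides", "data.frame"),
            accounting = accounting)
}

#' Residue accounting of a maturation run
#' @param peptides A `mature_peptides` object.
#' @return Named integer vector; `total_in` equals the sum of the other
#'   components.
#' @export
maturation_accounting <- function(peptides) attr(peptides, "accounting")
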
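# Rule-based segmentation of a precursor protein: dibasic proprotein
# convertase site scanning and grammar-driven parsing against an
# architecture template.

#' Construct a precursor annotation
#'
#' @param segments Data frame with columns `role`, `start`, `end` (1-based
#'   inclusive residue intervals).
#' @param validate_grammar Also enforce the precursor grammar (every HD
#'   preceded by a spacer and followed by a cleavage site; HLD followed by a
#'   cleavage site), in addition to gap-free tiling.
#' @return Object of class `precursor_annotation`; `n_hd` is stored as an
#'   attribute and via `n_hd()`.
#' @export
precursor_annotation <- function(segments, validate_grammar = TRUE) {
  stopifnot(is.data.frame(segments),
            all(c("role", "start", "end") %in% names(segments)))
  if (nrow(segments) > 0L) {
    if (segments$start[1L] != 1L ||
        any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)) {
      stop("annotation segments must tile the protein without gaps or overlaps")
    }
    if (any(segments$end < segments$start)) stop("empty annotation segment")
  }
  if (validate_grammar) {
    r <- segments$role
    hd <- which(r == "HD")
    if (length(hd) > 0L) {
      if (any(hd == 1L) || any(r[hd - 1L] != "spacer") ||
          any(hd == length(r)) || any(r[hd + 1L] != "cleavage")) {
        stop("every HD must be preceded by a spacer and followed by a cleavage site")
      }
    }
    hld <- which(r == "HLD")
    if (length(hld) > 0L && (any(hld == length(r)) || any(r[hld + 1L] != "cleavage"))) {
      stop("the HLD must be followed by a cleavage site")
    }
  }
  structure(segments, class = c("precursor_annotation", "data.frame"),
            n_hd = sum(segments$role == "HD"))
}

#' Number of hymenoptaecin domains in an annotation
#' @param annotation A `precursor_annotation`.
#' @export
n_hd <- function(annotation) attr(annotation, "n_hd")

#' Scan a protein for proprotein-convertase cleavage sites
#'
#' Finds all non-overlapping dibasic motifs left-to-right greedily: each
#' residue belongs to at most one site, and in a run such as `RRR` the
#' leftmost pair wins. The reported `position` is the last residue of the
#' motif; the scissile bond is C-terminal to it. `RXXR` recognition (X any
#' residue) is off by default.
#'
#' @param protein Amino-acid string.
#' @param motifs Dibasic motifs to recognise.
#' @param include_rxxr Also recognise `RXXR` furin-type sites.
#' @return Data frame with columns `start`, `position`, `motif`.
#' @export
scan_cleavage_sites <- function(protein, motifs = c("RR", "KR", "RK"),
                                include_rxxr = FALSE) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  starts <- integer()
  ends <- integer()
  found <- character()
  i <- 1L
  while (i <= n - 1L) {
    pair <- paste0(res[i], res[i + 1L])
    if (pair %in% motifs) {
      starts <- c(starts, i)
      ends <- c(ends, i + 1L)
      found <- c(found, pair)
      i <- i + 2L
    } else if (include_rxxr && i <= n - 3L &&
               res[i] == "R" && res[i + 3L] == "R") {
      starts <- c(starts, i)
      ends <- c(ends, i + 3L)
      found <- c(found, paste(res[i:(i + 3L)], collapse = ""))
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, position = ends, motif = found,
             stringsAsFactors = FALSE)
}

#' Segment a precursor protein against an architecture template
#'
#' Deterministic parse: consume `signal_len`, then `pro_len` residues, then a
#' cleavage motif, then the HLD up to the next cleavage motif, then repeat
#' (spacer, HD up to the next cleavage motif) until the protein is exhausted.
#' A missing motif where the grammar requires one is a parse error naming the
#' position and the expected motif. Deviations of HD length or first residue
#' from the template are reported as warnings, not errors.
#'
#' @param protein Amino-acid string.
#' @param spec An [architecture_spec()].
#' @return A `precursor_annotation`.
#' @export
segment_precursor <- function(protein, spec) {
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  dibasic <- .DIBASIC_MOTIFS
  sp <- spec$spacer_motif
  sp_len <- nchar(sp)

  next_dibasic <- function(from) {
    i <- from
    while (i <= n - 1L) {
      if (paste0(res[i], res[i + 1L]) %in% dibasic) return(i)
      i <- i + 1L
    }
    NA_integer_
  }

  roles <- character(); starts <- integer(); ends <- integer()
  push <- function(role, s, e) {
    roles <<- c(roles, role); starts <<- c(starts, s); ends <<- c(ends, e)
  }
  pos <- 1L
  if (n < spec$signal_len + spec$pro_len + 2L) {
    stop("precursor parse error: protein too short for signal+pro+cleavage")
  }
  push("signal", pos, pos + spec$signal_len - 1L)
  pos <- pos + spec$signal_len
  push("pro", pos, pos + spec$pro_len - 1L)
  pos <- pos + spec$pro_len
  if (!paste0(res[pos], res[pos + 1L]) %in% dibasic) {
    stop("precursor parse error at position ", pos,
         ": expected dibasic cleavage motif after the propeptide")
  }
  push("cleavage", pos, pos + 1L)
  pos <- pos + 2L
  j <- next_dibasic(pos)
  if (is.na(j)) {
    stop("precursor parse error at position ", pos,
         ": expected a cleavage motif terminating the HLD")
  }
  push("HLD", pos, j - 1L)
  hld_seq <- res[pos:(j - 1L)]
  if (hld_seq[1L] != spec$hld_first_residue) {
    warning("HLD starts with ", hld_seq[1L], ", template expects ",
            spec$hld_first_residue)
  }
  if (length(hld_seq) != spec$hld_len) {
    warning("HLD length ", length(hld_seq), " deviates from template ", spec$hld_len)
  }
  push("cleavage", j, j + 1L)
  pos <- j + 2L

  hd_lens <- integer()
  while (pos <= n) {
    if (pos + sp_len - 1L > n ||
        paste(res[pos:(pos + sp_len - 1L)], collapse = "") != sp) {
      stop("precursor parse error at position ", pos,
           ": expected spacer motif '", sp, "'")
    }
    push("spacer", pos, pos + sp_len - 1L)
    pos <- pos + sp_len
    j <- next_dibasic(pos)
    if (is.na(j)) {
      stop("precursor parse error at position ", pos,
           ": expected a cleavage motif terminating the HD")
    }
    push("HD", pos, j - 1L)
    hd_lens <- c(hd_lens, j - pos)
    if (res[pos] != spec$hd_first_residue) {
      warning("HD at position ", pos, " starts with ", res[pos],
              ", template expects ", spec$hd_first_residue)
    }
    push("cleavage", j, j + 1L)
    pos <- j + 2L
  }
  if (length(hd_lens) > 0L && length(unique(hd_lens)) > 1L) {
    warning("non-uniform HD lengths: ", paste(hd_lens, collapse = ", "))
  }
  if (length(hd_lens) > 0L && any(hd_lens != spec$hd_len)) {
    bad <- unique(hd_lens[hd_lens != spec$hd_len])
    warning("HD length(s) ", paste(bad, collapse = ", "),
            " deviate from template ", spec$hd_len)
  }
  precursor_annotation(data.frame(role = roles, start = starts, end = ends,
                                  stringsAsFactors = FALSE))
}

#' Map annotated protein segments to cDNA intervals
#'
#' Residue `i` corresponds to cDNA nucleotides
#' `[cds_start + 3(i-1), cds_start + 3i - 1]`.
#'
#' @param annotation A `precursor_annotation`.
#' @param cds_start_on_cdna 1-based CDS start on the cDNA.
#' @param cdna_len Optional cDNA length for range checking.
#' @return The annotation with added `nt_start`, `nt_end` columns.
#' @export
map_segments_to_cdna <- function(annotation, cds_start_on_cdna, cdna_len = NULL) {
  stopifnot(inherits(annotation, "precursor_annotation"))
  nt_start <- cds_start_on_cdna + 3L * (annotation$start - 1L)
  nt_end <- cds_start_on_cdna + 3L * annotation$end - 1L
  if (!is.null(cdna_len) && any(nt_end > cdna_len)) {
    stop("segment maps outside the cDNA (length ", cdna_len, ")")
  }
  out <- as.data.frame(annotation)
  out$nt_start <- nt_start
  out$nt_end <- nt_end
  structure(out, class = c("precursor_annotation", "data.frame"),
            n_hd = attr(annotation, "n_hd"))
}
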
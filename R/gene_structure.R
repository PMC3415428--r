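# Gene models and exact splice mapping of a cDNA onto its genomic sequence.
# All coordinates are 1-based inclusive on the plus strand.

#' Construct a gene model
#'
#' @param exons Two-column integer matrix (`start`, `end`) of transcript exon
#'   intervals on the genomic sequence, ordered and non-overlapping.
#' @param genomic_len Genomic sequence length (defaults to the last exon end).
#' @param cds_start_on_cdna 1-based start of the CDS on the cDNA (NA if
#'   unknown).
#' @param cds_len_nt CDS length in nt, excluding the stop codon (NA if
#'   unknown).
#' @return An object of class `gene_model` with derived `introns`.
#' @export
gene_model <- function(exons, genomic_len = NULL, cds_start_on_cdna = NA_integer_,
                       cds_len_nt = NA_integer_) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(exons) >= 1L, all(exons[, "end"] >= exons[, "start"]))
  if (nrow(exons) > 1L) {
    stopifnot(all(exons[-1L, "start"] > exons[-nrow(exons), "end"]))
  }
  introns <- if (nrow(exons) > 1L) {
    cbind(start = exons[-nrow(exons), "end"] + 1L,
          end = exons[-1L, "start"] - 1L)
  } else {
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(
    exons = exons, introns = introns,
    genomic_len = if (is.null(genomic_len)) exons[nrow(exons), "end"] else as.integer(genomic_len),
    cds_start_on_cdna = as.integer(cds_start_on_cdna),
    cds_len_nt = as.integer(cds_len_nt),
    strand = "+"
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model: ", nrow(x$exons), " exon(s), ", nrow(x$introns),
      " intron(s)", sep = "")
  if (nrow(x$introns) > 0L) {
    cat(" (", paste(x$introns[, "end"] - x$introns[, "start"] + 1L,
                    collapse = ", "), " nt)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Intron lengths of a gene model
#' @param model A `gene_model`.
#' @export
intron_lengths <- function(model) {
  if (nrow(model$introns) == 0L) return(integer())
  unname(model$introns[, "end"] - model$introns[, "start"] + 1L)
}

#' Splice a genomic sequence according to a gene model
#' @param genomic Genomic nucleotide string.
#' @param model A `gene_model`.
#' @return The concatenated exon sequence (cDNA).
#' @export
spliced_cdna <- function(genomic, model) {
  paste(substring(genomic, model$exons[, "start"], model$exons[, "end"]),
        collapse = "")
}

#' Map a cDNA onto its genomic sequence by exact splice mapping
#'
#' Greedy left-to-right extension: genomic and cDNA are matched until the
#' first mismatch, then the downstream genomic sequence is searched for the
#' longest exact resumption anchored by `min_anchor` nt (or by the whole
#' remaining cDNA when shorter), preferring the smallest intron. Equally
#' small complete models raise an "ambiguous splice" error. Each inferred
#' intron is canonicalised within its slide interval to the leftmost GT..AG
#' placement, as spliced aligners do; mismatches and indels are out of scope.
#'
#' @param genomic,cdna Nucleotide strings.
#' @param min_anchor Minimum exact resumption anchor in nt (default 20).
#' @param cds_start_on_cdna,cds_len_nt Optional CDS annotation carried into
#'   the returned model.
#' @return A `gene_model`.
#' @export
splice_map <- function(genomic, cdna, min_anchor = 20L,
                       cds_start_on_cdna = NA_integer_, cds_len_nt = NA_integer_) {
  g <- strsplit(toupper(genomic), "")[[1L]]
  cd <- strsplit(toupper(cdna), "")[[1L]]
  ng <- length(g)
  nc <- length(cd)
  if (nc > ng) stop("cDNA longer than genomic sequence")
  best_unmapped <- 0L

  solve <- function(gi, ci) {
    # Longest common run from (gi, ci).
    run_max <- min(ng - gi + 1L, nc - ci + 1L)
    if (run_max <= 0L) return(NULL)
    cmp <- g[gi:(gi + run_max - 1L)] == cd[ci:(ci + run_max - 1L)]
    run <- if (all(cmp)) run_max else which(!cmp)[1L] - 1L
    if (ci + run - 1L == nc) {                   # cDNA fully consumed
      return(list(list(g_start = gi, g_end = gi + run - 1L)))
    }
    if (run == 0L) return(NULL)
    ci2 <- ci + run
    gi2 <- gi + run
    best_unmapped <<- max(best_unmapped, ci2)
    rem <- nc - ci2 + 1L
    a <- min(as.integer(min_anchor), rem)
    anchor <- cd[ci2:(ci2 + a - 1L)]
    cand <- integer()
    if (gi2 + 1L <= ng - a + 1L) {
      rng <- (gi2 + 1L):(ng - a + 1L)
      for (p in rng[g[rng] == anchor[1L]]) {
        if (all(g[p:(p + a - 1L)] == anchor)) cand <- c(cand, p)
      }
    }
    if (length(cand) == 0L) return(NULL)
    sols <- list()
    for (p in cand) {
      down <- solve(p, ci2)
      if (!is.null(down)) {
        sols[[length(sols) + 1L]] <- c(list(list(g_start = gi, g_end = gi2 - 1L)),
                                       down)
      }
    }
    if (length(sols) == 0L) return(NULL)
    tot <- vapply(sols, function(s) {
      sum(vapply(seq_len(length(s) - 1L), function(i) {
        s[[i + 1L]]$g_start - s[[i]]$g_end - 1L
      }, numeric(1)))
    }, numeric(1))
    if (sum(tot == min(tot)) > 1L) stop("ambiguous splice: multiple equally small models")
    sols[[which.min(tot)]]
  }

  sol <- solve(1L, 1L)
  if (is.null(sol)) {
    stop("no consistent splice model; first unmappable cDNA offset: ",
         best_unmapped + 1L)
  }
  exons <- do.call(rbind, lapply(sol, function(s) c(s$g_start, s$g_end)))
  exons <- .canonicalise_splice(g, exons)
  gene_model(exons, genomic_len = ng,
             cds_start_on_cdna = cds_start_on_cdna, cds_len_nt = cds_len_nt)
}

# Slide each intron within its sequence-equivalent interval and prefer the
# leftmost placement with GT..AG ends; keep the greedy (rightmost) placement
# when no GT..AG placement exists.
.canonicalise_splice <- function(g, exons) {
  n <- nrow(exons)
  if (n < 2L) return(exons)
  for (i in seq_len(n - 1L)) {
    s <- exons[i, 2L] + 1L                  # intron start
    e <- exons[i + 1L, 1L] - 1L             # intron end
    if (e < s) next
    # Left slides: placement (s-k, e-k) is sequence-equivalent while
    # g[s-k] == g[e-k+1] for k = 1, 2, ...
    ks <- 0L
    k <- 1L
    lo <- if (i == 1L) 1L else exons[i, 1L] + 1L   # keep exon i non-empty
    while (s - k >= lo && g[s - k] == g[e - k + 1L]) {
      ks <- k
      k <- k + 1L
    }
    if (ks == 0L) next
    placements <- ks:0L                      # leftmost first
    is_gtag <- vapply(placements, function(k2) {
      g[s - k2] == "G" && g[s - k2 + 1L] == "T" &&
        g[e - k2 - 1L] == "A" && g[e - k2] == "G"
    }, logical(1))
    k2 <- if (any(is_gtag)) placements[which(is_gtag)[1L]] else 0L
    if (k2 > 0L) {
      exons[i, 2L] <- exons[i, 2L] - k2
      exons[i + 1L, 1L] <- exons[i + 1L, 1L] - k2
    }
  }
  exons
}

#' Per-intron phase and interrupted-codon report
#'
#' The phase of an intron is the number of nucleotides of the interrupted
#' codon already emitted upstream. A phase-0 intron falls between codons
#' `k` and `k+1`; phase-1/2 introns fall inside codon `k`.
#'
#' @param model A `gene_model` with CDS annotation.
#' @param protein Optional precursor protein string, used to report the
#'   residue at the interrupted codon.
#' @return Data frame with columns `index`, `length`, `phase`,
#'   `interrupted_codon` (text, e.g. `"22"` or `"between 39|40"`), `codon`
#'   (integer codon index; for phase 0 the upstream codon), and `residue`.
#' @export
intron_report <- function(model, protein = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.na(model$cds_start_on_cdna) || is.na(model$cds_len_nt)) {
    stop("gene model lacks CDS annotation")
  }
  n_int <- nrow(model$introns)
  if (n_int == 0L) {
    return(data.frame(index = integer(), length = integer(), phase = character(),
                      interrupted_codon = character(), codon = integer(),
                      residue = character(), stringsAsFactors = FALSE))
  }
  exon_lens <- model$exons[, "end"] - model$exons[, "start"] + 1L
  cum_exon <- cumsum(exon_lens)
  out <- lapply(seq_len(n_int), function(i) {
    len <- model$introns[i, "end"] - model$introns[i, "start"] + 1L
    cdna_pos <- cum_exon[i]                       # last cDNA nt before intron
    coding_nt <- cdna_pos - model$cds_start_on_cdna + 1L
    if (coding_nt <= 0L) {
      return(data.frame(index = i, length = len, phase = "noncoding",
                        interrupted_codon = NA_character_, codon = NA_integer_,
                        residue = NA_character_, stringsAsFactors = FALSE))
    }
    coding_nt <- min(coding_nt, model$cds_len_nt)
    ph <- coding_nt %% 3L
    if (ph == 0L) {
      k <- coding_nt %/% 3L
      codon <- k
      label <- paste0("between ", k, "|", k + 1L)
    } else {
      codon <- coding_nt %/% 3L + 1L
      label <- as.character(codon)
    }
    resid <- if (!is.null(protein) && codon <= nchar(protein)) {
      substr(protein, codon, codon)
    } else NA_character_
    data.frame(index = i, length = len, phase = as.character(ph),
               interrupted_codon = label, codon = codon, residue = resid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' CDS exon lengths of a gene model
#'
#' Overlap of each transcript exon with the CDS (stop codon excluded), in nt.
#'
#' @param model A `gene_model` with CDS annotation.
#' @export
cds_exon_lengths <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.na(model$cds_start_on_cdna) || is.na(model$cds_len_nt)) {
    stop("gene model lacks CDS annotation")
  }
  exon_lens <- model$exons[, "end"] - model$exons[, "start"] + 1L
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  cds0 <- model$cds_start_on_cdna
  cds1 <- cds0 + model$cds_len_nt - 1L
  pmax(0L, pmin(ends, cds1) - pmax(starts, cds0) + 1L)
}

#' Protein length encoded by a gene model
#'
#' Sum of CDS exon lengths divided by three; an error if the total is not
#' divisible by 3.
#'
#' @param model A `gene_model` with CDS annotation.
#' @export
coding_protein_length <- function(model) {
  tot <- sum(cds_exon_lengths(model))
  if (tot %% 3L != 0L) stop("total CDS length ", tot, " nt not divisible by 3")
  tot %/% 3L
}
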
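# Alignment machinery for the per-domain phylogenies: a global affine-gap
# (Gotoh) engine that aligns profiles as well as sequences, a progressive
# MSA driven by a k-mer-distance NJ guide, conserved-block cleaning, and
# alignment distances.

.GAP <- "-"

#' Construct an alignment
#'
#' @param rows Named character vector of equal-length gapped strings.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return Object of class `alignment`.
#' @export
alignment <- function(rows, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  stopifnot(length(rows) >= 1L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, ""))
  if (ncol(mat) > 0L && any(colSums(mat != .GAP) == 0L)) {
    stop("alignment has all-gap columns")
  }
  structure(list(rows = rows, kind = kind), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment (", x$kind, "): ", length(x$rows), " rows x ",
      nchar(x$rows[[1L]]), " columns\n", sep = "")
  invisible(x)
}

# Row matrix of single characters.
.aln_matrix <- function(aln) do.call(rbind, strsplit(aln$rows, ""))

# Substitution matrix for a kind: BLOSUM62 for protein, +1/-1 for nucleotide.
.subst_matrix <- function(kind) {
  if (kind == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    S <- e$BLOSUM62
    S[.AA20, .AA20]
  } else {
    S <- matrix(-1, 4L, 4L, dimnames = list(.BASES, .BASES))
    diag(S) <- 1
    S
  }
}

# Column-frequency profile of an alignment: alphabet x L, counts / n rows
# (gap mass simply missing, so gaps contribute zero substitution score).
.profile_of <- function(aln) {
  ab <- if (aln$kind == "protein") .AA20 else .BASES
  mat <- .aln_matrix(aln)
  L <- ncol(mat)
  prof <- matrix(0, nrow = length(ab), ncol = L, dimnames = list(ab, NULL))
  for (a in ab) prof[a, ] <- colSums(mat == a)
  prof / nrow(mat)
}

# Global affine-gap profile-profile alignment (Gotoh). Returns the score and
# the traceback path as moves "d" (column from both), "u" (column from a,
# gap in b), "l" (gap in a, column from b). Tie-break: diagonal, then up,
# then left, applied both to the final cell and to every predecessor choice.
.gotoh <- function(prof_a, prof_b, S, gap_open, gap_extend) {
  La <- ncol(prof_a)
  Lb <- ncol(prof_b)
  sub <- t(prof_a) %*% S %*% prof_b          # La x Lb expected column scores
  NEG <- -1e18
  M <- matrix(NEG, La + 1L, Lb + 1L)
  X <- matrix(NEG, La + 1L, Lb + 1L)         # ends consuming a (gap in b)
  Y <- matrix(NEG, La + 1L, Lb + 1L)         # ends consuming b (gap in a)
  M[1L, 1L] <- 0
  if (La > 0L) X[2L:(La + 1L), 1L] <- -gap_open - gap_extend * seq_len(La)
  if (Lb > 0L) Y[1L, 2L:(Lb + 1L)] <- -gap_open - gap_extend * seq_len(Lb)
  for (i in seq_len(La)) {
    for (j in seq_len(Lb)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + sub[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend,
                               Y[i, j + 1L] - gap_open - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               X[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  eps <- 1e-9
  score <- max(M[La + 1L, Lb + 1L], X[La + 1L, Lb + 1L], Y[La + 1L, Lb + 1L])
  state <- if (M[La + 1L, Lb + 1L] >= score - eps) "M"
           else if (X[La + 1L, Lb + 1L] >= score - eps) "X" else "Y"
  moves <- character()
  i <- La; j <- Lb
  while (i > 0L || j > 0L) {
    if (state == "M") {
      moves <- c("d", moves)
      val <- M[i + 1L, j + 1L] - sub[i, j]
      state <- if (M[i, j] >= val - eps) "M" else if (X[i, j] >= val - eps) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      moves <- c("u", moves)
      v <- X[i + 1L, j + 1L]
      state <- if (M[i, j + 1L] - gap_open - gap_extend >= v - eps) "M"
               else if (X[i, j + 1L] - gap_extend >= v - eps) "X" else "Y"
      i <- i - 1L
    } else {
      moves <- c("l", moves)
      v <- Y[i + 1L, j + 1L]
      state <- if (M[i + 1L, j] - gap_open - gap_extend >= v - eps) "M"
               else if (X[i + 1L, j] - gap_open - gap_extend >= v - eps) "X" else "Y"
      j <- j - 1L
    }
  }
  list(score = score, moves = moves)
}

# Merge two alignments along a traceback path.
.merge_alignments <- function(aln_a, aln_b, moves, kind) {
  mat_a <- .aln_matrix(aln_a)
  mat_b <- .aln_matrix(aln_b)
  na <- nrow(mat_a); nb <- nrow(mat_b)
  L <- length(moves)
  out <- matrix(.GAP, nrow = na + nb, ncol = L)
  ia <- 0L; ib <- 0L
  for (c0 in seq_len(L)) {
    mv <- moves[c0]
    if (mv != "l") { ia <- ia + 1L; out[seq_len(na), c0] <- mat_a[, ia] }
    if (mv != "u") { ib <- ib + 1L; out[na + seq_len(nb), c0] <- mat_b[, ib] }
  }
  rows <- apply(out, 1L, paste, collapse = "")
  names(rows) <- c(names(aln_a$rows), names(aln_b$rows))
  alignment(rows, kind = kind)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' BLOSUM62 scoring for protein, match +1 / mismatch -1 for nucleotide; a
#' gap of length `L` costs `gap_open + L * gap_extend`. Traceback ties are
#' broken deterministically: diagonal, then up, then left.
#'
#' @param a,b Sequences (ungapped strings).
#' @param kind `"protein"`, `"nucleotide"`, or `"auto"`.
#' @param gap_open,gap_extend Affine gap parameters (default 10 and 0.5).
#' @return List with elements `alignment` (an [alignment()]) and `score`.
#' @export
pairwise_align <- function(a, b, kind = c("auto", "protein", "nucleotide"),
                           gap_open = 10, gap_extend = 0.5) {
  kind <- match.arg(kind)
  stopifnot(nchar(a) > 0L || nchar(b) > 0L)
  if (kind == "auto") {
    kind <- if (grepl("^[ACGT]*$", paste0(a, b))) "nucleotide" else "protein"
  }
  na <- if (is.null(names(a))) "a" else names(a)
  nb <- if (is.null(names(b))) "b" else names(b)
  aln_a <- list(rows = stats::setNames(a, na), kind = kind)
  aln_b <- list(rows = stats::setNames(b, nb), kind = kind)
  class(aln_a) <- class(aln_b) <- "alignment"
  S <- .subst_matrix(kind)
  g <- .gotoh(.profile_of(aln_a), .profile_of(aln_b), S, gap_open, gap_extend)
  list(alignment = .merge_alignments(aln_a, aln_b, g$moves, kind),
       score = g$score)
}

# Fractional common k-mer distance between two ungapped sequences.
.kmer_distance <- function(a, b, k = 3L) {
  ka <- table(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- table(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  common <- intersect(names(ka), names(kb))
  shared <- sum(pmin(ka[common], kb[common]))
  1 - shared / (min(nchar(a), nchar(b)) - k + 1L)
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide from neighbor joining on fractional common k-mer distances
#' and merges profiles by global affine profile-profile alignment in guide
#' order. Deterministic: the guide's tie-breaks are lexicographic on
#' sequence names, so shuffling the input order does not change the result.
#'
#' @param seqs Named character vector of >= 2 ungapped sequences.
#' @param kind `"protein"`, `"nucleotide"`, or `"auto"`.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return An [alignment()] (rows in input order).
#' @export
progressive_msa <- function(seqs, kind = c("auto", "protein", "nucleotide"),
                            gap_open = 10, gap_extend = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (kind == "auto") {
    kind <- if (all(grepl("^[ACGT]*$", seqs))) "nucleotide" else "protein"
  }
  S <- .subst_matrix(kind)
  mk <- function(s, nm) structure(list(rows = stats::setNames(s, nm), kind = kind),
                                  class = "alignment")
  if (length(seqs) == 2L) {
    nm <- sort(names(seqs))
    g <- .gotoh(.profile_of(mk(seqs[[nm[1L]]], nm[1L])),
                .profile_of(mk(seqs[[nm[2L]]], nm[2L])), S, gap_open, gap_extend)
    res <- .merge_alignments(mk(seqs[[nm[1L]]], nm[1L]),
                             mk(seqs[[nm[2L]]], nm[2L]), g$moves, kind)
    return(alignment(res$rows[names(seqs)], kind))
  }
  nms <- names(seqs)
  D <- matrix(0, length(seqs), length(seqs), dimnames = list(nms, nms))
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (j > i) D[i, j] <- D[j, i] <- .kmer_distance(seqs[[i]], seqs[[j]])
    }
  }
  guide <- nj_tree(D)
  joins <- attr(guide, "joins")
  profiles <- stats::setNames(lapply(nms, function(nm) mk(seqs[[nm]], nm)), nms)
  for (jn in joins) {
    a <- profiles[[jn[1L]]]
    b <- profiles[[jn[2L]]]
    g <- .gotoh(.profile_of(a), .profile_of(b), S, gap_open, gap_extend)
    merged <- .merge_alignments(a, b, g$moves, kind)
    rep_nm <- min(jn)
    profiles[[jn[1L]]] <- NULL
    profiles[[jn[2L]]] <- NULL
    profiles[[rep_nm]] <- merged
  }
  final <- profiles[[1L]]
  alignment(final$rows[nms], kind)
}

#' Conserved-block cleaning of an alignment
#'
#' Keeps maximal runs of at least `min_block` columns whose gap fraction is
#' at most `max_gap_frac` and whose most-frequent residue (gaps counting
#' against conservation) reaches at least `min_conserved_frac` of the rows.
#'
#' @param aln An [alignment()].
#' @param max_gap_frac,min_conserved_frac Column thresholds.
#' @param min_block Minimum run length retained.
#' @return The cleaned [alignment()]; an error if no block survives.
#' @export
clean_blocks <- function(aln, max_gap_frac = 0.5, min_conserved_frac = 0.5,
                         min_block = 5L) {
  stopifnot(inherits(aln, "alignment"))
  mat <- .aln_matrix(aln)
  n <- nrow(mat)
  gap_frac <- colMeans(mat == .GAP)
  cons_frac <- apply(mat, 2L, function(col) {
    col <- col[col != .GAP]
    if (length(col) == 0L) 0 else max(table(col)) / n
  })
  good <- gap_frac <= max_gap_frac & cons_frac >= min_conserved_frac
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- logical(ncol(mat))
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_block) keep[starts[i]:ends[i]] <- TRUE
  }
  if (!any(keep)) stop("no blocks retained")
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(rows) <- names(aln$rows)
  alignment(rows, aln$kind)
}

#' Pairwise distances from an alignment
#'
#' Gap-containing sites are deleted per pair (pairwise deletion). `model =
#' "p"` is the mismatch fraction; `"poisson"` applies `-log(1 - p)`.
#'
#' @param aln An [alignment()].
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "alignment"), length(aln$rows) >= 2L)
  mat <- .aln_matrix(aln)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(aln$rows), names(aln$rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != .GAP & mat[j, ] != .GAP
      if (!any(ok)) stop("no comparable sites between '", names(aln$rows)[i],
                         "' and '", names(aln$rows)[j], "'")
      p <- mean(mat[i, ok] != mat[j, ok])
      d <- if (model == "p") p else {
        if (p >= 1) stop("saturated distance between '", names(aln$rows)[i],
                         "' and '", names(aln$rows)[j], "'")
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
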
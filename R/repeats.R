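# De-novo detection of tandem nucleotide repeats by k-mer self-matching at
# candidate period offsets, with ungapped copy-vs-consensus scoring. The
# copy model has no indels (the repeats modelled here are exact-length).

#' Find tandem repeats in a nucleotide sequence
#'
#' For each candidate period `d` in `[min_period, max_period]`, positions
#' where the sequence matches itself at offset `d` are seeded with exact
#' k-mers (`k = 12`), chained (seed gaps up to one period are bridged),
#' extended outwards base-by-base, and scored against a per-column
#' majority-vote consensus (ties broken alphabetically). Arrays below
#' `min_identity` or `min_copies` (floor of the copy number) are discarded;
#' overlapping reports are resolved by highest `copies * period`, then
#' smallest period.
#'
#' @param seq Nucleotide string, longer than `2 * min_period`.
#' @param min_period,max_period Period bounds in nt.
#' @param min_copies Minimum whole copies.
#' @param min_identity Minimum mean copy-vs-consensus identity.
#' @param k Seed k-mer length.
#' @return Data frame with columns `start`, `end`, `period`, `copies`
#'   (fractional), `copies_floor`, `mean_identity`, `consensus`, ordered by
#'   rank; zero rows when nothing is found.
#' @export
find_tandem_repeats <- function(seq, min_period = 30L, max_period = 600L,
                                min_copies = 2L, min_identity = 0.8, k = 12L) {
  x <- strsplit(toupper(seq), "")[[1L]]
  n <- length(x)
  if (n <= 2L * min_period) stop("sequence shorter than twice the minimum period")
  max_period <- min(max_period, n %/% 2L)
  hits <- list()
  for (d in min_period:max_period) {
    m <- n - d
    if (m < k) next
    eq <- x[1:m] == x[(d + 1L):n]
    # positions i where all of eq[i..i+k-1] hold
    cs <- cumsum(eq)
    wins <- cs[k:m] - c(0, cs)[1:(m - k + 1L)]
    seeds <- which(wins == k)
    if (length(seeds) == 0L) next
    # chain seeds: bridge gaps up to one period
    brk <- which(diff(seeds) > d)
    chain_start <- seeds[c(1L, brk + 1L)]
    chain_end <- seeds[c(brk, length(seeds))] + k - 1L
    for (ci in seq_along(chain_start)) {
      s0 <- chain_start[ci]
      e0 <- chain_end[ci]
      while (s0 > 1L && eq[s0 - 1L]) s0 <- s0 - 1L
      while (e0 < m && eq[e0 + 1L]) e0 <- e0 + 1L
      span_start <- s0
      span_end <- e0 + d
      L <- span_end - span_start + 1L
      copies <- L / d
      if (floor(copies) < min_copies) next
      sc <- .score_array(x, span_start, span_end, d)
      if (sc$mean_identity < min_identity) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = span_start, end = span_end, period = d, copies = copies,
        copies_floor = as.integer(floor(copies)),
        mean_identity = sc$mean_identity, consensus = sc$consensus,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), copies_floor = integer(),
                      mean_identity = numeric(), consensus = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-(out$copies * out$period), out$period, out$start), , drop = FALSE]
  keep <- logical(nrow(out))
  occupied <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(out))) {
    if (nrow(occupied) == 0L ||
        all(out$end[i] < occupied[, 1L] | out$start[i] > occupied[, 2L])) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(out$start[i], out$end[i]))
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Majority-vote consensus and mean copy-vs-consensus identity for the array
# x[from..to] tiled at period d (the final copy may be partial).
.score_array <- function(x, from, to, d) {
  L <- to - from + 1L
  n_full <- L %/% d
  cols <- matrix(NA_character_, nrow = n_full + (L %% d > 0L), ncol = d)
  for (ci in seq_len(nrow(cols))) {
    s <- from + (ci - 1L) * d
    e <- min(s + d - 1L, to)
    cols[ci, seq_len(e - s + 1L)] <- x[s:e]
  }
  consensus <- apply(cols, 2L, function(col) {
    col <- col[!is.na(col)]
    tab <- sort(table(col), decreasing = TRUE)
    cands <- names(tab)[tab == tab[1L]]
    sort(cands)[1L]
  })
  matches <- sweep(cols, 2L, consensus, FUN = "==")
  mean_identity <- mean(matches[!is.na(cols)])
  list(consensus = paste(consensus, collapse = ""), mean_identity = mean_identity)
}

#' Predicted amplicon ladder from a tandem repeat
#'
#' PCR across a tandem array yields artefactual products missing whole
#' repeat units; their predicted lengths are
#' `full_length - i * period` for `i = 0..copies`.
#'
#' @param full_length Full amplicon length in nt.
#' @param period Repeat unit length in nt.
#' @param copies Number of removable copies.
#' @return Integer vector of predicted lengths, longest first.
#' @export
amplicon_ladder <- function(full_length, period, copies) {
  stopifnot(full_length > 0L, period > 0L, copies >= 0L)
  as.integer(full_length - (0:copies) * period)
}
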
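# Sequence and tree I/O. Sequences travel through the package as named
# character vectors of uppercase strings; Biostrings does the parsing and the
# genetic code, ape does Newick. Coordinates are 1-based inclusive throughout.

.NUC_ALPHABET  <- c("A", "C", "G", "T", "N")
.AA20          <- c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y")
.PROT_ALPHABET <- c(.AA20, "X", "*")

#' Read a FASTA file
#'
#' Records are uppercased on load (lowercase input is reported via a message)
#' and validated against the nucleotide or protein alphabet. Malformed input
#' (empty records, illegal characters) is rejected with an error that names
#' the offending record and, where possible, the file line.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nuc"`, `"prot"`, or `"auto"` (guess from content).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nuc", "prot")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA parse error: no records in '", path, "'")
  seqs <- as.character(set)
  ids <- names(seqs)
  empties <- which(nchar(seqs) == 0L)
  if (length(empties) > 0L) {
    stop("FASTA parse error in '", path, "': empty record '",
         ids[empties[1L]], "' (record ", empties[1L], ", line ",
         .fasta_record_line(path, empties[1L]), ")")
  }
  if (any(grepl("[a-z]", seqs))) {
    message("read_fasta: lowercase residues uppercased on load")
    seqs <- toupper(seqs)
  }
  if (alphabet == "auto") {
    alphabet <- if (all(grepl("^[ACGTN]*$", seqs))) "nuc" else "prot"
  }
  allowed <- if (alphabet == "nuc") .NUC_ALPHABET else .PROT_ALPHABET
  bad <- which(!grepl(paste0("^[", paste(allowed, collapse = ""), "]*$"), seqs))
  if (length(bad) > 0L) {
    ch <- setdiff(strsplit(seqs[bad[1L]], "")[[1L]], allowed)[1L]
    stop("FASTA parse error in '", path, "': illegal character '", ch,
         "' in record '", ids[bad[1L]], "' (record ", bad[1L], ", line ",
         .fasta_record_line(path, bad[1L]), ")")
  }
  seqs
}

# Line number of the header of the i-th record (error reporting only).
.fasta_record_line <- function(path, i) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (length(headers) >= i) headers[i] else NA_integer_
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nchar(seqs) > 0L))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code only. The length must be divisible by 3; an internal
#' stop codon is an error naming the codon index unless `allow_stop = TRUE`
#' (stops are then emitted as `*`). A single terminal stop is trimmed when
#' `trim_terminal_stop = TRUE`.
#'
#' @param cds Nucleotide string (A/C/G/T).
#' @param allow_stop Permit internal stop codons.
#' @param trim_terminal_stop Drop a trailing stop codon before translating.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, allow_stop = FALSE, trim_terminal_stop = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    stop("untranslatable codon '", codons[which(is.na(aa))[1L]],
         "' at codon index ", which(is.na(aa))[1L])
  }
  if (trim_terminal_stop && aa[n_codon] == "*") {
    aa <- aa[-n_codon]
    n_codon <- n_codon - 1L
  }
  internal <- which(aa == "*")
  internal <- internal[internal < n_codon]
  if (!allow_stop && length(internal) > 0L) {
    stop("internal stop codon at codon index ", internal[1L])
  }
  paste(aa, collapse = "")
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]. Internal node
#' labels are used for integer bootstrap supports.
#'
#' @param path File path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in '", path, "': no tree read")
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
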
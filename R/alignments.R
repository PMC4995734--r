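# Lightweight sequence containers. Alignments are named character vectors
# of equal-length uppercase strings; '-' is the gap character. Codon
# alignments additionally have length divisible by 3 and whole-codon gaps.

#' Read/write FASTA as named character vectors
#'
#' Thin wrappers around Biostrings readers keeping the package's working
#' representation (named character vectors).
#'
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]), seqs[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}

# character matrix (rows = sequences) from an alignment
aln_matrix <- function(aln) {
  stopifnot(is.character(aln))
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

# matrix of codon strings (rows = sequences, cols = codon sites)
codon_matrix <- function(aln) {
  stopifnot(is.character(aln))
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (L %% 3L != 0L) stop("codon alignment length not divisible by 3")
  n_cod <- L %/% 3L
  starts <- seq(1L, L, by = 3L)
  m <- matrix(unlist(lapply(toupper(aln), function(s) {
    substring(s, starts, starts + 2L)
  }), use.names = FALSE), nrow = length(aln), ncol = n_cod, byrow = TRUE,
  dimnames = list(names(aln), NULL))
  m
}

#' Translate a coding sequence
#'
#' Standard-code translation; a terminal stop codon is stripped, an internal
#' stop raises an error naming the position.
#'
#' @param cds Nucleotide string with length divisible by 3.
#' @param id Sequence id used in error messages.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, id = "cds") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("CDS '%s' length %d not divisible by 3", id, nchar(cds)))
  }
  starts <- seq(1L, nchar(cds), by = 3L)
  cods <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  aa[is.na(aa)] <- "X"
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  stops <- which(aa == "*")
  if (length(stops)) {
    stop(sprintf("internal stop codon in '%s' at codon %d", id, stops[1L]))
  }
  paste(aa, collapse = "")
}
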
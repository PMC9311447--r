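#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors (the package keeps reads as character columns).
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, IUPAC allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random genome sequence
#'
#' @param length number of bases.
#' @param gc_content expected fraction of G+C bases.
#' @return a single character string over A/C/G/T.
#' @export
random_genome <- function(length, gc_content = 0.5) {
  stopifnot(length >= 0, gc_content >= 0, gc_content <= 1)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# phred+33 helpers ------------------------------------------------------------

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

constant_qual <- function(len, q = 37L) {
  ch <- rawToChar(as.raw(q + 33L))
  strrep(ch, len)
}

# Hamming distance between two equal-length strings (N matches nothing when
# `n_mismatches = TRUE` is not requested; plain byte comparison otherwise).
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# number of matching columns, N never matches (used for identity clustering)
match_columns <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n <- charToRaw("N")[1]
  sum(ra == rb & ra != n)
}

# FASTQ I/O -------------------------------------------------------------------

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(s),
             seq = as.character(s),
             qual = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
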
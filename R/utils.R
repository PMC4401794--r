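## Internal sequence and I/O helpers. Sequences travel as plain character
## vectors; Biostrings does the heavy lifting for file formats and
## mismatch-tolerant matching.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N; U tolerated).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  bases <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / bases
}

## Seeded random DNA; rejection against a predicate (e.g. the junk rules).
random_dna <- function(n, len, gc = 0.5, reject = NULL, max_tries = 1000L) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- rep_len(len, n)
  out <- character(n)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      s <- paste(sample(names(probs), lens[i], replace = TRUE, prob = probs),
                 collapse = "")
      if (is.null(reject) || !isTRUE(reject(s))) break
      if (t == max_tries)
        stop("random_dna: could not satisfy rejection predicate")
    }
    out[i] <- s
  }
  out
}

#' Read a FASTA file as a named character vector
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#' @param path file path (plain or gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(ss),
             seq = toupper(as.character(ss)),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Sanger / Phred+33)
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  lines <- character(4L * nrow(reads))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
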
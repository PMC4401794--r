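## Read cleaning: adapter trimming, length filter, junk filter, collapse.
##
## The junk rules follow the telegraphic convention of small RNA pipelines:
## >=2 N total; homopolymer runs of >=7 A, >=8 C, >=6 G, >=7 T; tandem
## repeats of a 2-mer unit >=10 copies, a 3-mer unit >=6 copies, a 4-mer
## unit >=5 copies. Rules are tested in that order and the first violated
## rule is reported. Homopolymeric repeat units never reach the di/tri/
## tetramer rules because the run rules (checked earlier) already catch any
## homopolymer long enough to form such a repeat.

.junk_rules <- list(
  list(label = ">=2N",        fun = function(s) nchar(s) - nchar(gsub("N", "", s, fixed = TRUE)) >= 2L),
  list(label = ">=7A",        fun = function(s) grepl("A{7,}", s)),
  list(label = ">=8C",        fun = function(s) grepl("C{8,}", s)),
  list(label = ">=6G",        fun = function(s) grepl("G{6,}", s)),
  list(label = ">=7T",        fun = function(s) grepl("T{7,}", s)),
  list(label = ">=10 dimer",  fun = function(s) grepl("([ACGTN]{2})\\1{9,}", s, perl = TRUE)),
  list(label = ">=6 trimer",  fun = function(s) grepl("([ACGTN]{3})\\1{5,}", s, perl = TRUE)),
  list(label = ">=5 tetramer", fun = function(s) grepl("([ACGTN]{4})\\1{4,}", s, perl = TRUE))
)

#' Trim the 3' adapter from reads
#'
#' Returns the read prefix preceding the leftmost occurrence of at least
#' `min_overlap` bases of the adapter's 5' end. Reads with no such match are
#' returned as `NA` ("3' adapter not found") and are discarded downstream.
#'
#' @param seqs character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum number of adapter bases that must match
#'   (default 8); matching is exact (no mismatches).
#' @return character vector: trimmed inserts, possibly `""` when the adapter
#'   starts at position 1, or `NA` when the adapter is not found.
#' @export
#' @examples
#' trim_adapter(c("ACGTACGTAGATCGGAAGAGC", "ACGTACGTACGTACGTACGTA"),
#'              "AGATCGGAAGAGCACACGTC")
trim_adapter <- function(seqs, adapter, min_overlap = 8L) {
  if (!is.character(adapter) || length(adapter) != 1L || nchar(adapter) == 0L)
    stop("adapter must be a single non-empty sequence")
  if (min_overlap < 1L || min_overlap > nchar(adapter))
    stop("min_overlap must be between 1 and the adapter length")
  seed <- substr(adapter, 1L, min_overlap)
  pos <- regexpr(seed, seqs, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), NA_character_)
  out
}

#' Length filter for cleaned tags
#'
#' @param seqs character vector of sequences.
#' @param min_len,max_len inclusive bounds (defaults 18 and 26 nt).
#' @return logical vector, `TRUE` when the length is within bounds.
#' @export
length_pass <- function(seqs, min_len = 18L, max_len = 26L) {
  n <- nchar(seqs)
  n >= min_len & n <= max_len
}

#' First violated junk rule, if any
#'
#' @param seqs character vector over the alphabet A/C/G/T/N.
#' @return character vector with the label of the first violated rule
#'   (in the documented order) or `NA` for clean sequences.
#' @export
#' @examples
#' junk_reason(c("TACCCTGTAGAACCGAATTTGT", "ACACACACACACACACACAC"))
junk_reason <- function(seqs) {
  if (any(grepl("[^ACGTN]", seqs)))
    stop("junk_reason: sequences must be over the alphabet {A,C,G,T,N}")
  out <- rep(NA_character_, length(seqs))
  todo <- rep(TRUE, length(seqs))
  for (rule in .junk_rules) {
    if (!any(todo)) break
    hit <- todo & rule$fun(seqs)
    out[hit] <- rule$label
    todo <- todo & !hit
  }
  out
}

#' Clean a raw read library and collapse it to counted unique tags
#'
#' Pipeline order is fixed: adapter trim, then length filter, then junk
#' filter, then collapse. Each raw read receives exactly one fate so the
#' accounting report partitions the input.
#'
#' @param reads data.frame with columns `id` and `seq` (e.g. from
#'   [read_fastq()]), or a character vector of sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter overlap, see [trim_adapter()].
#' @param min_len,max_len tag length bounds, see [length_pass()].
#' @return a list of class `mir_clean` with elements
#'   \describe{
#'     \item{tags}{data.frame `seq`, `count`, sorted by decreasing count
#'       then sequence;}
#'     \item{fates}{per-read fate, one of `adapter_length`, `junk`, `clean`;}
#'     \item{junk_reasons}{per-read junk rule label or `NA`;}
#'     \item{report}{data.frame with rows `raw`, `adapter_length`, `junk`,
#'       `clean`: total and unique read counts plus percentages of raw.
#'       Unique counts are distinct raw-read sequences per fate.}
#'   }
#' @export
clean_library <- function(reads, adapter, min_overlap = 8L,
                          min_len = 18L, max_len = 26L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) stop("clean_library: empty read set")
  trimmed <- trim_adapter(seqs, adapter, min_overlap)
  ok_len <- !is.na(trimmed) & length_pass(trimmed, min_len, max_len)
  fates <- ifelse(ok_len, "clean", "adapter_length")
  reasons <- rep(NA_character_, length(seqs))
  reasons[ok_len] <- junk_reason(trimmed[ok_len])
  fates[ok_len & !is.na(reasons)] <- "junk"
  clean <- fates == "clean"

  tab <- table(trimmed[clean])
  tags <- data.frame(seq = as.character(names(tab) %||% character(0)),
                     count = as.integer(tab), stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$seq), , drop = FALSE]
  rownames(tags) <- NULL

  n_total <- function(f) sum(fates == f)
  n_uniq <- function(f) length(unique(seqs[fates == f]))
  cat_names <- c("adapter_length", "junk", "clean")
  report <- data.frame(
    category = c("raw", cat_names),
    total = c(length(seqs), vapply(cat_names, n_total, integer(1))),
    unique = c(length(unique(seqs)), vapply(cat_names, n_uniq, integer(1))),
    stringsAsFactors = FALSE
  )
  report$total_pct <- round(100 * report$total / length(seqs), 2)
  rownames(report) <- NULL

  structure(list(tags = tags, fates = fates, junk_reasons = reasons,
                 report = report),
            class = "mir_clean")
}

#' @export
print.mir_clean <- function(x, ...) {
  cat("Read cleaning report (", x$report$total[1], " raw reads):\n", sep = "")
  print(x$report, row.names = FALSE)
  cat(nrow(x$tags), "unique clean tags\n")
  invisible(x)
}
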
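## Contaminant / annotation classification of clean tags.
##
## Tags are 18-26 nt, so matching is plain ungapped full-tag substring
## search (both strands) rather than a heuristic aligner. Categories are
## made disjoint by a priority order mirroring the usual report layout;
## each tag is assigned to the first category whose reference set it hits.

.default_priority <- c("rRNA", "tRNA", "snRNA", "snoRNA",
                       "other_ncRNA", "mRNA", "repeats")

#' Match a tag against a reference sequence set
#'
#' A hit is an end-to-end ungapped alignment of the tag as a substring of
#' some reference, on either strand, with at most `max_mismatch`
#' substitutions. Ties are broken deterministically: fewest mismatches,
#' then lexicographically smallest reference id, then plus strand, then
#' smallest start.
#'
#' @param tag a single tag sequence.
#' @param refset named character vector of reference sequences.
#' @param max_mismatch 0 or 1 allowed substitutions.
#' @return one-row data.frame (`ref_id`, `strand`, `start`, `mismatches`)
#'   or `NULL` when there is no hit.
#' @export
match_reference <- function(tag, refset, max_mismatch = 0L) {
  if (length(refset) == 0L) stop("match_reference: empty reference set")
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  subject <- Biostrings::DNAStringSet(refset)
  ord <- order(names(refset))
  best <- NULL
  for (mm in 0:max_mismatch) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      hits <- Biostrings::vmatchPattern(pat, subject, max.mismatch = mm)
      n_hit <- lengths(hits)
      for (i in ord) {
        if (n_hit[i] == 0L) next
        st <- BiocGenerics::start(hits[[i]])
        ## verify actual mismatch count (vmatchPattern reports <= mm)
        for (s in sort(st)) {
          win <- substr(refset[i], s, s + nchar(tag) - 1L)
          q <- if (strand == "+") tag else revcomp(tag)
          d <- sum(strsplit(win, "")[[1]] != strsplit(q, "")[[1]])
          if (d != mm) next
          return(data.frame(ref_id = names(refset)[i], strand = strand,
                            start = s, mismatches = mm,
                            stringsAsFactors = FALSE))
        }
      }
    }
  }
  best
}

#' Classify tags into contaminant categories by priority
#'
#' @param tags data.frame with columns `seq`, `count` (see [clean_library()]).
#' @param ref_sets named list of reference sets (named character vectors);
#'   names are category labels.
#' @param priority character vector listing every category once; tags are
#'   assigned to the first category (in this order) they hit. Defaults to
#'   rRNA, tRNA, snRNA, snoRNA, other_ncRNA, mRNA, repeats restricted to
#'   the categories present in `ref_sets`.
#' @param max_mismatch substitutions allowed per match (default 0).
#' @return list of class `mir_annot`:
#'   \describe{
#'     \item{assignments}{data.frame `seq`, `count`, `category`, `ref_id`
#'       (`category` is `"retained"` for unhit tags);}
#'     \item{retained}{data.frame `seq`, `count` of tags kept for miRNA
#'       analysis;}
#'     \item{report}{per-category totals/uniques and percentages of input.}
#'   }
#' @export
classify_tags <- function(tags, ref_sets, priority = NULL, max_mismatch = 0L) {
  if (is.null(priority))
    priority <- intersect(.default_priority, names(ref_sets))
  priority <- c(priority, setdiff(names(ref_sets), priority))
  if (anyDuplicated(priority))
    stop("classify_tags: priority must list every category once")
  missing <- setdiff(priority, names(ref_sets))
  if (length(missing))
    stop("classify_tags: no reference set for category: ",
         paste(missing, collapse = ", "))

  category <- rep("retained", nrow(tags))
  ref_id <- rep(NA_character_, nrow(tags))
  ## fast screen for exact matching: concatenate each category's references
  ## (and their reverse complements) with a separator outside the alphabet
  blobs <- lapply(ref_sets, function(refs) {
    if (length(refs) == 0L) return("")
    paste(c(refs, revcomp(refs)), collapse = "|")
  })
  for (cat in priority) {
    todo <- which(category == "retained")
    if (!length(todo)) break
    refs <- ref_sets[[cat]]
    if (length(refs) == 0L) next
    if (max_mismatch == 0L) {
      screen <- vapply(tags$seq[todo],
                       function(s) grepl(s, blobs[[cat]], fixed = TRUE),
                       logical(1))
      todo <- todo[screen]
    }
    for (i in todo) {
      hit <- match_reference(tags$seq[i], refs, max_mismatch)
      if (!is.null(hit)) {
        category[i] <- cat
        ref_id[i] <- hit$ref_id
      }
    }
  }
  assignments <- cbind(tags, data.frame(category = category, ref_id = ref_id,
                                        stringsAsFactors = FALSE))
  retained <- tags[category == "retained", , drop = FALSE]
  rownames(retained) <- NULL

  cats <- c(priority, "retained")
  total <- vapply(cats, function(cc) sum(tags$count[category == cc]),
                  integer(1))
  uniq <- vapply(cats, function(cc) sum(category == cc), integer(1))
  report <- data.frame(category = cats, total = total, unique = uniq,
                       stringsAsFactors = FALSE, row.names = NULL)
  report$total_pct <- round(100 * report$total / sum(tags$count), 2)
  report$unique_pct <- round(100 * report$unique / nrow(tags), 2)
  structure(list(assignments = assignments, retained = retained,
                 report = report),
            class = "mir_annot")
}

#' @export
print.mir_annot <- function(x, ...) {
  cat("Tag annotation report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
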
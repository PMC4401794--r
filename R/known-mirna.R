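## Known miRNA identification.
##
## Retained tags are aligned (ungapped, sense strand) onto the reference
## precursors with at most one substitution and end offsets of at most
## `max_offset` nucleotides relative to the annotated mature sequence. The
## isomiR naming convention encodes 5'/3' end shifts and substitutions:
## "<base>_L+1R-1" (one extra 5' base, one missing 3' base),
## "<base>_R+1_1ss12TA" (one extra 3' base, substitution at tag position 12,
## reference T observed A).

#' Locate each mature miRNA inside its precursor
#'
#' @param mature,precursors named character vectors.
#' @return data.frame `mature_id`, `precursor_id`, `start`, `end` (1-based,
#'   inclusive, on the precursor). A mature sequence must occur in exactly
#'   one precursor.
#' @export
locate_mature <- function(mature, precursors) {
  rows <- lapply(names(mature), function(id) {
    hits <- which(vapply(precursors, function(p)
      grepl(mature[[id]], p, fixed = TRUE), logical(1)))
    if (length(hits) != 1L)
      stop("mature '", id, "' occurs in ", length(hits),
           " precursors (expected exactly 1)")
    pid <- names(precursors)[hits]
    s <- regexpr(mature[[id]], precursors[[pid]], fixed = TRUE)
    data.frame(mature_id = id, precursor_id = pid, start = as.integer(s),
               end = as.integer(s) + nchar(mature[[id]]) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Match a tag to the known mature miRNA references
#'
#' Finds the mature reference minimizing (number of substitutions,
#' total absolute end offset, mature id); the tag must locate on the
#' mature's precursor within the offset bound.
#'
#' @param tag a single tag sequence.
#' @param mature,precursors named character vectors of reference sequences.
#' @param mature_map optional precomputed [locate_mature()] table.
#' @param max_mismatch maximum substitutions (default 1).
#' @param max_offset maximum absolute 5' or 3' end offset in nt (default 3).
#' @return one-row data.frame (`mature_id`, `precursor_id`, `off5`, `off3`,
#'   `mismatches`, `sub_pos`, `sub_ref`, `sub_obs`, `name`) or `NULL`.
#' @export
match_known <- function(tag, mature, precursors, mature_map = NULL,
                        max_mismatch = 1L, max_offset = 3L) {
  if (is.null(mature_map)) mature_map <- locate_mature(mature, precursors)
  best <- NULL
  best_key <- c(Inf, Inf)
  prec_set <- Biostrings::DNAStringSet(precursors)
  hits <- Biostrings::vmatchPattern(tag, prec_set, max.mismatch = max_mismatch)
  n_tag <- nchar(tag)
  tag_chars <- strsplit(tag, "")[[1]]
  for (pi in which(lengths(hits) > 0L)) {
    pid <- names(precursors)[pi]
    mrows <- mature_map[mature_map$precursor_id == pid, , drop = FALSE]
    if (!nrow(mrows)) next
    for (ts in BiocGenerics::start(hits[[pi]])) {
      te <- ts + n_tag - 1L
      if (ts < 1L || te > nchar(precursors[[pi]])) next
      win <- strsplit(substr(precursors[[pi]], ts, te), "")[[1]]
      mm_pos <- which(win != tag_chars)
      if (length(mm_pos) > max_mismatch) next
      for (mi in seq_len(nrow(mrows))) {
        off5 <- mrows$start[mi] - ts       # + : tag extends 5' of mature
        off3 <- te - mrows$end[mi]         # + : tag extends 3' of mature
        if (abs(off5) > max_offset || abs(off3) > max_offset) next
        key <- c(length(mm_pos), abs(off5) + abs(off3))
        better <- key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (all(key == best_key) && !is.null(best) &&
             mrows$mature_id[mi] < best$mature_id)
        if (!better) next
        subs <- if (length(mm_pos)) {
          data.frame(pos = mm_pos, ref = win[mm_pos], obs = tag_chars[mm_pos],
                     stringsAsFactors = FALSE)
        } else NULL
        best_key <- key
        best <- data.frame(
          mature_id = mrows$mature_id[mi], precursor_id = pid,
          off5 = off5, off3 = off3, mismatches = length(mm_pos),
          sub_pos = if (is.null(subs)) NA_integer_ else subs$pos[1],
          sub_ref = if (is.null(subs)) NA_character_ else subs$ref[1],
          sub_obs = if (is.null(subs)) NA_character_ else subs$obs[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(best)) {
    subs <- if (!is.na(best$sub_pos))
      data.frame(pos = best$sub_pos, ref = best$sub_ref, obs = best$sub_obs)
    else NULL
    best$name <- variant_name(best$mature_id, best$off5, best$off3, subs)
  }
  best
}

#' Canonical isomiR variant name
#'
#' @param base mature miRNA id.
#' @param off5 signed 5' end offset (positive: extra 5' bases).
#' @param off3 signed 3' end offset (positive: extra 3' bases).
#' @param subs optional data.frame `pos`, `ref`, `obs` (at most one row):
#'   1-based position on the tag, reference base, observed base.
#' @return the variant name; the bare base name when all are zero/empty.
#' @export
#' @examples
#' variant_name("oar-miR-10b", 1, -1, NULL)   # "oar-miR-10b_L+1R-1"
#' variant_name("oar-miR-10a", 0, 1, data.frame(pos = 12, ref = "T", obs = "A"))
variant_name <- function(base, off5 = 0L, off3 = 0L, subs = NULL) {
  name <- base
  endpart <- paste0(
    if (off5 != 0L) sprintf("L%+d", off5) else "",
    if (off3 != 0L) sprintf("R%+d", off3) else "")
  if (nzchar(endpart)) name <- paste0(name, "_", endpart)
  if (!is.null(subs) && nrow(subs) > 0L) {
    stopifnot(nrow(subs) == 1L)
    name <- paste0(name, sprintf("_%dss%d%s%s", nrow(subs),
                                 subs$pos[1], subs$ref[1], subs$obs[1]))
  }
  name
}

#' Parse an isomiR variant name back into its parts
#'
#' Inverse of [variant_name()], provided for round-trip testing.
#'
#' @param name a variant name.
#' @return list with `base`, `off5`, `off3` and `subs` (data.frame or NULL).
#' @export
parse_variant_name <- function(name) {
  off5 <- 0L; off3 <- 0L; subs <- NULL
  rest <- name
  m <- regmatches(rest, regexec("_(\\d+)ss(\\d+)([ACGTN])([ACGTN])$", rest))[[1]]
  if (length(m)) {
    subs <- data.frame(pos = as.integer(m[3]), ref = m[4], obs = m[5],
                       stringsAsFactors = FALSE)
    rest <- sub("_\\d+ss\\d+[ACGTN][ACGTN]$", "", rest)
  }
  m <- regmatches(rest, regexec("_(?:L([+-]\\d+))?(?:R([+-]\\d+))?$", rest,
                                perl = TRUE))[[1]]
  if (length(m) && nzchar(m[1]) && m[1] != "_") {
    if (nzchar(m[2])) off5 <- as.integer(m[2])
    if (nzchar(m[3])) off3 <- as.integer(m[3])
    rest <- substr(rest, 1L, nchar(rest) - nchar(m[1]))
  }
  list(base = rest, off5 = off5, off3 = off3, subs = subs)
}

## exact substring search of `x` in the genome, both strands; returns the
## first locus (contig, 1-based start/end, strand) or NULL
genome_locus <- function(x, genome) {
  for (ci in order(names(genome))) {
    s <- regexpr(x, genome[[ci]], fixed = TRUE)
    if (s > 0L)
      return(list(contig = names(genome)[ci], start = as.integer(s),
                  end = as.integer(s) + nchar(x) - 1L, strand = "+"))
    s <- regexpr(revcomp(x), genome[[ci]], fixed = TRUE)
    if (s > 0L)
      return(list(contig = names(genome)[ci], start = as.integer(s),
                  end = as.integer(s) + nchar(x) - 1L, strand = "-"))
  }
  NULL
}

#' Assign the evidence group of a (possibly matched) tag
#'
#' Groups follow the standard four-way evidence split for small RNA-seq
#' miRNA reports:
#' \describe{
#'   \item{gp1b}{tag matches a known miRNA and the reference precursor maps
#'     to the genome;}
#'   \item{gp2a}{tag matches a known miRNA, the precursor does not map, but
#'     the tag maps to the genome and the extended locus can form a hairpin;}
#'   \item{gp3a}{tag matches a known miRNA and neither the precursor nor
#'     the tag maps to the genome;}
#'   \item{gp4a}{tag matches no known miRNA but maps to the genome with a
#'     hairpin-forming extension.}
#' }
#' Unmatched tags that map nowhere (or map without hairpin evidence) are
#' dropped (`NA`).
#'
#' @param tag tag sequence.
#' @param match result of [match_known()] for the tag (or `NULL`).
#' @param genome named character vector of contigs.
#' @param precursors named character vector of reference precursors.
#' @param flank extension used for the hairpin check (default 80 nt).
#' @return `"gp1b"`, `"gp2a"`, `"gp3a"`, `"gp4a"` or `NA`.
#' @export
assign_group <- function(tag, match, genome, precursors, flank = 80L) {
  tag_loc <- genome_locus(tag, genome)
  if (!is.null(match)) {
    prec_loc <- genome_locus(precursors[[match$precursor_id]], genome)
    if (!is.null(prec_loc)) return("gp1b")
    if (is.null(tag_loc)) return("gp3a")
    if (locus_forms_hairpin(tag, tag_loc, genome, flank)) return("gp2a")
    return("gp3a")
  }
  if (!is.null(tag_loc) && locus_forms_hairpin(tag, tag_loc, genome, flank))
    return("gp4a")
  NA_character_
}

## does any flank-extended window around the locus pass the hairpin filters?
locus_forms_hairpin <- function(tag, loc, genome, flank = 80L) {
  wins <- candidate_windows(genome, loc, flank)
  for (w in wins) {
    ev <- evaluate_candidate(w$seq, w$mature_start, w$mature_end)
    if (ev$pass) return(TRUE)
  }
  FALSE
}
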
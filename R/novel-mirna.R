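## Novel miRNA candidate evaluation.
##
## Unannotated tags that map to the genome are extended by `flank` nt,
## folded, and the hairpin enclosing the tag is excised and screened with
## the canonical precursor filters: trimmed length 50-123 nt, GC fraction
## 0.23-0.77, free energy -80.5..-17.7 kcal/mol, a single terminal loop,
## and the mature entirely on one arm with at most `max_unpaired` unpaired
## mature bases.
##
## The default folding backend is a built-in dynamic-programming maximizer
## of weighted base pairs (GC=3, AU=2, GU=1, minimum loop 3). Its "free
## energy" is -(pair weight sum) * `dg_per_unit`; the calibration constant
## 0.35 kcal/mol per weight unit places typical miRNA-like hairpins
## (25-40 pair stems) inside the published bounds. A thermodynamic folder
## can be substituted via the `backend` argument of [fold_sequence()].

.novel_defaults <- list(
  min_len = 50L, max_len = 123L,
  min_gc = 0.23, max_gc = 0.77,
  min_dg = -80.5, max_dg = -17.7,
  max_unpaired = 4L,
  dg_per_unit = 0.35
)

#' Fold a sequence into a nested secondary structure
#'
#' @param seq RNA or DNA sequence (T and U are equivalent).
#' @param backend a folding backend: `"nussinov"` (built-in, default) or a
#'   function `function(seq)` returning `list(structure=, dg=)` for an
#'   external thermodynamic folder.
#' @param min_loop minimum hairpin loop size for the built-in backend.
#' @param dg_per_unit kcal/mol per pair-weight unit for the built-in
#'   backend's energy calibration.
#' @return list with `structure` (dot-bracket), `dg` (kcal/mol) and, for
#'   the built-in backend, the raw `score`.
#' @export
#' @examples
#' fold_sequence("GGGGAAAACCCC")
fold_sequence <- function(seq, backend = "nussinov", min_loop = 3L,
                          dg_per_unit = .novel_defaults$dg_per_unit) {
  if (is.function(backend)) return(backend(seq))
  stopifnot(identical(backend, "nussinov"))
  res <- .nussinov_fold(toupper(seq), as.integer(min_loop))
  list(structure = res$structure, dg = -res$score * dg_per_unit,
       score = res$score)
}

#' Parse dot-bracket notation into a pairing table
#'
#' @param db dot-bracket string.
#' @return integer vector: `partner[i]` is the paired position of base `i`
#'   or 0 when unpaired. Errors on unbalanced brackets.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    } else if (ch[i] != ".") stop("invalid dot-bracket character: ", ch[i])
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  partner
}

## terminal loops: closing pairs (i,j) with every base between them unpaired
terminal_loops <- function(partner) {
  out <- list()
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > i && (j == i + 1L || all(partner[(i + 1L):(j - 1L)] == 0L)))
      out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

## number of terminal loops inside [a, b]
loops_within <- function(loops, a, b) {
  sum(vapply(loops, function(l) l[1] >= a && l[2] <= b, logical(1)))
}

## for each terminal loop, the largest enclosing pair whose interval still
## contains only that loop ("hairpin span"); returns list of c(a, b)
hairpin_spans <- function(partner) {
  loops <- terminal_loops(partner)
  lapply(loops, function(l) {
    a <- l[1]; b <- l[2]
    repeat {
      nxt <- NULL
      for (x in rev(seq_len(a - 1L))) {
        if (partner[x] > b) { nxt <- c(x, partner[x]); break }
        if (partner[x] != 0L && partner[x] < b) break  # sibling structure
      }
      if (is.null(nxt) || loops_within(loops, nxt[1], nxt[2]) != 1L) break
      a <- nxt[1]; b <- nxt[2]
    }
    c(a, b)
  })
}

#' Extract flank-extended candidate windows around a genomic tag locus
#'
#' Returns up to three windows (left-extended, right-extended, and both),
#' clipped at contig ends, with the tag's position inside each window.
#' Minus-strand loci are reverse-complemented so the tag reads 5' to 3'.
#'
#' @param genome named character vector of contigs.
#' @param contig contig name.
#' @param start,end 1-based inclusive tag coordinates on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @param flank extension in nt (default 80).
#' @return list of windows, each `list(seq, mature_start, mature_end,
#'   contig, win_start, win_end, strand, kind)` with mature coordinates
#'   1-based within `seq`.
#' @export
extract_flanks <- function(genome, contig, start, end, strand = "+",
                           flank = 80L) {
  if (!contig %in% names(genome)) stop("contig not found: ", contig)
  start <- as.integer(start); end <- as.integer(end)
  flank <- as.integer(flank)
  len <- nchar(genome[[contig]])
  if (start < 1L || end > len || start > end)
    stop("locus outside contig bounds")
  mk <- function(ws, we, kind) {
    ws <- max(1L, ws); we <- min(len, we)
    s <- substr(genome[[contig]], ws, we)
    ms <- start - ws + 1L
    me <- end - ws + 1L
    if (strand == "-") {
      s <- revcomp(s)
      n <- nchar(s)
      new_ms <- n - me + 1L
      me <- n - ms + 1L
      ms <- new_ms
    }
    list(seq = s, mature_start = ms, mature_end = me, contig = contig,
         win_start = ws, win_end = we, strand = strand, kind = kind)
  }
  list(both = mk(start - flank, end + flank, "both"),
       left = mk(start - flank, end, "left"),
       right = mk(start, end + flank, "right"))
}

#' Screen a candidate window with the precursor filters
#'
#' Folds the window (unless a structure is supplied), excises the hairpin
#' enclosing the mature tag, and applies the precursor filters. The trimmed
#' hairpin span — not the full search window — is reported as the precursor.
#'
#' @param window_seq candidate window sequence.
#' @param mature_start,mature_end 1-based mature (tag) coordinates within
#'   the window.
#' @param fold result of [fold_sequence()] on `window_seq`; computed when
#'   `NULL`.
#' @param params filter bounds; see `.novel_defaults` in the package source
#'   (length 50-123, GC 0.23-0.77, dG -80.5..-17.7, at most 4 unpaired
#'   mature bases).
#' @return list with `pass` (logical), `reasons` (character, empty iff
#'   pass) and on success `candidate`: list(`precursor_seq`, `structure`,
#'   `dg`, `gc`, `arm` ("5p"/"3p"), `precursor_start`, `precursor_end`,
#'   `mature_seq`).
#' @export
evaluate_candidate <- function(window_seq, mature_start, mature_end,
                               fold = NULL, params = list()) {
  p <- utils::modifyList(.novel_defaults, params)
  n <- nchar(window_seq)
  if (mature_start < 1L || mature_end > n || mature_start > mature_end)
    stop("mature interval outside the window")
  if (is.null(fold)) fold <- fold_sequence(window_seq,
                                           dg_per_unit = p$dg_per_unit)
  partner <- parse_dotbracket(fold$structure)
  loops <- terminal_loops(partner)
  spans <- hairpin_spans(partner)
  reasons <- character(0)

  ## hairpin span containing the mature
  sel <- NULL
  for (k in seq_along(spans)) {
    sp <- spans[[k]]
    if (mature_start >= sp[1] && mature_end <= sp[2]) { sel <- k; break }
  }
  if (is.null(sel))
    return(list(pass = FALSE, reasons = "no hairpin enclosing mature",
                candidate = NULL))
  span <- spans[[sel]]
  loop <- loops[[sel]]
  a <- span[1]; b <- span[2]

  prec <- substr(window_seq, a, b)
  struct <- substr(fold$structure, a, b)
  plen <- b - a + 1L
  gc <- gc_fraction(prec)
  ## energy of the excised hairpin: pairs wholly inside the span
  idx <- which(partner > seq_along(partner) & seq_along(partner) >= a &
                 partner <= b)
  w <- pair_weights(window_seq, idx, partner)
  dg <- -sum(w) * p$dg_per_unit

  if (plen < p$min_len) reasons <- c(reasons, sprintf("length<%d", p$min_len))
  if (plen > p$max_len) reasons <- c(reasons, sprintf("length>%d", p$max_len))
  if (gc < p$min_gc) reasons <- c(reasons, sprintf("GC<%.2f", p$min_gc))
  if (gc > p$max_gc) reasons <- c(reasons, sprintf("GC>%.2f", p$max_gc))
  if (dg < p$min_dg) reasons <- c(reasons, sprintf("dG<%.1f", p$min_dg))
  if (dg > p$max_dg) reasons <- c(reasons, sprintf("dG>%.1f", p$max_dg))

  arm <- NA_character_
  if (mature_end <= loop[1]) arm <- "5p"
  else if (mature_start >= loop[2]) arm <- "3p"
  if (is.na(arm))
    reasons <- c(reasons, "mature overlaps terminal loop")
  unpaired <- sum(partner[mature_start:mature_end] == 0L)
  if (unpaired > p$max_unpaired)
    reasons <- c(reasons, sprintf("unpaired mature bases>%d", p$max_unpaired))

  pass <- length(reasons) == 0L
  cand <- if (pass) {
    list(precursor_seq = prec, structure = struct, dg = dg, gc = gc,
         arm = arm, precursor_start = a, precursor_end = b,
         mature_seq = substr(window_seq, mature_start, mature_end))
  } else NULL
  list(pass = pass, reasons = reasons, candidate = cand)
}

## pair weights (GC=3, AU=2, GU=1) for opening positions `idx`
pair_weights <- function(seq, idx, partner) {
  if (!length(idx)) return(numeric(0))
  s <- chartr("T", "U", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  vapply(idx, function(i) {
    duo <- paste0(sort(c(ch[i], ch[partner[i]])), collapse = "")
    switch(duo, "CG" = 3, "AU" = 2, "GU" = 1, 0)
  }, numeric(1))
}

#' Candidate name in the PC-{arm}-{index}_{count} convention
#' @param arm "5p" or "3p" (mature arm).
#' @param index integer candidate index.
#' @param count read count of the mature tag.
#' @return e.g. `"PC-5p-69112_10"`.
#' @export
pc_name <- function(arm, index, count) sprintf("PC-%s-%d_%d", arm, index, count)

#' Parse a PC-style candidate name
#' @param name candidate name from [pc_name()].
#' @return list with `arm`, `index`, `count`.
#' @export
parse_pc_name <- function(name) {
  m <- regmatches(name, regexec("^PC-(5p|3p)-(\\d+)_(\\d+)$", name))[[1]]
  if (!length(m)) stop("not a PC candidate name: ", name)
  list(arm = m[2], index = as.integer(m[3]), count = as.integer(m[4]))
}

#' Mature-anchored candidate windows around a genomic locus
#'
#' The flank-extended search window is scanned with a grid of subwindows
#' anchored at the mature tag (smallest extensions first, the three full
#' flank windows last). Hairpin excision on subwindows is far more robust
#' than folding the whole search window, where distant flank sequence can
#' pair across the planted stem.
#'
#' @inheritParams extract_flanks
#' @param loc locus list with `contig`, `start`, `end`, `strand` (e.g.
#'   from the genome search in [find_novel_candidates()]).
#' @param steps 5'/3' extension grid in nt.
#' @return list of windows in evaluation order, each with `seq`,
#'   `mature_start`, `mature_end`.
#' @export
candidate_windows <- function(genome, loc, flank = 80L,
                              steps = c(8L, 20L, 35L, 55L, 80L)) {
  wins <- extract_flanks(genome, loc$contig, loc$start, loc$end,
                         loc$strand, flank)
  base <- wins$both
  n <- nchar(base$seq)
  steps <- sort(unique(pmin(steps, flank)))
  grid <- expand.grid(d5 = steps, d3 = steps)
  grid <- grid[order(grid$d5 + grid$d3, grid$d5), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(grid))) {
    ws <- max(1L, base$mature_start - grid$d5[k])
    we <- min(n, base$mature_end + grid$d3[k])
    out[[length(out) + 1L]] <- list(
      seq = substr(base$seq, ws, we),
      mature_start = base$mature_start - ws + 1L,
      mature_end = base$mature_end - ws + 1L)
  }
  c(out, unname(wins))
}

#' Find novel miRNA candidates among unannotated tags
#'
#' Each tag is searched in the genome (exact, both strands); the
#' mature-anchored windows around the first locus ([candidate_windows()])
#' are screened with [evaluate_candidate()] and the first passing window
#' yields the candidate.
#'
#' @param tags data.frame with columns `seq` and per-library counts
#'   (`count_p`, `count_r` or a single `count`).
#' @param genome named character vector of contigs.
#' @param flank window extension in nt (default 80).
#' @param params filter overrides passed to [evaluate_candidate()].
#' @return data.frame, one row per candidate: `name`, `seq`, `arm`,
#'   `length`, `precursor_seq`, `structure`, `dg`, `gc`, `contig`,
#'   `start`, `end`, `strand`, plus the count columns of `tags`.
#' @export
find_novel_candidates <- function(tags, genome, flank = 80L, params = list()) {
  count_cols <- intersect(c("count", "count_p", "count_r"), names(tags))
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    loc <- genome_locus(tags$seq[i], genome)
    if (is.null(loc)) next
    wins <- candidate_windows(genome, loc, flank)
    for (w in wins) {
      ev <- evaluate_candidate(w$seq, w$mature_start, w$mature_end,
                               params = params)
      if (!ev$pass) next
      cc <- ev$candidate
      total <- sum(unlist(tags[i, count_cols, drop = FALSE]))
      row <- data.frame(
        name = pc_name(cc$arm, i, total), seq = tags$seq[i], arm = cc$arm,
        length = nchar(tags$seq[i]), precursor_seq = cc$precursor_seq,
        structure = cc$structure, dg = cc$dg, gc = cc$gc,
        contig = loc$contig, start = loc$start, end = loc$end,
        strand = loc$strand, stringsAsFactors = FALSE)
      for (col in count_cols) row[[col]] <- tags[[col]][i]
      rows[[length(rows) + 1L]] <- row
      break
    }
  }
  if (!length(rows)) {
    out <- data.frame(name = character(0), seq = character(0),
                      arm = character(0), length = integer(0),
                      precursor_seq = character(0), structure = character(0),
                      dg = numeric(0), gc = numeric(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    for (col in count_cols) out[[col]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
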
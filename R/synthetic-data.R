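## Seeded synthetic data: reference bundles, FASTQ libraries with known
## ground truth, and qPCR Ct tables.
##
## The generator emulates a two-condition small RNA-seq experiment: known
## miRNA hairpins (a subset embedded in a genome), contaminant reference
## sets, 3'UTRs with planted seed sites, GO/pathway annotation, and raw
## 36 bp adapter-ligated reads whose per-miRNA counts follow a negative
## binomial around design means with planted fold changes. miRNA and
## contaminant reads are clean by construction (rejection-sampled against
## the junk rules and adapter collisions) so that cleaning/annotation
## reports can be compared with the ground truth exactly; junk reads are
## built to violate a specific junk rule.

.default_adapter <- "TGGAATTCTCGGGTGCCAAG"

## mature length distribution (mode 22), mirroring the typical clean-read
## length profile of mammalian small RNA libraries
.mature_length_probs <- c(`18` = 0.04, `19` = 0.05, `20` = 0.10, `21` = 0.18,
                          `22` = 0.38, `23` = 0.12, `24` = 0.06, `25` = 0.04,
                          `26` = 0.03)

## contaminant category weights (share of raw reads, normalized internally)
.contaminant_weights <- c(rRNA = 7.80, tRNA = 1.26, snRNA = 0.27,
                          snoRNA = 0.31, other_ncRNA = 0.75, mRNA = 3.07,
                          repeats = 1.35)

is_junk <- function(s) !is.na(junk_reason(s))

## one hairpin precursor with the mature on the requested arm:
## perfect stem (pads + mature), loop drawn from {A, C} so the loop cannot
## pair internally, guaranteeing a single terminal loop
build_hairpin <- function(mature, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  pad5 <- random_dna(1, sample(2:4, 1))
  pad3 <- random_dna(1, sample(2:4, 1))
  loop <- paste(sample(c("A", "C"), sample(9:15, 1), replace = TRUE),
                collapse = "")
  stem <- paste0(pad5, mature, pad3)
  if (arm == "5p") paste0(stem, loop, revcomp(stem))
  else paste0(revcomp(stem), loop, stem)
}

#' Generate a synthetic reference bundle
#'
#' Builds mature miRNAs (each an exact substring of exactly one hairpin
#' precursor, on one arm), contaminant reference sets, a genome embedding a
#' known subset of the precursors, 3'UTRs with planted seed-match target
#' sites, and a gene-to-term annotation table. Everything derives from one
#' integer seed; identical seeds give byte-identical output.
#'
#' Known miRNAs are split into evidence classes: `n_gp2a` have an
#' alternative hairpin (same mature, different loop/pads) embedded in the
#' genome while their reference precursor is absent; `n_gp3a` are absent
#' from the genome entirely; the rest have their precursor embedded
#' (gp1b). `n_novel` extra hairpins are embedded whose matures are absent
#' from the reference sets (gp4a / novel candidates).
#'
#' @param n_mirna number of known mature miRNAs (>= 1).
#' @param n_gp2a,n_gp3a,n_novel evidence-class sizes (see above).
#' @param n_contigs,contig_spacer genome layout: number of contigs and the
#'   random spacer length between embedded elements (contigs come out at
#'   least 1 kb).
#' @param contaminants_per_category,contaminant_length number and length
#'   range of reference sequences per contaminant category.
#' @param n_genes,utr_length number and length range of 3'UTR sequences.
#' @param targets_per_mirna planted seed-site target genes per known miRNA.
#' @param n_go_terms,n_pathways annotation vocabulary sizes.
#' @param mature_lengths allowed mature lengths; must lie within 18-26 nt.
#' @param seed integer seed.
#' @return a list of class `mir_bundle`; see the package vignette for the
#'   component layout.
#' @export
generate_references <- function(n_mirna = 30, n_gp2a = 2, n_gp3a = 2,
                                n_novel = 4, n_contigs = 4,
                                contig_spacer = c(150, 350),
                                contaminants_per_category = 6,
                                contaminant_length = c(200, 800),
                                n_genes = 60, utr_length = c(300, 900),
                                targets_per_mirna = 4, n_go_terms = 40,
                                n_pathways = 15, mature_lengths = 18:26,
                                seed = 1) {
  if (n_mirna < 1 || n_contigs < 1 || n_genes < 1)
    stop("size parameters must be >= 1")
  if (any(mature_lengths < 18 | mature_lengths > 26))
    stop("mature lengths must be between 18 and 26 nt")
  if (n_gp2a + n_gp3a > n_mirna)
    stop("n_gp2a + n_gp3a cannot exceed n_mirna")
  set.seed(as.integer(seed))

  probs <- .mature_length_probs[as.character(mature_lengths)]
  probs[is.na(probs)] <- min(.mature_length_probs)
  draw_len <- function(n) sample(mature_lengths, n, replace = TRUE,
                                 prob = probs)

  ## --- known matures + precursors -------------------------------------
  n_all <- n_mirna + n_novel
  matures <- character(0)
  seed8 <- substr(.default_adapter, 1, 8)
  bad_mature <- function(s) is_junk(s) || grepl(seed8, s, fixed = TRUE)
  repeat {
    need <- n_all - length(matures)
    if (need == 0L) break
    cand <- random_dna(need, draw_len(need), gc = 0.5, reject = bad_mature)
    matures <- unique(c(matures, cand))
  }
  arms <- rep_len(c("5p", "3p"), n_all)
  precs <- vapply(seq_len(n_all), function(i)
    build_hairpin(matures[i], arms[i]), character(1))
  ## no mature may occur in a foreign precursor (or twice anywhere)
  for (i in seq_len(n_all)) {
    while (sum(vapply(precs, function(p)
      grepl(matures[i], p, fixed = TRUE), logical(1))) != 1L) {
      precs[i] <- build_hairpin(matures[i], arms[i])  # extremely rare
    }
  }
  known <- seq_len(n_mirna)
  mat_ids <- sprintf("syn-miR-%03d", known)
  prec_ids <- sprintf("syn-mir-%03d", known)
  nov_idx <- setdiff(seq_len(n_all), known)
  mature <- setNames(matures[known], mat_ids)
  precursors <- setNames(precs[known], prec_ids)
  novel_mature <- setNames(matures[nov_idx],
                           sprintf("syn-novel-%03d", seq_along(nov_idx)))
  novel_precursors <- setNames(precs[nov_idx], names(novel_mature))

  cls <- rep("gp1b", n_mirna)
  if (n_gp2a > 0) cls[seq_len(n_gp2a)] <- "gp2a"
  if (n_gp3a > 0) cls[n_gp2a + seq_len(n_gp3a)] <- "gp3a"

  ## --- genome ----------------------------------------------------------
  inserts <- list()
  for (i in known) {
    if (cls[i] == "gp1b")
      inserts[[length(inserts) + 1L]] <-
        list(kind = "precursor", id = prec_ids[i], seq = precs[i])
    if (cls[i] == "gp2a")
      inserts[[length(inserts) + 1L]] <-
        list(kind = "alt_hairpin", id = mat_ids[i],
             seq = build_hairpin(matures[i], arms[i]))
  }
  for (k in seq_along(nov_idx))
    inserts[[length(inserts) + 1L]] <-
      list(kind = "novel", id = names(novel_mature)[k],
           seq = novel_precursors[[k]])
  strands <- rep_len(c("+", "-"), length(inserts))
  contig_of <- rep_len(seq_len(n_contigs), length(inserts))
  genome <- character(n_contigs)
  loci <- list()
  spacer <- function() random_dna(
    1, sample(contig_spacer[1]:contig_spacer[2], 1), gc = 0.42)
  for (ci in seq_len(n_contigs)) {
    cname <- sprintf("contig_%02d", ci)
    parts <- spacer()
    for (k in which(contig_of == ci)) {
      ins <- inserts[[k]]
      ## hairpin-evidence inserts (gp2a alternative hairpins and novel
      ## precursors) must actually pass the hairpin screen in their genomic
      ## context; rebuild pads/loop/spacer until they do
      needs_hairpin <- ins$kind %in% c("alt_hairpin", "novel")
      if (needs_hairpin) {
        mat <- if (ins$kind == "novel") novel_mature[[ins$id]]
               else mature[[ins$id]]
        marm <- if (ins$kind == "novel")
          arms[nov_idx[match(ins$id, names(novel_mature))]]
        else arms[match(ins$id, mat_ids)]
      }
      for (try in 1:30) {
        s <- ins$seq
        if (strands[k] == "-") s <- revcomp(s)
        cand_contig <- paste0(parts, s, spacer())
        if (!needs_hairpin) break
        mloc <- genome_locus(mat, setNames(cand_contig, cname))
        ok <- !is.null(mloc) &&
          any(vapply(candidate_windows(setNames(cand_contig, cname), mloc),
                     function(w) evaluate_candidate(w$seq, w$mature_start,
                                                    w$mature_end)$pass,
                     logical(1)))
        if (ok) break
        if (try == 30L) stop("could not embed a context-valid hairpin for ",
                             ins$id)
        ins$seq <- build_hairpin(mat, marm)
      }
      if (ins$kind == "novel") novel_precursors[[ins$id]] <- ins$seq
      inserts[[k]] <- ins
      start <- nchar(parts) + 1L
      loci[[length(loci) + 1L]] <- data.frame(
        kind = ins$kind, id = ins$id, contig = cname, start = start,
        end = start + nchar(ins$seq) - 1L, strand = strands[k],
        stringsAsFactors = FALSE)
      parts <- cand_contig
    }
    while (nchar(parts) < 1000L)
      parts <- paste0(parts, random_dna(1, 200, gc = 0.42))
    genome[ci] <- parts
  }
  names(genome) <- sprintf("contig_%02d", seq_len(n_contigs))
  genome_loci <- do.call(rbind, loci)

  ## --- contaminants ----------------------------------------------------
  contaminants <- lapply(setNames(nm = names(.contaminant_weights)),
                         function(cat) {
    lens <- sample(contaminant_length[1]:contaminant_length[2],
                   contaminants_per_category, replace = TRUE)
    setNames(random_dna(contaminants_per_category, lens, gc = 0.45),
             sprintf("%s_%03d", cat, seq_len(contaminants_per_category)))
  })

  ## --- UTRs, planted target sites, annotation --------------------------
  gene_ids <- sprintf("G%04d.1", seq_len(n_genes))
  utr3 <- setNames(random_dna(n_genes,
                              sample(utr_length[1]:utr_length[2], n_genes,
                                     replace = TRUE), gc = 0.4), gene_ids)
  sites <- list()
  used <- setNames(vector("list", n_genes), gene_ids)  # planted starts (1-based)
  for (i in seq_len(n_mirna)) {
    tg <- sample(gene_ids, min(targets_per_mirna, n_genes))
    site <- revcomp(substr(mature[[i]], 2L, 8L))
    for (g in tg) {
      repeat {  # avoid overwriting a previously planted site
        pos <- sample(seq_len(nchar(utr3[[g]]) - 7L), 1)
        if (!length(used[[g]]) || all(abs(pos - used[[g]]) >= 7L)) break
      }
      substr(utr3[[g]], pos, pos + 6L) <- site
      used[[g]] <- c(used[[g]], pos)
      sites[[length(sites) + 1L]] <- data.frame(
        mirna = mat_ids[i], gene = g, position = pos - 1L,
        stringsAsFactors = FALSE)
    }
  }
  planted_sites <- do.call(rbind, sites)
  utr3 <- scrub_accidental_sites(utr3, mature, planted_sites)

  terms_go <- sprintf("GO:%07d", seq_len(n_go_terms))
  terms_pw <- sprintf("PW%04d", seq_len(n_pathways))
  tm <- list()
  for (g in gene_ids) {
    tm[[length(tm) + 1L]] <- data.frame(
      gene = g, namespace = "GO",
      term = sample(terms_go, sample(2:4, 1)), stringsAsFactors = FALSE)
    tm[[length(tm) + 1L]] <- data.frame(
      gene = g, namespace = "pathway",
      term = sample(terms_pw, sample(1:2, 1)), stringsAsFactors = FALSE)
  }
  term_map <- do.call(rbind, tm)

  mature_map <- locate_mature(mature, precursors)
  mature_map$arm <- arms[known]
  mature_map$class <- cls

  structure(list(
    mature = mature, precursors = precursors, mature_map = mature_map,
    contaminants = contaminants, genome = genome, genome_loci = genome_loci,
    novel_mature = novel_mature, novel_precursors = novel_precursors,
    utr3 = utr3, term_map = term_map, planted_sites = planted_sites,
    params = list(seed = seed, n_mirna = n_mirna, n_gp2a = n_gp2a,
                  n_gp3a = n_gp3a, n_novel = n_novel)),
    class = "mir_bundle")
}

## remove unplanned occurrences of any known miRNA's 7-mer (2-8) seed site
## so that strict-mode target prediction recovers exactly the planted genes
scrub_accidental_sites <- function(utr3, mature, planted_sites) {
  sites <- setNames(revcomp(substr(unname(mature), 2L, 8L)), names(mature))
  for (pass in 1:50) {
    dirty <- FALSE
    for (g in names(utr3)) {
      all_planted <- planted_sites$position[planted_sites$gene == g]
      protected <- unique(unlist(lapply(all_planted, function(s) s + 0:6)))
      for (mi in names(sites)) {
        planted <- planted_sites$position[planted_sites$mirna == mi &
                                            planted_sites$gene == g]
        pos <- gregexpr(sites[[mi]], utr3[[g]], fixed = TRUE)[[1]]
        pos <- setdiff(as.integer(pos[pos > 0]) - 1L, planted)
        for (p0 in pos) {
          dirty <- TRUE
          ## mutate a base of the stray site that lies outside every
          ## planted site
          off <- setdiff(0:6, protected - p0)
          if (!length(off)) next  # fully shadowed by planted sites
          at <- p0 + off[ceiling(length(off) / 2)] + 1L  # 1-based
          old <- substr(utr3[[g]], at, at)
          substr(utr3[[g]], at, at) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    if (!dirty) return(utr3)
  }
  stop("could not scrub accidental seed sites")
}

#' Construct and validate a synthetic library design
#'
#' @param n_mirna_reads expected miRNA-derived reads per condition.
#' @param planted_fold_changes named numeric, true R/P count ratio per
#'   miRNA id (all > 0); unlisted miRNAs get ratio 1.
#' @param contaminant_fraction,junk_fraction,no_adapter_fraction raw-read
#'   composition; together they must leave a positive miRNA share.
#' @param adapter 3' adapter sequence ligated to every real read.
#' @param read_length raw read length before trimming (default 36).
#' @param dispersion negative-binomial dispersion of the per-miRNA counts
#'   (default 1e-4, i.e. near-Poisson: the design has no biological
#'   replicates, so only sampling noise is modeled).
#' @param windows_per_ref contaminant read windows drawn per reference
#'   sequence (bounds the number of distinct contaminant tags).
#' @param seed integer seed for [generate_libraries()].
#' @return validated design list of class `mir_design`.
#' @export
library_design <- function(n_mirna_reads = 50000,
                           planted_fold_changes = numeric(0),
                           contaminant_fraction = 0.15,
                           junk_fraction = 0.001,
                           no_adapter_fraction = 0.30,
                           adapter = .default_adapter,
                           read_length = 36L, dispersion = 1e-4,
                           windows_per_ref = 25L, seed = 1) {
  total_frac <- contaminant_fraction + junk_fraction + no_adapter_fraction
  if (any(c(contaminant_fraction, junk_fraction, no_adapter_fraction) < 0) ||
      total_frac >= 1)
    stop("fractions must be non-negative and sum to < 1")
  if (length(planted_fold_changes) && any(planted_fold_changes <= 0))
    stop("planted fold changes must be > 0")
  if (n_mirna_reads < 1) stop("n_mirna_reads must be >= 1")
  structure(list(n_mirna_reads = n_mirna_reads,
                 planted_fold_changes = planted_fold_changes,
                 contaminant_fraction = contaminant_fraction,
                 junk_fraction = junk_fraction,
                 no_adapter_fraction = no_adapter_fraction,
                 adapter = adapter, read_length = read_length,
                 dispersion = dispersion,
                 windows_per_ref = as.integer(windows_per_ref),
                 seed = seed),
            class = "mir_design")
}

## junk insert archetypes, one per rule; the insert must not contain the
## adapter seed (it would be truncated at trimming and change its fate)
junk_insert <- function(type, seed8 = substr(.default_adapter, 1, 8)) {
  repeat {
    s <- .junk_insert_raw(type)
    if (!grepl(seed8, s, fixed = TRUE)) return(s)
  }
}

.junk_insert_raw <- function(type) {
  rnd <- function(n) random_dna(1, n, reject = is_junk)
  switch(type,
         `1` = { s <- rnd(22); substr(s, 5, 5) <- "N"; substr(s, 12, 12) <- "N"; s },
         `2` = paste0(rnd(8), "AAAAAAA", rnd(7)),
         `3` = paste0(rnd(7), "CCCCCCCC", rnd(7)),
         `4` = paste0(rnd(8), "GGGGGG", rnd(8)),
         `5` = paste0(rnd(8), "TTTTTTT", rnd(7)),
         `6` = strrep("AC", 10),
         `7` = strrep("AGC", 6),
         `8` = strrep("AAGG", 5))
}

#' Generate two raw FASTQ libraries with ground truth
#'
#' Every miRNA read is its mature sequence plus the 3' adapter (truncated
#' at `read_length`); contaminant reads are clean 18-26 nt windows of the
#' contaminant references; junk reads violate one junk rule; adapter-less
#' reads are random sequences free of the adapter seed. Per-miRNA counts
#' are negative-binomial around the design means, with the planted fold
#' change applied to the R condition.
#'
#' @param bundle a [generate_references()] bundle.
#' @param design a [library_design()].
#' @return list of class `mir_libraries` with elements `reads` (list `P`,
#'   `R` of data.frames `id`, `seq`, `qual`, shuffled), `truth` (list:
#'   `reads` per-read origin table, `mirna_counts` per-miRNA true counts
#'   and fold), and `design`.
#' @export
generate_libraries <- function(bundle, design = library_design()) {
  stopifnot(inherits(bundle, "mir_bundle"), inherits(design, "mir_design"))
  if (!length(bundle$mature)) stop("bundle contains no miRNAs")
  set.seed(as.integer(design$seed))
  adapter <- design$adapter
  seed8 <- substr(adapter, 1, 8)
  rl <- design$read_length

  all_mature <- c(bundle$mature, bundle$novel_mature)
  if (any(grepl(seed8, all_mature, fixed = TRUE)))
    stop("a mature sequence contains the adapter seed; ",
         "regenerate the bundle or change the adapter")
  n_mir <- length(all_mature)
  fold <- setNames(rep(1, n_mir), names(all_mature))
  unknown <- setdiff(names(design$planted_fold_changes), names(all_mature))
  if (length(unknown))
    stop("planted fold change for unknown miRNA: ",
         paste(unknown, collapse = ", "))
  fold[names(design$planted_fold_changes)] <- design$planted_fold_changes
  mu_p <- rep(design$n_mirna_reads / n_mir, n_mir)
  mu_r <- mu_p * fold
  size <- 1 / design$dispersion

  ## contaminant window pool (shared by both libraries)
  lens <- as.integer(names(.mature_length_probs))
  pool <- lapply(bundle$contaminants, function(refs) {
    out <- character(0)
    for (ref in refs) {
      for (k in seq_len(design$windows_per_ref)) {
        repeat {
          w <- sample(lens, 1, prob = .mature_length_probs)
          s <- sample(nchar(ref) - w + 1L, 1)
          win <- substr(ref, s, s + w - 1L)
          if (!is_junk(win) && !grepl(seed8, win, fixed = TRUE)) break
        }
        out <- c(out, win)
      }
    }
    out
  })
  w_cat <- .contaminant_weights / sum(.contaminant_weights)

  make_lib <- function(lib) {
    counts <- as.integer(rnbinom(n_mir, mu = if (lib == "P") mu_p else mu_r,
                                 size = size))
    n_mir_reads <- sum(counts)
    mirna_frac <- 1 - design$contaminant_fraction - design$junk_fraction -
      design$no_adapter_fraction
    total <- round(n_mir_reads / mirna_frac)
    n_cont <- round(total * design$contaminant_fraction * w_cat)
    n_junk <- round(total * design$junk_fraction)
    n_noad <- max(0L, total - n_mir_reads - sum(n_cont) - n_junk)

    seqs <- rep(unname(all_mature), counts)
    class <- rep("mirna", n_mir_reads)
    origin <- rep(names(all_mature), counts)
    for (cat in names(pool)) {
      if (n_cont[[cat]] == 0L) next
      win <- sample(pool[[cat]], n_cont[[cat]], replace = TRUE)
      seqs <- c(seqs, win)
      class <- c(class, rep(paste0("contaminant:", cat), n_cont[[cat]]))
      origin <- c(origin, rep(cat, n_cont[[cat]]))
    }
    if (n_junk > 0L) {
      jt <- as.character(rep_len(1:8, n_junk))
      seqs <- c(seqs, vapply(jt, junk_insert, character(1), seed8 = seed8))
      class <- c(class, rep("junk", n_junk))
      origin <- c(origin, paste0("junk_rule_", jt))
    }
    reads <- substr(paste0(seqs, adapter), 1L, rl)
    if (n_noad > 0L) {
      noad <- random_dna(n_noad, rl,
                         reject = function(s) grepl(seed8, s, fixed = TRUE))
      reads <- c(reads, noad)
      class <- c(class, rep("no_adapter", n_noad))
      origin <- c(origin, rep(NA_character_, n_noad))
    }
    ord <- sample(length(reads))
    df <- data.frame(id = sprintf("%s_read%07d", lib, seq_along(reads)),
                     seq = reads[ord], qual = strrep("I", nchar(reads[ord])),
                     stringsAsFactors = FALSE)
    truth <- data.frame(id = df$id, library = lib, class = class[ord],
                        origin = origin[ord], stringsAsFactors = FALSE)
    list(reads = df, truth = truth, counts = counts)
  }

  p <- make_lib("P")
  r <- make_lib("R")
  mirna_counts <- data.frame(name = names(all_mature),
                             seq = unname(all_mature),
                             count_p = p$counts, count_r = r$counts,
                             fold = unname(fold), stringsAsFactors = FALSE)
  structure(list(reads = list(P = p$reads, R = r$reads),
                 truth = list(reads = rbind(p$truth, r$truth),
                              mirna_counts = mirna_counts),
                 design = design),
            class = "mir_libraries")
}

#' Generate a synthetic stem-loop qPCR Ct table
#'
#' Ct values satisfy ddCt = -log2(true ratio) plus Gaussian noise; the
#' reference gene Ct is constant across conditions up to the same noise.
#'
#' @param true_ratios named numeric vector of true R/P expression ratios
#'   (> 0).
#' @param n_replicates replicates per condition (default 9).
#' @param noise_sd Gaussian Ct noise standard deviation (default 0.1
#'   cycles; 0 for exact tables).
#' @param ct_base,ct_ref baseline target and reference-gene Ct levels.
#' @param seed integer seed.
#' @return data.frame `mirna`, `condition`, `replicate`, `ct_mirna`,
#'   `ct_ref`.
#' @export
generate_qpcr_table <- function(true_ratios, n_replicates = 9,
                                noise_sd = 0.1, ct_base = 28, ct_ref = 15,
                                seed = 1) {
  if (any(true_ratios <= 0)) stop("true ratios must be > 0")
  set.seed(as.integer(seed))
  rows <- list()
  for (mi in names(true_ratios)) {
    for (cond in c("P", "R")) {
      mu <- if (cond == "P") ct_base else ct_base - log2(true_ratios[[mi]])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, condition = cond, replicate = seq_len(n_replicates),
        ct_mirna = mu + rnorm(n_replicates, 0, noise_sd),
        ct_ref = ct_ref + rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a reference bundle to disk (FASTA + TSV)
#' @param bundle a [generate_references()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$mature, file.path(dir, "mature.fa"))
  write_fasta(bundle$precursors, file.path(dir, "precursors.fa"))
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_fasta(bundle$utr3, file.path(dir, "utr3.fa"))
  for (cat in names(bundle$contaminants))
    write_fasta(bundle$contaminants[[cat]],
                file.path(dir, paste0("contaminant_", cat, ".fa")))
  write_tsv(bundle$term_map, file.path(dir, "term_map.tsv"))
  write_tsv(bundle$genome_loci, file.path(dir, "genome_loci.tsv"))
  invisible(dir)
}

#' Write generated libraries to disk (FASTQ + ground-truth TSV)
#' @param libs a [generate_libraries()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_libraries <- function(libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(libs$reads$P, file.path(dir, "P.fastq"))
  write_fastq(libs$reads$R, file.path(dir, "R.fastq"))
  write_tsv(libs$truth$reads, file.path(dir, "truth_reads.tsv"))
  write_tsv(libs$truth$mirna_counts, file.path(dir, "truth_mirna_counts.tsv"))
  invisible(dir)
}
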
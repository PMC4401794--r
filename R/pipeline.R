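## End-to-end orchestration: clean -> annotate -> known/novel miRNAs ->
## differential expression -> targets/enrichment/network -> qPCR summary,
## with per-stage reports mirroring the standard small RNA-seq tables.

#' Tag length distribution of a cleaned library
#'
#' @param tags data.frame `seq`, `count` from [clean_library()].
#' @return data.frame `length`, `count`, `pct` (percent of clean reads).
#' @export
length_distribution <- function(tags) {
  lens <- nchar(tags$seq)
  agg <- tapply(tags$count, lens, sum)
  out <- data.frame(length = as.integer(names(agg)),
                    count = as.integer(agg))
  out$pct <- round(100 * out$count / sum(out$count), 2)
  out[order(out$length), , drop = FALSE]
}

#' Venn summary of detected miRNA sets
#'
#' @param set_r,set_p character vectors of miRNA names detected in the R
#'   and P libraries.
#' @return named numeric vector `r`, `p`, `shared`, `union`.
#' @export
#' @examples
#' venn_summary(c("a", "b"), c("b", "c"))
venn_summary <- function(set_r, set_p) {
  set_r <- unique(set_r); set_p <- unique(set_p)
  shared <- length(intersect(set_r, set_p))
  c(r = length(set_r), p = length(set_p), shared = shared,
    union = length(set_r) + length(set_p) - shared)
}

#' Read a reference bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return a `mir_bundle` list (without the generator's ground-truth
#'   extras).
#' @export
read_bundle <- function(dir) {
  cats <- names(.contaminant_weights)
  contaminants <- lapply(setNames(nm = cats), function(cat) {
    f <- file.path(dir, paste0("contaminant_", cat, ".fa"))
    if (!file.exists(f)) stop("missing reference for category ", cat,
                              ": ", f)
    read_fasta(f)
  })
  mature <- read_fasta(file.path(dir, "mature.fa"))
  precursors <- read_fasta(file.path(dir, "precursors.fa"))
  structure(list(
    mature = mature, precursors = precursors,
    mature_map = locate_mature(mature, precursors),
    contaminants = contaminants,
    genome = read_fasta(file.path(dir, "genome.fa")),
    utr3 = read_fasta(file.path(dir, "utr3.fa")),
    term_map = read_tsv(file.path(dir, "term_map.tsv"))),
    class = "mir_bundle")
}

#' Run the full profiling pipeline
#'
#' @param config a list with elements
#'   \describe{
#'     \item{bundle}{a `mir_bundle` (in memory or a [write_bundle()]
#'       directory path);}
#'     \item{reads_p, reads_r}{read sets: data.frames (`id`, `seq`) or
#'       FASTQ paths;}
#'     \item{qpcr}{optional Ct table (data.frame or TSV path);}
#'     \item{out_dir}{optional output directory for the report files;}
#'     \item{adapter, min_overlap, alpha, min_ne, zero, lfc, flank,
#'       max_offset, target_mode, seed}{parameters with the documented
#'       defaults (adapter is required);}
#'     \item{do_novel, do_enrichment}{stage toggles (default `TRUE`).}
#'   }
#' @return a list of class `mir_run` with every stage result (cleaning,
#'   annotation, known/novel tables, `de`, `venn`, enrichment, network,
#'   `qpcr`, `manifest`). Written files mirror the standard report tables.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    min_overlap = 8L, alpha = 0.05, min_ne = 1, zero = 0.001, lfc = 1,
    flank = 80L, max_offset = 3L, max_mismatch = 1L, target_mode = "strict",
    do_novel = TRUE, do_enrichment = TRUE, seed = NA), config)
  if (is.null(cfg$adapter)) stop("config error: adapter is required")
  bundle <- cfg$bundle
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  if (!inherits(bundle, "mir_bundle")) stop("config error: invalid bundle")
  get_reads <- function(x) if (is.character(x)) read_fastq(x) else x

  ## --- cleaning --------------------------------------------------------
  cleaned <- lapply(list(P = get_reads(cfg$reads_p),
                         R = get_reads(cfg$reads_r)),
                    clean_library, adapter = cfg$adapter,
                    min_overlap = cfg$min_overlap)
  totals <- vapply(cleaned, function(x) sum(x$tags$count), numeric(1))

  ## --- contaminant annotation -----------------------------------------
  annotated <- lapply(cleaned, function(cl)
    classify_tags(cl$tags, bundle$contaminants))

  ## --- per-tag counts across libraries (outer join on sequence) -------
  join <- merge(stats::setNames(annotated$P$retained, c("seq", "count_p")),
                stats::setNames(annotated$R$retained, c("seq", "count_r")),
                by = "seq", all = TRUE)
  join[is.na(join)] <- 0
  join <- join[order(-(join$count_p + join$count_r), join$seq), , drop = FALSE]

  ## --- known miRNA matching -------------------------------------------
  mature_map <- bundle$mature_map %||% locate_mature(bundle$mature,
                                                     bundle$precursors)
  matches <- vector("list", nrow(join))
  for (i in seq_len(nrow(join)))
    matches[[i]] <- match_known(join$seq[i], bundle$mature,
                                bundle$precursors, mature_map,
                                max_mismatch = cfg$max_mismatch,
                                max_offset = cfg$max_offset)
  matched <- !vapply(matches, is.null, logical(1))
  known <- if (any(matched)) {
    md <- do.call(rbind, matches[matched])
    md$seq <- join$seq[matched]
    md$count_p <- join$count_p[matched]
    md$count_r <- join$count_r[matched]
    agg <- lapply(split(md, md$name), function(d) data.frame(
      name = d$name[1], seq = d$seq[which.max(d$count_p + d$count_r)],
      precursor_id = d$precursor_id[1],
      count_p = sum(d$count_p), count_r = sum(d$count_r),
      stringsAsFactors = FALSE))
    kd <- do.call(rbind, agg)
    kd$group <- vapply(seq_len(nrow(kd)), function(i)
      assign_group(kd$seq[i],
                   md[md$name == kd$name[i], , drop = FALSE][1, ],
                   bundle$genome, bundle$precursors, cfg$flank),
      character(1))
    rownames(kd) <- NULL
    kd[order(kd$name), , drop = FALSE]
  } else {
    data.frame(name = character(0), seq = character(0),
               precursor_id = character(0), count_p = numeric(0),
               count_r = numeric(0), group = character(0))
  }

  ## --- novel candidates ------------------------------------------------
  novel <- if (isTRUE(cfg$do_novel)) {
    unmatched <- join[!matched, , drop = FALSE]
    nv <- find_novel_candidates(unmatched, bundle$genome, flank = cfg$flank)
    if (nrow(nv)) nv$group <- "gp4a"
    nv
  } else NULL

  ## --- differential expression ----------------------------------------
  counts <- rbind(known[, c("name", "count_p", "count_r")],
                  if (!is.null(novel) && nrow(novel))
                    novel[, c("name", "count_p", "count_r")])
  de <- de_table(counts, total_p = totals[["P"]], total_r = totals[["R"]],
                 alpha = cfg$alpha, min_ne = cfg$min_ne, zero = cfg$zero,
                 lfc = cfg$lfc)
  venn <- venn_summary(counts$name[counts$count_r > 0],
                       counts$name[counts$count_p > 0])

  ## --- targets / enrichment / network ---------------------------------
  enrichment <- network <- targets <- NULL
  if (isTRUE(cfg$do_enrichment) && !is.null(bundle$utr3) &&
      !is.null(bundle$term_map)) {
    seqs <- setNames(c(known$seq, if (!is.null(novel)) novel$seq),
                     c(known$name, if (!is.null(novel)) novel$name))
    de_sig <- de$name[!is.na(de$significant) & de$significant]
    targets <- predict_targets(seqs[intersect(de_sig, names(seqs))],
                               bundle$utr3, mode = cfg$target_mode)
    target_genes <- unique(unlist(targets))
    enrichment <- list(
      GO = enrich_terms(target_genes, bundle$term_map, "GO", cfg$alpha),
      pathway = enrich_terms(target_genes, bundle$term_map, "pathway",
                             cfg$alpha))
    network <- build_network(de, targets)
  }

  ## --- qPCR ------------------------------------------------------------
  qpcr <- NULL
  if (!is.null(cfg$qpcr)) {
    qt <- if (is.character(cfg$qpcr)) read_tsv(cfg$qpcr) else cfg$qpcr
    qpcr <- summarize_validation(qt, de)
  }

  params <- cfg[setdiff(names(cfg), c("bundle", "reads_p", "reads_r",
                                      "qpcr", "out_dir"))]
  manifest <- list(package = "mirflow",
                   version = as.character(utils::packageVersion("mirflow")),
                   seed = cfg$seed,
                   params = params[order(names(params))],
                   params_hash = digest::digest(params[order(names(params))]),
                   totals = as.list(totals))

  run <- structure(list(cleaning = cleaned, annotation = annotated,
                        known = known, novel = novel, de = de, venn = venn,
                        targets = targets, enrichment = enrichment,
                        network = network, qpcr = qpcr,
                        manifest = manifest),
                   class = "mir_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' Write the report files of a pipeline run
#' @param run a `mir_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in c("P", "R")) {
    write_tsv(run$cleaning[[lib]]$report,
              file.path(dir, sprintf("cleaning_report_%s.tsv", lib)))
    write_tsv(run$annotation[[lib]]$report,
              file.path(dir, sprintf("annotation_report_%s.tsv", lib)))
    write_tsv(length_distribution(run$cleaning[[lib]]$tags),
              file.path(dir, sprintf("length_distribution_%s.tsv", lib)))
  }
  write_tsv(run$known, file.path(dir, "known_mirnas.tsv"))
  if (!is.null(run$novel))
    write_tsv(run$novel, file.path(dir, "novel_candidates.tsv"))
  write_tsv(as.data.frame(run$de), file.path(dir, "de_table.tsv"))
  write_tsv(data.frame(set = names(run$venn), size = as.integer(run$venn)),
            file.path(dir, "venn.tsv"))
  if (!is.null(run$enrichment)) {
    write_tsv(run$enrichment$GO, file.path(dir, "enrichment_GO.tsv"))
    write_tsv(run$enrichment$pathway,
              file.path(dir, "enrichment_pathway.tsv"))
  }
  if (!is.null(run$network)) {
    write_tsv(run$network$edges, file.path(dir, "network_edges.tsv"))
    write_tsv(run$network$degree, file.path(dir, "network_degree.tsv"))
  }
  if (!is.null(run$qpcr))
    write_tsv(run$qpcr, file.path(dir, "qpcr_summary.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.mir_run <- function(x, ...) {
  cat("mirflow pipeline run\n")
  cat("  clean reads: P =", x$manifest$totals$P,
      ", R =", x$manifest$totals$R, "\n")
  cat("  known miRNAs:", nrow(x$known),
      "; novel candidates:", if (is.null(x$novel)) 0 else nrow(x$novel), "\n")
  sig <- sum(x$de$significant, na.rm = TRUE)
  cat("  DE table rows:", nrow(x$de), "(", sig, "significant )\n")
  cat("  venn: R =", x$venn[["r"]], ", P =", x$venn[["p"]],
      ", shared =", x$venn[["shared"]], ", union =", x$venn[["union"]], "\n")
  invisible(x)
}
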
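test_that("reference bundles respect their invariants", {
  b <- fix_bundle()
  ## every mature is a substring of exactly its one precursor
  for (i in seq_len(nrow(b$mature_map))) {
    hits <- vapply(b$precursors, function(p)
      grepl(b$mature[[b$mature_map$mature_id[i]]], p, fixed = TRUE),
      logical(1))
    expect_identical(sum(hits), 1L)
    expect_identical(names(b$precursors)[hits], b$mature_map$precursor_id[i])
  }
  ## recorded genome coordinates return the embedded sequence
  gl <- b$genome_loci
  for (i in seq_len(nrow(gl))) {
    s <- substr(b$genome[[gl$contig[i]]], gl$start[i], gl$end[i])
    if (gl$strand[i] == "-") s <- revcomp(s)
    if (gl$kind[i] == "precursor")
      expect_identical(s, unname(b$precursors[[gl$id[i]]]))
    if (gl$kind[i] == "novel")
      expect_identical(s, unname(b$novel_precursors[[gl$id[i]]]))
  }
  ## contigs are at least 1 kb
  expect_true(all(nchar(b$genome) >= 1000))
})

test_that("generation is deterministic, byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(generate_references(n_mirna = 6, n_gp2a = 1, n_gp3a = 1,
                                   n_novel = 1, n_genes = 10, seed = 3), d1)
  write_bundle(generate_references(n_mirna = 6, n_gp2a = 1, n_gp3a = 1,
                                   n_novel = 1, n_genes = 10, seed = 3), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("impossible generator parameters raise parameter errors", {
  expect_error(generate_references(n_mirna = 0), ">= 1")
  expect_error(generate_references(mature_lengths = 30), "18 and 26")
  expect_error(generate_references(n_mirna = 3, n_gp2a = 2, n_gp3a = 2),
               "exceed")
  expect_error(library_design(contaminant_fraction = 0.9,
                              no_adapter_fraction = 0.2), "sum")
  expect_error(library_design(planted_fold_changes = c(a = -1)), "> 0")
  expect_error(library_design(n_mirna_reads = 0), "n_mirna_reads")
})

test_that("library ground truth is self-consistent", {
  libs <- fix_libs()
  for (lib in c("P", "R")) {
    reads <- libs$reads[[lib]]
    tr <- libs$truth$reads[libs$truth$reads$library == lib, ]
    expect_identical(nrow(reads), nrow(tr))
    expect_identical(reads$id, tr$id)
    ## miRNA counts in the truth table match the per-read labels
    col <- paste0("count_", tolower(lib))
    mc <- libs$truth$mirna_counts
    for (j in seq_len(nrow(mc)))
      expect_identical(sum(tr$class == "mirna" & tr$origin == mc$name[j]),
                       mc[[col]][j])
  }
})

test_that("exactly the designed reads lack the adapter", {
  libs <- fix_libs()
  seed8 <- substr(fix_design()$adapter, 1, 8)
  for (lib in c("P", "R")) {
    reads <- libs$reads[[lib]]
    tr <- libs$truth$reads[libs$truth$reads$library == lib, ]
    has_ad <- grepl(seed8, reads$seq, fixed = TRUE)
    expect_identical(!has_ad, tr$class == "no_adapter")
  }
})

test_that("planted fold changes are recovered within sampling error", {
  ## 20 seeds, expected counts >= 1000 per miRNA: >= 95% of the planted
  ## ratios land within 10% of the truth
  b <- generate_references(n_mirna = 4, n_gp2a = 0, n_gp3a = 0, n_novel = 0,
                           n_genes = 5, contaminants_per_category = 2,
                           seed = 12)
  ok <- 0L; total <- 0L
  for (s in 1:20) {
    d <- library_design(n_mirna_reads = 8000,
                        planted_fold_changes = c(`syn-miR-002` = 4,
                                                 `syn-miR-003` = 0.5),
                        contaminant_fraction = 0, junk_fraction = 0,
                        no_adapter_fraction = 0, seed = 100 + s)
    libs <- generate_libraries(b, d)
    mc <- libs$truth$mirna_counts
    ratio <- mc$count_r / mc$count_p
    total <- total + nrow(mc)
    ok <- ok + sum(abs(ratio / mc$fold - 1) <= 0.10)
  }
  expect_gte(ok / total, 0.95)
})

test_that("qPCR generator round-trips planted ratios", {
  q <- generate_qpcr_table(c(m = 4), n_replicates = 9, noise_sd = 0.1,
                           seed = 6)
  de <- data.frame(name = "m", ratio = 4)
  out <- summarize_validation(q, de)
  expect_lt(abs(out$rel_expr - 4) / 4, 0.25)
})
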
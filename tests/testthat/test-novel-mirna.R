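test_that("the built-in folder matches a brute-force enumeration oracle", {
  ## the 12-mer from the operation contract: 4 GC pairs close a 4-nt loop
  f <- fold_sequence("GGGGAAAACCCC")
  expect_equal(f$score, oracle_fold_score("GGGGAAAACCCC"))
  expect_equal(f$score, 12L)
  expect_lt(f$dg, 0)
  ## no complementary bases -> no pairs, dG = 0
  f0 <- fold_sequence("AAAAAAAAAAAA")
  expect_equal(f0$score, 0L)
  expect_equal(f0$dg, 0)
  expect_identical(f0$structure, strrep(".", 12))
  ## random short sequences
  set.seed(31)
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(8:13, 1), TRUE),
               collapse = "")
    expect_equal(fold_sequence(s)$score, oracle_fold_score(s), info = s)
  }
  ## T/U spelling invariance
  expect_identical(fold_sequence("GGGGTTTTCCCC"),
                   fold_sequence("GGGGUUUUCCCC"))
  expect_error(fold_sequence("ACGX"), "invalid")
})

test_that("parse_dotbracket validates and inverts structures", {
  expect_identical(parse_dotbracket("((..))"),
                   c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(a)"), "invalid")
})

test_that("extract_flanks windows are clipped and strand-corrected", {
  g <- c(chr1 = random_dna_for_tests(1000, seed = 7))
  ## tag occupying 1-based 101..122 on a 1 kb contig
  w <- extract_flanks(g, "chr1", 101, 122, "+", 80)
  expect_identical(c(w$both$win_start, w$both$win_end), c(21L, 202L))
  expect_identical(w$both$seq, substr(g[[1]], 21, 202))
  expect_identical(c(w$both$mature_start, w$both$mature_end), c(81L, 102L))
  ## clipping at the contig start
  w2 <- extract_flanks(g, "chr1", 10, 31, "+", 80)
  expect_identical(w2$left$win_start, 1L)
  ## minus strand window is the reverse complement of the plus slice
  w3 <- extract_flanks(g, "chr1", 101, 122, "-", 80)
  expect_identical(w3$both$seq, revcomp(substr(g[[1]], 21, 202)))
  expect_identical(substr(w3$both$seq, w3$both$mature_start,
                          w3$both$mature_end),
                   revcomp(substr(g[[1]], 101, 122)))
  expect_error(extract_flanks(g, "chrX", 1, 10), "not found")
  expect_error(extract_flanks(g, "chr1", 990, 1005), "bounds")
})

test_that("evaluate_candidate applies every precursor filter with reasons", {
  ## a clean 49-nt hairpin fails only the length rule
  stem <- "GCGTACGTGCATGCACGTAG"   # 20 nt
  hp49 <- paste0(stem, "AACACACAC", revcomp(stem))
  expect_identical(nchar(hp49), 49L)
  ev <- evaluate_candidate(hp49, 3, 18)
  expect_false(ev$pass)
  expect_true("length<50" %in% ev$reasons)
  ## AT-only stem: GC fraction far below 0.23
  stem_at <- strrep("AT", 14)
  hp_at <- paste0(stem_at, "AACACACAC", revcomp(stem_at))
  ev_at <- evaluate_candidate(hp_at, 3, 20)
  expect_false(ev_at$pass)
  expect_true("GC<0.23" %in% ev_at$reasons)
  ## weak short stem inside a long window: dG above -17.7
  ev_dg <- evaluate_candidate(paste0("GCGC", "AAAA", "GCGC",
                                     strrep("A", 50)), 2, 3)
  expect_false(ev_dg$pass)
  expect_true(any(grepl("dG>", ev_dg$reasons)) ||
                "length<50" %in% ev_dg$reasons)
  expect_error(evaluate_candidate("ACGT", 2, 10), "window")
})

test_that("reasons are empty exactly when a candidate passes", {
  b <- fix_bundle()
  gl <- b$genome_loci[b$genome_loci$kind == "novel", ]
  for (i in seq_len(nrow(gl))) {
    m <- b$novel_mature[[gl$id[i]]]
    loc <- list(contig = gl$contig[i], start = gl$start[i], end = gl$end[i],
                strand = gl$strand[i])
    for (w in candidate_windows(b$genome, loc)[1:6]) {
      ms <- regexpr(m, w$seq, fixed = TRUE)
      if (ms < 1) next
      ev <- evaluate_candidate(w$seq, w$mature_start, w$mature_end)
      expect_identical(ev$pass, length(ev$reasons) == 0L)
      expect_identical(is.null(ev$candidate), !ev$pass)
    }
  }
})

test_that("every planted novel precursor is recovered as a candidate", {
  b <- fix_bundle()
  run <- fix_run()
  expect_identical(nrow(run$novel), length(b$novel_mature))
  expect_setequal(run$novel$seq, unname(b$novel_mature))
  expect_true(all(run$novel$length >= 18 & run$novel$length <= 26))
  expect_true(all(run$novel$gc >= 0.23 & run$novel$gc <= 0.77))
  expect_true(all(run$novel$dg >= -80.5 & run$novel$dg <= -17.7))
})

test_that("shuffled windows rarely pass the precursor filters", {
  b <- fix_bundle()
  gl <- b$genome_loci[b$genome_loci$kind == "novel", ][1, ]
  loc <- list(contig = gl$contig, start = gl$start, end = gl$end,
              strand = gl$strand)
  w <- extract_flanks(b$genome, loc$contig, loc$start, loc$end, loc$strand,
                      80)$both
  set.seed(17)
  passes <- 0L
  for (i in 1:100) {
    sh <- paste(sample(strsplit(w$seq, "")[[1]]), collapse = "")
    ev <- evaluate_candidate(sh, w$mature_start, w$mature_end)
    passes <- passes + ev$pass
  }
  expect_lt(passes / 100, 0.25)
})

test_that("PC candidate names round-trip", {
  expect_identical(pc_name("5p", 69112, 10), "PC-5p-69112_10")
  p <- parse_pc_name("PC-3p-22067_41")
  expect_identical(p, list(arm = "3p", index = 22067L, count = 41L))
  expect_error(parse_pc_name("miR-1"), "PC")
})
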
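test_that("normalize_ne is reads-per-million", {
  expect_equal(normalize_ne(50, 1e6), 50)
  expect_equal(normalize_ne(0, 123), 0)
  ## a 22-nt bin holding 51.43% of a library
  ne <- normalize_ne(2770035, 5386427)
  expect_equal(ne, 514261.7, tolerance = 1e-6)
  expect_equal(round(ne / 1e4, 2), 51.43)
  expect_error(normalize_ne(5, 0), "total")
  expect_error(normalize_ne(-1, 10), "non-negative")
})

test_that("prefilter discards doubly-low pairs and replaces zeros", {
  out <- prefilter_ne(c(0.5, 12.90, 5), c(0.8, 0, 3))
  expect_identical(out$discard, c(TRUE, FALSE, FALSE))
  expect_identical(out$ne_p[2], 0.001)
  expect_identical(out$ne_r[2], 12.90)
  expect_identical(out$ne_r[3], 5)
  expect_identical(out$ne_p[3], 3)
})

test_that("fold_change reproduces printed worked examples to 2 dp", {
  fc <- fold_change(c(2334.57, 1842.72, 28337.35), c(657.07, 16.28, 5791.48))
  expect_lt(abs(fc$ratio[1] - 3.55), 0.01)
  expect_lt(abs(fc$log2_ratio[1] - 1.83), 0.01)
  expect_lt(abs(fc$ratio[2] - 113.18), 0.011)
  expect_lt(abs(fc$log2_ratio[2] - 6.82), 0.01)
  expect_lt(abs(fc$log2_ratio[3] - 2.29), 0.01)
  ## identity
  expect_equal(fold_change(7, 7)$log2_ratio, 0)
  expect_error(fold_change(1, 0), "positive")
})

test_that("ac_pvalue agrees with the direct-evaluation oracle", {
  ## frozen closed forms
  expect_equal(ac_pvalue(0, 0, 5e6, 5e6, "less"), 0.5)
  expect_equal(ac_pvalue(0, 0, 5e6, 5e6), 1)
  expect_equal(ac_pvalue(5, 0, 5e6, 5e6, "less"), 1 / 64)
  ## brute-force grid (the full x,y <= 50 sweep runs in the acceptance suite)
  for (r in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- r * 1e6
    for (x in c(0L, 1L, 3L, 12L)) for (y in c(0L, 2L, 7L, 15L)) {
      o <- oracle_ac_tails(x, y, n1, n2)
      t <- ac_tails(x, y, n1, n2)
      expect_equal(t$c_tail, o$c_tail, tolerance = 1e-12)
      expect_equal(t$d_tail, o$d_tail, tolerance = 1e-10)
      expect_equal(t$p_two_sided, o$p, tolerance = 1e-10)
    }
  }
  ## formula symmetry: at equal depths the conditional probability is
  ## exchangeable term by term, p(y|x) = p(x|y) (the tail-based two-sided
  ## p-value is not, a known property of this conditional test)
  for (pair in list(c(9, 3), c(0, 5), c(20, 11)))
    expect_equal(mirflow:::.ac_logp(pair[2], pair[1], 1),
                 mirflow:::.ac_logp(pair[1], pair[2], 1), tolerance = 1e-12)
  ## the conditional distribution sums to 1
  for (x in c(0L, 5L, 20L)) {
    lp <- mirflow:::.ac_logp(0:2000, x, 1.3)
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
  }
  expect_error(ac_pvalue(-1, 0, 1, 1), "non-negative")
  expect_error(ac_pvalue(1.5, 0, 1, 1), "integer")
})

test_that("classify_fold partitions (0, Inf) into three classes", {
  expect_identical(classify_fold(c(113.18, 0.497, 2, 0.5, 2.001, 1)),
                   c("up", "down", "mid", "down", "up", "mid"))
  set.seed(8)
  r <- exp(runif(200, -6, 6))
  cl <- classify_fold(r)
  expect_true(all(cl %in% c("down", "mid", "up")))
  expect_identical(cl == "down", r <= 0.5)
  expect_identical(cl == "up", r > 2)
  expect_error(classify_fold(0), "positive")
})

test_that("library NE sums to one million", {
  tags <- fix_run()$cleaning$P$tags
  expect_equal(sum(normalize_ne(tags$count, sum(tags$count))), 1e6,
               tolerance = 1e-6)
})

test_that("de_table flags specific miRNAs and orders deterministically", {
  counts <- data.frame(name = c("a", "b", "only_r", "only_p", "low"),
                       count_p = c(2000L, 1600L, 0L, 1000L, 1L),
                       count_r = c(8000L, 1590L, 1200L, 0L, 1L))
  de <- de_table(counts, total_p = 2e6, total_r = 2e6)
  expect_identical(de$name[de$specific], c("only_p", "only_r"))
  expect_true(all(is.na(de$p_value[de$specific])))
  expect_true(all(is.na(de$ratio[de$specific])))
  ## low expression in both libraries is discarded
  expect_false("low" %in% de$name)
  ## ordering: by decreasing |log2 ratio|, specific rows last
  nonspec <- de$name[!de$specific]
  expect_identical(nonspec[1], "a")
  expect_identical(de$significant[de$name == "a"], TRUE)
  expect_identical(de$significant[de$name == "b"], FALSE)
})

test_that("identical libraries yield no significant calls", {
  counts <- data.frame(name = sprintf("m%02d", 1:20),
                       count_p = rep(500L, 20), count_r = rep(500L, 20))
  de <- de_table(counts, 1e5, 1e5)
  expect_identical(sum(de$significant), 0L)
  expect_true(all(de$reg_class == "mid"))
})
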
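test_that("seed_match finds reverse-complement seed sites", {
  mir <- "TGGCAGTGTCTTAGCTGGTTGT"          # positions 2-7 = GGCAGT
  utr <- paste0(strrep("T", 20), "ACTGCC", strrep("T", 20))
  hits <- seed_match(mir, utr, "2-7")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 20L)
  ## no complement -> empty
  expect_identical(nrow(seed_match(mir, strrep("T", 40), "2-7")), 0L)
  ## two sites at the correct offsets
  utr2 <- paste0("AA", "ACTGCC", strrep("G", 10), "ACTGCC", "AA")
  expect_identical(seed_match(mir, utr2, "2-7")$position, c(2L, 18L))
  ## 2-8 span uses the 7-mer and is U/T-insensitive
  utr3 <- chartr("T", "U", paste0("AA", revcomp(substr(mir, 2, 8)), "CC"))
  expect_identical(nrow(seed_match(mir, utr3, "2-8")), 1L)
  expect_error(seed_match("ACGTACG", "ACGT"), "8 nt")
})

test_that("strict-mode targets are recovered exactly and nest in loose mode", {
  b <- fix_bundle()
  strict <- predict_targets(b$mature, b$utr3, "strict")
  loose <- predict_targets(b$mature, b$utr3, "loose")
  for (mi in names(b$mature)) {
    planted <- sort(b$planted_sites$gene[b$planted_sites$mirna == mi])
    expect_identical(strict[[mi]], planted, info = mi)
    expect_true(all(strict[[mi]] %in% loose[[mi]]))
  }
  ## a miRNA with no sites anywhere has no targets
  empty <- predict_targets(c(nv = "TGGCAGTGTCTTAGCTGGTTGT"),
                           c(u1 = strrep("T", 50)), "strict")
  expect_identical(empty$nv, character(0))
  expect_warning(predict_targets(c(short = "ACGT"), b$utr3), "skipping")
})

test_that("hypergeom_enrich equals exhaustive enumeration", {
  ## closed-form worked example: all 4 annotated genes among 5 draws of 10
  expect_equal(hypergeom_enrich(10, 5, 4, 4), 6 / 252, tolerance = 1e-12)
  expect_identical(hypergeom_enrich(10, 5, 4, 0), 1)
  expect_identical(hypergeom_enrich(10, 5, 10, 3), 1)
  ## enumeration over all subsets for small N (full N <= 12 sweep in the
  ## acceptance suite)
  for (N in c(5L, 7L, 9L)) {
    for (n in c(2L, N %/% 2, N - 1L)) {
      subsets <- utils::combn(N, n)
      for (M in c(1L, 3L, N)) {
        for (m in 0:min(n, M)) {
          hits <- colSums(subsets <= M) >= m
          expect_equal(hypergeom_enrich(N, n, M, m), mean(hits),
                       tolerance = 1e-12,
                       info = sprintf("N=%d n=%d M=%d m=%d", N, n, M, m))
        }
      }
    }
  }
  ## monotonicity in m
  p <- hypergeom_enrich(rep(40, 5), 10, 15, 1:5)
  expect_true(all(diff(p) <= 1e-12))
  expect_error(hypergeom_enrich(10, 11, 5, 2), "invalid")
})

test_that("enrich_terms ranks a planted term first", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  term_map <- data.frame(gene = rep(genes, each = 2), namespace = "GO",
                         term = "GO:BASE", stringsAsFactors = FALSE)
  term_map$term[c(TRUE, FALSE)] <-
    sample(sprintf("GO:%04d", 1:10), 200, replace = TRUE)
  ## plant: targets are mostly the carriers of GO:PLANT
  carriers <- genes[1:20]
  term_map <- rbind(term_map, data.frame(gene = carriers, namespace = "GO",
                                         term = "GO:PLANT"))
  targets <- c(carriers[1:18], genes[150:151])
  res <- enrich_terms(targets, term_map, "GO")
  expect_identical(res$term[1], "GO:PLANT")
  expect_lt(res$p[1], 0.05)
  ## a term covering every background gene is never enriched
  expect_identical(res$p[res$term == "GO:BASE"], 1)
  expect_error(enrich_terms(targets, term_map, "missing_ns"), "background")
})

test_that("build_network weights edges and counts degrees", {
  de <- data.frame(name = c("m1", "m2"), log2_ratio = c(2, -3))
  targets <- list(m1 = c("gA", "gB"), m2 = c("gB"))
  net <- build_network(de, targets)
  expect_identical(dim(net$adjacency), c(2L, 2L))
  expect_identical(net$adjacency["m1", "gA"], 2)
  expect_identical(net$adjacency["m2", "gB"], 3)
  expect_identical(net$degree$degree[net$degree$node == "gB"], 2L)
  ## binary weighting
  netb <- build_network(de, targets, weights = "binary")
  expect_true(all(netb$adjacency %in% c(0, 1)))
  ## no targets -> zero matrix
  net0 <- build_network(de, list(m1 = character(0), m2 = character(0)))
  expect_identical(nrow(net0$edges), 0L)
  ## a hub gene targeted by 8 miRNAs tops the degree ranking
  de8 <- data.frame(name = sprintf("m%d", 1:8), log2_ratio = rep(1.5, 8))
  t8 <- setNames(lapply(1:8, function(i) c("hub", sprintf("g%d", i))),
                 de8$name)
  net8 <- build_network(de8, t8)
  expect_identical(net8$degree$node[1], "hub")
  expect_identical(net8$degree$degree[1], 8L)
  ## degree of a gene equals the number of miRNAs targeting it
  expect_identical(net8$degree$degree[net8$degree$node == "g3"], 1L)
})
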
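test_that("variant_name encodes offsets and substitutions canonically", {
  expect_identical(variant_name("oar-miR-10b", 1, -1), "oar-miR-10b_L+1R-1")
  expect_identical(variant_name("x", 0, 0), "x")
  expect_identical(
    variant_name("oar-miR-10a", 0, 1,
                 data.frame(pos = 12, ref = "T", obs = "A")),
    "oar-miR-10a_R+1_1ss12TA")
  expect_identical(variant_name("m", 0, -3), "m_R-3")
  expect_identical(variant_name("m", -2, 0), "m_L-2")
})

test_that("variant names round-trip through the parser", {
  set.seed(5)
  for (i in 1:50) {
    off5 <- sample(-3:3, 1); off3 <- sample(-3:3, 1)
    subs <- if (runif(1) < 0.5)
      data.frame(pos = sample(1:22, 1), ref = sample(c("A", "C", "G", "T"), 1),
                 obs = sample(c("A", "C", "G", "T"), 1),
                 stringsAsFactors = FALSE)
    else NULL
    nm <- variant_name("syn-miR-001", off5, off3, subs)
    p <- parse_variant_name(nm)
    expect_identical(p$base, "syn-miR-001")
    expect_identical(p$off5, as.integer(off5))
    expect_identical(p$off3, as.integer(off3))
    if (is.null(subs)) expect_null(p$subs)
    else expect_identical(p$subs, subs)
  }
})

test_that("match_known recovers identity, end shifts and substitutions", {
  b <- fix_bundle()
  mm <- b$mature_map
  id <- mm$mature_id[1]
  mat <- b$mature[[id]]
  prec <- b$precursors[[mm$precursor_id[1]]]
  ## exact mature -> offsets 0, no substitution, bare name
  hit <- match_known(mat, b$mature, b$precursors, mm)
  expect_identical(hit$mature_id, id)
  expect_identical(c(hit$off5, hit$off3), c(0L, 0L))
  expect_identical(hit$name, id)
  ## one extra 3' base plus a substitution at position 12
  ext <- substr(prec, mm$start[1], mm$end[1] + 1L)
  ref_base <- substr(ext, 12, 12)
  obs_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  substr(ext, 12, 12) <- obs_base
  hit2 <- match_known(ext, b$mature, b$precursors, mm)
  expect_identical(hit2$off3, 1L)
  expect_identical(hit2$off5, 0L)
  expect_identical(hit2$sub_pos, 12L)
  expect_identical(hit2$name,
                   sprintf("%s_R+1_1ss12%s%s", id, ref_base, obs_base))
  ## two substitutions -> no match
  two <- mat
  substr(two, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(two, 3, 3))[1]
  substr(two, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(two, 9, 9))[1]
  expect_null(match_known(two, b$mature, b$precursors, mm))
  ## offsets beyond the bound -> no match
  far <- substr(prec, mm$start[1] - 4L, mm$end[1])
  if (mm$start[1] > 4L)
    expect_null(match_known(far, b$mature, b$precursors, mm, max_offset = 3))
})

test_that("assign_group reflects genome and hairpin evidence", {
  b <- fix_bundle()
  mm <- b$mature_map
  for (cls in c("gp1b", "gp2a", "gp3a")) {
    i <- which(mm$class == cls)[1]
    tag <- b$mature[[mm$mature_id[i]]]
    hit <- match_known(tag, b$mature, b$precursors, mm)
    expect_identical(assign_group(tag, hit, b$genome, b$precursors), cls,
                     info = cls)
  }
  ## unmatched tag embedded in a genomic hairpin locus -> gp4a
  nov <- b$novel_mature[[1]]
  expect_identical(assign_group(nov, NULL, b$genome, b$precursors), "gp4a")
  ## unmatched tag mapping nowhere -> dropped
  expect_true(is.na(assign_group(strrep("ACGT", 5), NULL, b$genome,
                                 b$precursors)))
})

test_that("groups partition the reported miRNAs and planted knowns are exact", {
  run <- fix_run()
  b <- fix_bundle()
  expect_true(all(run$known$group %in% c("gp1b", "gp2a", "gp3a")))
  expect_false(any(is.na(run$known$group)))
  ## every planted known miRNA is recovered under its bare reference name
  expect_setequal(run$known$name, names(b$mature))
  expect_identical(run$known$group,
                   b$mature_map$class[match(run$known$name,
                                            b$mature_map$mature_id)])
})
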
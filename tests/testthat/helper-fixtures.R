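## Shared fixtures, built once per test run. Sizes are kept small so the
## whole suite stays fast; the acceptance tests build their own larger
## instances.

.fixtures <- new.env(parent = emptyenv())

fix_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generate_references(
      n_mirna = 12, n_gp2a = 2, n_gp3a = 2, n_novel = 3, n_contigs = 3,
      contaminants_per_category = 4, n_genes = 30, targets_per_mirna = 3,
      seed = 42)
  .fixtures$bundle
}

fix_design <- function() {
  library_design(
    n_mirna_reads = 9000,
    planted_fold_changes = c(`syn-miR-003` = 4, `syn-miR-007` = 0.25),
    seed = 11)
}

fix_libs <- function() {
  if (is.null(.fixtures$libs))
    .fixtures$libs <- generate_libraries(fix_bundle(), fix_design())
  .fixtures$libs
}

fix_run <- function() {
  if (is.null(.fixtures$run)) {
    libs <- fix_libs()
    .fixtures$run <- run_pipeline(list(
      bundle = fix_bundle(), reads_p = libs$reads$P, reads_r = libs$reads$R,
      adapter = fix_design()$adapter, seed = 1))
  }
  .fixtures$run
}

## deterministic random sequence for constructing references in tests
random_dna_for_tests <- function(len, seed = 99) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## independent brute-force folding oracle: recursive enumeration of the
## maximum pair-weight over all nested structures (min loop 3)
oracle_fold_score <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    duo <- paste0(sort(c(a, b)), collapse = "")
    switch(duo, "CG" = 3, "AU" = 2, "GU" = 1, 0)
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - 4)) {
      wk <- w(ch[k], ch[j])
      if (wk == 0) next
      left <- if (k > i) rec(i, k - 1) else 0
      best <- max(best, left + rec(k + 1, j - 1) + wk)
    }
    best
  }
  rec(1, length(ch))
}

## independent AC-test oracle: terms of the conditional distribution built
## by direct recursion p(0|x) = (1+r)^-(x+1),
## p(y+1|x) = p(y|x) * r * (x+y+1) / ((y+1)(1+r)) -- no log-space machinery
oracle_ac_terms <- function(x, r, y_max) {
  p <- numeric(y_max + 1L)
  p[1] <- (1 + r)^-(x + 1)
  for (y in seq_len(y_max))
    p[y + 1L] <- p[y] * r * (x + y) / (y * (1 + r))
  p
}

oracle_ac_tails <- function(x, y, n1, n2, upper_cap = 4000L) {
  r <- n2 / n1
  p <- oracle_ac_terms(x, r, upper_cap)
  ctail <- sum(p[seq_len(y + 1L)])
  dtail <- sum(p[(y + 1L):(upper_cap + 1L)])
  list(c_tail = ctail, d_tail = dtail,
       p = min(1, 2 * min(ctail, dtail)))
}
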
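## Two-library differential expression.
##
## Counts are normalized to reads per million of each library's clean
## reads. The significance test is the exact conditional two-library count
## test (Audic-Claverie): given x counts of a tag among N1 reads in one
## library, the count y among N2 reads in the other follows
##   p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)).
## Tail sums give the lower tail C(y' <= y | x) and upper tail
## D(y' >= y | x); the reported two-sided p is min(1, 2 min(C, D)).
## Raw integer counts feed the test (the factorials require integers);
## normalized expression feeds the fold change and expression filters.

#' Reads-per-million normalized expression
#'
#' NE = count / total * 1e6.
#'
#' @param count non-negative count(s).
#' @param total total clean reads of the library (> 0).
#' @return normalized expression, same length as `count`.
#' @export
normalize_ne <- function(count, total) {
  if (any(total <= 0)) stop("total clean reads must be > 0")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total * 1e6
}

#' Zero-replacement and low-expression prefilter
#'
#' Pairs with NE below `min_ne` in both libraries are discarded; otherwise
#' any zero is replaced by `zero` so a ratio can be formed.
#'
#' @param ne_r,ne_p normalized expressions.
#' @param min_ne discard threshold (default 1).
#' @param zero replacement for exact zeros (default 0.001).
#' @return data.frame `ne_r`, `ne_p`, `discard`.
#' @export
#' @examples
#' prefilter_ne(c(0.5, 12.90, 5), c(0.8, 0, 3))
prefilter_ne <- function(ne_r, ne_p, min_ne = 1, zero = 0.001) {
  discard <- ne_r < min_ne & ne_p < min_ne
  data.frame(ne_r = ifelse(ne_r == 0, zero, ne_r),
             ne_p = ifelse(ne_p == 0, zero, ne_p),
             discard = discard)
}

#' Fold change between the two libraries
#'
#' @param ne_r,ne_p normalized expressions (P value must be positive; the
#'   prefilter guarantees this).
#' @return data.frame `ratio` (= ne_r / ne_p) and `log2_ratio`.
#' @export
fold_change <- function(ne_r, ne_p) {
  if (any(ne_p <= 0)) stop("ne_p must be positive (run prefilter_ne first)")
  ratio <- ne_r / ne_p
  data.frame(ratio = ratio, log2_ratio = log2(ratio))
}

## log p(y|x) for the AC conditional distribution, vectorized over y
.ac_logp <- function(y, x, r) {
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Exact conditional tails of the two-library count test
#'
#' @param x,y observed counts in the conditioning and tested library.
#' @param n1,n2 total clean reads of the respective libraries.
#' @return data.frame `c_tail` (P(y' <= y | x)), `d_tail` (P(y' >= y | x))
#'   and `p_two_sided` = min(1, 2 min(C, D)).
#' @export
ac_tails <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stop("x and y must be non-negative integers")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  c_tail <- d_tail <- numeric(n)
  for (i in seq_len(n)) {
    r <- n2[i] / n1[i]
    lp <- .ac_logp(0:y[i], x[i], r)
    ctail <- sum(exp(lp))
    c_tail[i] <- min(1, ctail)
    d_tail[i] <- min(1, 1 - ctail + exp(lp[length(lp)]))
  }
  p <- pmin(1, 2 * pmin(c_tail, d_tail))
  data.frame(c_tail = c_tail, d_tail = d_tail, p_two_sided = p)
}

#' Exact two-library count test p-value
#'
#' @inheritParams ac_tails
#' @param alternative `"two.sided"` (default, 2 min(C, D) capped at 1),
#'   `"less"` (lower tail C) or `"greater"` (upper tail D).
#' @return p-value(s) in \[0, 1\].
#' @export
#' @examples
#' ac_pvalue(5, 0, 1e6, 1e6)               # lower tail 1/64
#' ac_pvalue(0, 0, 1e6, 1e6)               # p = 1
ac_pvalue <- function(x, y, n1, n2, alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  t <- ac_tails(x, y, n1, n2)
  switch(alternative,
         two.sided = t$p_two_sided,
         less = t$c_tail,
         greater = t$d_tail)
}

#' Fold-change regulation class
#'
#' down: ratio <= 1/2; mid: 1/2 < ratio <= 2; up: ratio > 2.
#'
#' @param ratio positive fold change(s) (R over P).
#' @return character vector over `{"down", "mid", "up"}`.
#' @export
classify_fold <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  ifelse(ratio <= 0.5, "down", ifelse(ratio > 2, "up", "mid"))
}

#' Differential expression table for two libraries
#'
#' Applies normalize, prefilter, fold change, the exact count test and
#' fold classification per miRNA. miRNAs detected in exactly one library
#' (and passing the expression filter) are flagged `specific` and reported
#' without fold change or p-value. Rows are ordered by decreasing
#' |log2 ratio| then name, with specific rows last.
#'
#' @param counts data.frame with columns `name`, `count_p`, `count_r`
#'   (missing miRNAs in either library enter with zero counts).
#' @param total_p,total_r total clean reads of the P and R libraries.
#' @param alpha significance level (default 0.05).
#' @param min_ne,zero prefilter parameters, see [prefilter_ne()].
#' @param lfc |log2 ratio| threshold for significance (default 1).
#' @return data.frame of class `mir_de` with columns `name`, `count_p`,
#'   `count_r`, `ne_p`, `ne_r`, `ratio`, `log2_ratio`, `p_value`, `c_tail`,
#'   `d_tail`, `reg_class`, `significant`, `specific`.
#' @export
de_table <- function(counts, total_p, total_r, alpha = 0.05, min_ne = 1,
                     zero = 0.001, lfc = 1) {
  stopifnot(all(c("name", "count_p", "count_r") %in% names(counts)))
  ne_p <- normalize_ne(counts$count_p, total_p)
  ne_r <- normalize_ne(counts$count_r, total_r)
  pf <- prefilter_ne(ne_r, ne_p, min_ne = min_ne, zero = zero)
  keep <- !pf$discard
  df <- data.frame(name = counts$name, count_p = counts$count_p,
                   count_r = counts$count_r, ne_p = ne_p, ne_r = ne_r,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  specific <- xor(df$count_p == 0, df$count_r == 0)

  ratio <- log2_ratio <- p_value <- c_tail <- d_tail <- rep(NA_real_, nrow(df))
  reg_class <- rep(NA_character_, nrow(df))
  idx <- which(!specific)
  if (length(idx)) {
    fc <- fold_change(df$ne_r[idx], df$ne_p[idx])
    ratio[idx] <- fc$ratio
    log2_ratio[idx] <- fc$log2_ratio
    ## x conditions on the P library count, y is tested in R (N1 = P, N2 = R)
    tails <- ac_tails(df$count_p[idx], df$count_r[idx], total_p, total_r)
    c_tail[idx] <- tails$c_tail
    d_tail[idx] <- tails$d_tail
    p_value[idx] <- tails$p_two_sided
    reg_class[idx] <- classify_fold(fc$ratio)
  }
  significant <- !specific & p_value < alpha & abs(log2_ratio) > lfc
  out <- cbind(df, data.frame(ratio = ratio, log2_ratio = log2_ratio,
                              p_value = p_value, c_tail = c_tail,
                              d_tail = d_tail, reg_class = reg_class,
                              significant = significant, specific = specific,
                              stringsAsFactors = FALSE))
  ord <- order(out$specific, -abs(ifelse(is.na(out$log2_ratio), -Inf,
                                         out$log2_ratio)), out$name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mir_de", class(out))
  out
}
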
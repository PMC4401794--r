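## Stem-loop RT-qPCR relative quantification by 2^-ddCt.
##
## ddCt = (Ct_miRNA - Ct_ref)_R - (Ct_miRNA - Ct_ref)_P; the baseline
## condition evaluates to 1 by construction. Replicate aggregation averages
## the per-condition delta-Ct before forming ddCt; per-replicate relative
## expressions (against the mean baseline delta-Ct) supply the spread.

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_mirna_r,ct_ref_r target and reference-gene Ct in condition R.
#' @param ct_mirna_p,ct_ref_p target and reference-gene Ct in condition P
#'   (the baseline).
#' @return relative expression 2^-ddCt (vectorized).
#' @export
#' @examples
#' ddct(24, 15, 25, 15)   # R amplifies one cycle earlier -> 2
ddct <- function(ct_mirna_r, ct_ref_r, ct_mirna_p, ct_ref_p) {
  stopifnot(is.finite(ct_mirna_r), is.finite(ct_ref_r),
            is.finite(ct_mirna_p), is.finite(ct_ref_p))
  dd <- (ct_mirna_r - ct_ref_r) - (ct_mirna_p - ct_ref_p)
  2^(-dd)
}

#' Summarize qPCR validation against sequencing DE calls
#'
#' @param qpcr data.frame with columns `mirna`, `condition` (`"P"`/`"R"`),
#'   `replicate`, `ct_mirna`, `ct_ref`.
#' @param de a [de_table()] result (columns `name`, `ratio`).
#' @param baseline baseline condition (default `"P"`).
#' @return data.frame per miRNA: `mirna`, `rel_expr` (2^-ddCt from mean
#'   delta-Ct), `rel_mean`, `rel_sd` (over per-replicate relative
#'   expressions), `direction_qpcr`, `direction_seq` and `concordance` in
#'   `{"concordant", "discordant", "flat", "not_compared"}`.
#' @export
summarize_validation <- function(qpcr, de, baseline = "P") {
  stopifnot(all(c("mirna", "condition", "replicate", "ct_mirna", "ct_ref")
                %in% names(qpcr)))
  if (any(qpcr$ct_mirna < 10 | qpcr$ct_mirna > 40, na.rm = TRUE))
    warning("Ct values outside the typical 10-40 range")
  other <- setdiff(unique(qpcr$condition), baseline)
  stopifnot(length(other) == 1L)
  seq_ratio <- setNames(de$ratio, de$name)
  eps <- 1e-9
  rows <- lapply(sort(unique(qpcr$mirna)), function(mi) {
    sub <- qpcr[qpcr$mirna == mi, , drop = FALSE]
    dct <- sub$ct_mirna - sub$ct_ref
    dct_b <- dct[sub$condition == baseline]
    dct_o <- dct[sub$condition == other]
    if (!length(dct_b) || !length(dct_o))
      return(data.frame(mirna = mi, rel_expr = NA_real_, rel_mean = NA_real_,
                        rel_sd = NA_real_, direction_qpcr = NA_character_,
                        direction_seq = NA_character_,
                        concordance = "not_compared",
                        stringsAsFactors = FALSE))
    rel <- 2^(-(mean(dct_o) - mean(dct_b)))
    rel_i <- 2^(-(dct_o - mean(dct_b)))
    dir_q <- if (abs(log2(rel)) < eps) "flat" else if (rel > 1) "up" else "down"
    sr <- if (mi %in% names(seq_ratio)) seq_ratio[[mi]] else NA_real_
    if (is.na(sr)) {
      dir_s <- NA_character_; conc <- "not_compared"
    } else {
      dir_s <- if (abs(log2(sr)) < eps) "flat" else if (sr > 1) "up" else "down"
      conc <- if (dir_q == "flat" || dir_s == "flat") "flat"
      else if (dir_q == dir_s) "concordant" else "discordant"
    }
    data.frame(mirna = mi, rel_expr = rel, rel_mean = mean(rel_i),
               rel_sd = if (length(rel_i) > 1) sd(rel_i) else NA_real_,
               direction_qpcr = dir_q, direction_seq = dir_s,
               concordance = conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
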
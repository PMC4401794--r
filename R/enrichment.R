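## Seed-match target prediction, hypergeometric term enrichment and the
## miRNA-gene bipartite network.
##
## Animal miRNA targeting is dominated by Watson-Crick pairing of the seed
## (miRNA positions 2-7 or 2-8 from the 5' end) to the 3'UTR. The built-in
## predictor reports exact UTR occurrences of the seed's reverse
## complement; "strict" mode requires both the 6-mer (2-7) and 7-mer (2-8)
## spans to match somewhere in the UTR (emulating the usual two-program
## intersection rule), "loose" mode requires either.

#' Seed-match sites of a miRNA in a UTR
#'
#' @param mirna_seq miRNA sequence (>= 8 nt; T/U equivalent).
#' @param utr_seq 3'UTR sequence.
#' @param span seed span: `"2-7"` (6-mer) or `"2-8"` (7-mer).
#' @return data.frame `position` (0-based site start in the UTR) and
#'   `span`; zero rows when there is no site.
#' @export
seed_match <- function(mirna_seq, utr_seq, span = c("2-7", "2-8")) {
  span <- match.arg(span)
  if (nchar(mirna_seq) < 8L) stop("miRNA must be at least 8 nt")
  m <- chartr("Uu", "Tt", toupper(mirna_seq))
  u <- chartr("Uu", "Tt", toupper(utr_seq))
  seed <- substr(m, 2L, if (span == "2-7") 7L else 8L)
  site <- revcomp(seed)
  pos <- gregexpr(site, u, fixed = TRUE)[[1]]
  if (pos[1] == -1L)
    return(data.frame(position = integer(0), span = character(0)))
  data.frame(position = as.integer(pos) - 1L, span = span,
             stringsAsFactors = FALSE)
}

#' Predict target genes for a set of miRNAs
#'
#' @param mirna_seqs named character vector (name = miRNA id).
#' @param utrs named character vector of 3'UTR sequences (name = gene id).
#' @param mode `"strict"` (both the 2-7 and 2-8 seed spans must match,
#'   default) or `"loose"` (either).
#' @return named list: for each miRNA, the character vector of target gene
#'   ids (sorted). miRNAs with missing/short sequences are skipped with a
#'   warning.
#' @export
predict_targets <- function(mirna_seqs, utrs, mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  out <- list()
  for (id in names(mirna_seqs)) {
    s <- mirna_seqs[[id]]
    if (is.na(s) || nchar(s) < 8L) {
      warning("skipping miRNA without usable sequence: ", id)
      next
    }
    hit6 <- vapply(utrs, function(u) nrow(seed_match(s, u, "2-7")) > 0,
                   logical(1))
    hit7 <- vapply(utrs, function(u) nrow(seed_match(s, u, "2-8")) > 0,
                   logical(1))
    hits <- if (mode == "strict") hit6 & hit7 else hit6 | hit7
    out[[id]] <- sort(names(utrs)[hits])
  }
  out
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P = 1 - sum_{i=0}^{m-1} C(M, i) C(N-M, n-i) / C(N, n), the probability
#' of drawing at least `m` annotated genes when sampling `n` of `N`
#' background genes of which `M` carry the term. Computed in log space.
#'
#' @param N annotated genes in the background.
#' @param n annotated genes among the targets.
#' @param M background genes carrying the term.
#' @param m target genes carrying the term.
#' @return probability in \[0, 1\]; vectorized over equal-length inputs.
#' @export
#' @examples
#' hypergeom_enrich(10, 5, 4, 4)  # 6/252
hypergeom_enrich <- function(N, n, M, m) {
  k <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, k); n <- rep_len(n, k)
  M <- rep_len(M, k); m <- rep_len(m, k)
  if (any(m > pmin(n, M)) || any(n > N) || any(M > N) || any(m < 0))
    stop("invalid hypergeometric configuration (need 0 <= m <= min(n, M), n <= N, M <= N)")
  vapply(seq_len(k), function(j) {
    if (m[j] == 0) return(1)
    i <- 0:(m[j] - 1)
    terms <- exp(lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
                   lchoose(N[j], n[j]))
    min(1, max(0, 1 - sum(terms)))
  }, numeric(1))
}

#' Term enrichment of a target gene set
#'
#' @param target_genes character vector of target gene ids.
#' @param term_map data.frame with columns `gene`, `namespace`, `term`.
#' @param namespace namespace to test (e.g. `"GO"` or `"pathway"`).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame `term`, `N`, `n`, `M`, `m`, `p`, `significant`, one
#'   row per term with `m >= 1`, sorted by ascending p then term id.
#' @export
enrich_terms <- function(target_genes, term_map, namespace = "GO",
                         alpha = 0.05) {
  tm <- term_map[term_map$namespace == namespace, , drop = FALSE]
  if (!nrow(tm)) stop("empty background for namespace ", namespace)
  background <- unique(tm$gene)
  N <- length(background)
  targets <- intersect(unique(target_genes), background)
  n <- length(targets)
  terms <- sort(unique(tm$term))
  rows <- lapply(terms, function(tt) {
    genes_t <- unique(tm$gene[tm$term == tt])
    M <- length(genes_t)
    m <- length(intersect(genes_t, targets))
    if (m < 1L) return(NULL)
    data.frame(term = tt, N = N, n = n, M = M, m = m,
               p = hypergeom_enrich(N, n, M, m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), N = integer(0), n = integer(0),
                      M = integer(0), m = integer(0), p = numeric(0),
                      significant = logical(0)))
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-gene bipartite network from DE results and predicted targets
#'
#' The adjacency weight a\[i, j\] is |log2 ratio| of miRNA i when gene j is
#' a predicted target (configurable to binary), 0 otherwise.
#'
#' @param de a [de_table()] result (needs `name` and `log2_ratio`).
#' @param targets named list from [predict_targets()], keyed by DE miRNA.
#' @param weights `"log2"` (default) or `"binary"`.
#' @return list with `adjacency` (miRNA x gene matrix), `edges`
#'   (data.frame `mirna`, `gene`, `weight`) and `degree` (data.frame
#'   `node`, `type`, `degree`, genes sorted by decreasing degree).
#' @export
build_network <- function(de, targets, weights = c("log2", "binary")) {
  weights <- match.arg(weights)
  mirnas <- intersect(de$name, names(targets))
  genes <- sort(unique(as.character(unlist(targets[mirnas]))))
  adj <- matrix(0, nrow = length(mirnas), ncol = length(genes),
                dimnames = list(mirnas, genes))
  lfc <- setNames(abs(de$log2_ratio), de$name)
  for (mi in mirnas) {
    tg <- targets[[mi]]
    if (!length(tg)) next
    w <- if (weights == "log2") lfc[[mi]] else 1
    if (is.na(w)) w <- 1   # specific miRNAs have no fold change
    adj[mi, tg] <- w
  }
  edges <- which(adj > 0, arr.ind = TRUE)
  edges_df <- if (nrow(edges)) {
    data.frame(mirna = rownames(adj)[edges[, 1]],
               gene = colnames(adj)[edges[, 2]],
               weight = adj[edges], stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(0), gene = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  }
  edges_df <- edges_df[order(edges_df$mirna, edges_df$gene), , drop = FALSE]
  rownames(edges_df) <- NULL
  deg_g <- colSums(adj > 0)
  deg_m <- rowSums(adj > 0)
  degree <- rbind(
    data.frame(node = genes, type = rep("gene", length(genes)),
               degree = as.integer(deg_g), stringsAsFactors = FALSE),
    data.frame(node = mirnas, type = rep("miRNA", length(mirnas)),
               degree = as.integer(deg_m), stringsAsFactors = FALSE))
  degree <- degree[order(-degree$degree, degree$node), , drop = FALSE]
  rownames(degree) <- NULL
  list(adjacency = adj, edges = edges_df, degree = degree)
}
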
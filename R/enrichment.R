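#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated: `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Evaluated via
#' the survival form of [stats::phyper()], which works in log space
#' internally, so tiny tail probabilities are computed stably.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
#' @examples
#' hypergeometric_p(4, K = 5, n = 4, N = 10)  # 5/210
hypergeometric_p <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n))) {
    stop("k must lie in [0, min(K, n)]")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Supported methods: `"holm"` (the Bonferroni step-down procedure),
#' `"bh"` (Benjamini-Hochberg step-up FDR), and `"bonferroni"`. Output is in
#' input order. Backed by [stats::p.adjust()].
#'
#' @param ps numeric vector of p-values in \[0, 1\].
#' @param method one of `"holm"`, `"bh"`, `"bonferroni"`.
#' @return adjusted p-values, same length and order as `ps`.
#' @export
adjust_pvalues <- function(ps, method = c("holm", "bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(ps)) || any(ps < 0) || any(ps > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(ps, method = c(holm = "holm", bh = "BH",
                          bonferroni = "bonferroni")[[method]])
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation term for over-representation in the query set with
#' the hypergeometric upper-tail test, then corrects across terms. Query
#' genes outside the universe are dropped with a message; terms with no
#' overlap (k = 0) carry no evidence and are omitted before correction.
#'
#' @param genes character vector of query gene symbols.
#' @param annotation named list of term gene sets, as from [read_gmt()].
#' @param universe background gene set; default: all genes appearing in the
#'   annotation.
#' @param method multiple-testing correction, see [adjust_pvalues()];
#'   default `"holm"`.
#' @param alpha significance level for the `significant` flag (on adjusted
#'   p, strict `<`); default 0.05.
#' @return data.frame sorted by adjusted then raw p (ties by term id), with
#'   columns term, k, K, n, N, p, p_adj, significant, genes
#'   (comma-separated overlap members).
#' @export
enrich <- function(genes, annotation, universe = NULL,
                   method = c("holm", "bh", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  genes <- toupper(unique(genes))
  if (is.null(universe)) universe <- unique(unlist(annotation))
  universe <- toupper(unique(universe))
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    message("dropped ", length(outside), " query gene(s) outside the universe")
    genes <- intersect(genes, universe)
  }
  n <- length(genes)
  N <- length(universe)
  rows <- lapply(names(annotation), function(tm) {
    term_genes <- intersect(toupper(annotation[[tm]]), universe)
    overlap <- intersect(genes, term_genes)
    k <- length(overlap)
    if (k == 0) return(NULL)
    K <- length(term_genes)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeometric_p(k, K, n, N),
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  rows$p_adj <- adjust_pvalues(rows$p, method)
  rows$significant <- rows$p_adj < alpha
  rows <- rows[order(rows$p_adj, rows$p, rows$term),
               c("term", "k", "K", "n", "N", "p", "p_adj", "significant",
                 "genes")]
  rownames(rows) <- NULL
  rows
}
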
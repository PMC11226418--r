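#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more annotated genes in a selection of
#' `n` genes drawn without replacement from a universe of `N` genes of which
#' `K` carry the annotation:
#' `p = sum_{i >= k} C(K,i) C(N-K,n-i) / C(N,n)`,
#' evaluated in log space for numerical stability.
#'
#' @param k Observed overlap (selected genes with the term).
#' @param n Number of selected genes (annotated ones only).
#' @param K Universe genes with the term.
#' @param N Universe size.
#' @return The upper-tail probability (exactly 1 when `k = 0`).
#' @export
hypergeom_upper <- function(k, n, K, N) {
  stopifnot(length(k) == 1, k >= 0, n >= 0, K >= 0, n <= N, K <= N,
            k <= min(n, K))
  if (k == 0) return(1)
  i <- k:min(n, K)
  lo <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(lo)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: order the p-values, multiply by
#' `m / rank`, enforce monotonicity by a cumulative minimum from the largest
#' p downwards, cap at 1, and restore the input order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[ro]
}

#' GO term over-representation analysis
#'
#' Tests every GO term of at least `min_term_size` universe genes for
#' over-representation in a selected gene list, using the upper-tail
#' hypergeometric test with Benjamini-Hochberg correction. The universe is
#' the set of genes with at least one annotation in `gene2go`; selected genes
#' without any annotation are dropped from `n` with a message.
#'
#' @param selected Character vector of selected gene ids.
#' @param gene2go Named list mapping gene id to GO term ids (see
#'   [read_gene2go()]).
#' @param min_term_size Minimum number of universe genes per tested term.
#' @param alpha Significance threshold applied to the adjusted p-value.
#' @return data.frame of class `go_enrichment`, one row per tested term,
#'   sorted by raw p: `term`, `k`, `n`, `K`, `N`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
enrich <- function(selected, gene2go, min_term_size = 3, alpha = 0.05) {
  universe <- names(gene2go)
  N <- length(universe)
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0))
  class(empty) <- c("go_enrichment", "data.frame")
  if (length(selected) == 0) {
    warning("empty selected gene set")
    return(empty)
  }
  selected <- unique(selected)
  annotated <- selected[selected %in% universe]
  dropped <- length(selected) - length(annotated)
  if (dropped > 0)
    message(dropped, " selected gene(s) without annotation dropped")
  n <- length(annotated)

  term2gene <- split(rep(names(gene2go), lengths(gene2go)),
                     unlist(gene2go))
  term2gene <- term2gene[lengths(term2gene) >= min_term_size]
  if (length(term2gene) == 0 || n == 0) return(empty)

  rows <- lapply(names(term2gene), function(t) {
    K <- length(term2gene[[t]])
    k <- sum(annotated %in% term2gene[[t]])
    data.frame(term = t, k = k, n = n, K = K, N = N,
               p = hypergeom_upper(k, n, K, N))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("go_enrichment", "data.frame")
  out
}
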
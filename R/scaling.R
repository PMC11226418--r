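#' Ordinary least squares of mutation count on chromosome length
#'
#' Fits `count ~ length` by OLS and reports slope (mutations per Mb),
#' intercept, R-squared and the two-sided p-value of the slope t-statistic
#' (n - 2 degrees of freedom). A constant response is reported as R-squared
#' 0 with p = 1 (no length signal); constant lengths are an error (the slope
#' is undefined).
#'
#' @param counts Numeric vector of per-chromosome mutation counts (or any
#'   per-chromosome statistic).
#' @param lengths_mb Chromosome lengths in Mb.
#' @return Object of class `length_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n` and the underlying `lm` fit (`model`, absent
#'   for the degenerate constant-response case).
#' @export
fit_count_vs_length <- function(counts, lengths_mb) {
  n <- length(counts)
  if (n < 3) stop("need at least 3 chromosomes")
  if (length(lengths_mb) != n) stop("counts and lengths differ in length")
  if (any(lengths_mb <= 0)) stop("lengths must be positive")
  if (stats::var(lengths_mb) == 0)
    stop("zero variance in lengths: slope undefined")
  if (stats::var(counts) == 0) {
    fit <- list(slope = 0, intercept = mean(counts), r_squared = 0,
                p_value = 1, n = n, model = NULL)
    class(fit) <- "length_fit"
    return(fit)
  }
  model <- stats::lm(counts ~ lengths_mb)
  s <- summary(model)
  fit <- list(slope = unname(coef(model)[2]),
              intercept = unname(coef(model)[1]),
              r_squared = s$r.squared,
              p_value = unname(s$coefficients[2, 4]),
              n = n, model = model)
  class(fit) <- "length_fit"
  fit
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf(
    "<length_fit> n=%d  slope=%.4g /Mb  intercept=%.4g  R2=%.3f  p=%.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
coef.length_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Average-linkage dendrogram of a per-chromosome statistic
#'
#' Agglomerative clustering on the absolute differences of a scalar value
#' per chromosome, with average (UPGMA) linkage and a documented
#' deterministic tie rule: among minimum-distance cluster pairs, the pair
#' containing the earliest original label (then the earliest second label)
#' is merged first. With all values equal this yields a caterpillar tree in
#' label order.
#'
#' @param values Named numeric vector (names = chromosome labels).
#' @return Object of class `c("chrom_dendrogram", "hclust")`, usable with
#'   [stats::as.dendrogram()], [plot()] etc.
#' @export
build_dendrogram <- function(values) {
  labels <- names(values)
  n <- length(values)
  if (n < 2) stop("need at least two labels")
  if (is.null(labels) || anyDuplicated(labels)) stop("values must have unique names")
  d <- abs(outer(values, values, "-"))

  # active cluster bookkeeping: id < 0 singleton, > 0 merge row
  id <- -seq_len(n)
  size <- rep(1L, n)
  rank <- seq_len(n)           # earliest original label index per cluster
  dist <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      i <- act[ii]; j <- act[jj]
      cand <- c(dist[i, j], sort(c(rank[i], rank[j])))
      if (is.null(best) ||
          cand[1] < best[1] - 1e-12 ||
          (abs(cand[1] - best[1]) <= 1e-12 &&
           (cand[2] < best[2] || (cand[2] == best[2] && cand[3] < best[3])))) {
        best <- cand; bi <- i; bj <- j
      }
    }
    # order children: earlier-rank cluster on the left
    left <- if (rank[bi] <= rank[bj]) bi else bj
    right <- if (left == bi) bj else bi
    merge[step, ] <- c(id[left], id[right])
    height[step] <- dist[bi, bj]
    # Lance-Williams update for average linkage
    for (k in which(active)) {
      if (k == bi || k == bj) next
      dist[bi, k] <- dist[k, bi] <-
        (size[bi] * dist[k, bi] + size[bj] * dist[k, bj]) /
        (size[bi] + size[bj])
    }
    size[bi] <- size[bi] + size[bj]
    rank[bi] <- min(rank[bi], rank[bj])
    id[bi] <- step
    active[bj] <- FALSE
  }

  obj <- list(merge = merge, height = height,
              order = merge_order(merge),
              labels = labels, method = "average",
              dist.method = "absolute difference",
              call = match.call())
  class(obj) <- c("chrom_dendrogram", "hclust")
  obj
}

# leaf order by left-first traversal of the merge matrix
merge_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Entanglement between two dendrograms
#'
#' Both trees must carry the same label set. Each label gets its rank in
#' each tree's leaf order; entanglement is
#' `sum(|rank1 - rank2|^L) / W` where `W` is the same sum under a fully
#' reversed ranking. It is 0 for identical leaf orders and 1 for exactly
#' reversed orders.
#'
#' @param d1,d2 `chrom_dendrogram` (or `hclust`) objects over the same
#'   labels.
#' @param L Norm exponent (default 1.5, the conventional tanglegram
#'   default).
#' @return Object of class `entanglement_score`: list with `value`, `L`,
#'   `untangled`.
#' @export
entanglement <- function(d1, d2, L = 1.5) {
  structure(list(value = entanglement_value(leaf_order_labels(d1),
                                            leaf_order_labels(d2), L),
                 L = L, untangled = FALSE),
            class = "entanglement_score")
}

#' Leaf labels of a dendrogram in plotting order
#' @param d A `chrom_dendrogram`/`hclust` object.
#' @return Character vector of labels, left to right.
#' @export
leaf_labels <- function(d) {
  if (!is.null(d$labels)) d$labels[d$order] else as.character(d$order)
}

leaf_order_labels <- leaf_labels

entanglement_value <- function(labs1, labs2, L) {
  if (!setequal(labs1, labs2) || length(labs1) != length(labs2))
    stop("dendrograms must share the same label set")
  n <- length(labs1)
  r1 <- seq_len(n)
  r2 <- match(labs1, labs2)
  worst <- sum(abs(r1 - rev(r1))^L)
  if (worst == 0) return(0)
  sum(abs(r1 - r2)^L) / worst
}

#' @export
print.entanglement_score <- function(x, ...) {
  cat(sprintf("<entanglement> %.4f (L = %g%s)\n", x$value, x$L,
              if (x$untangled) ", after untangling" else ""))
  invisible(x)
}

#' Greedy untangling of a tanglegram
#'
#' Repeatedly tries flipping the children of every internal node of both
#' trees, keeping any flip that strictly lowers the entanglement, until no
#' single flip improves it. Entanglement never increases; the procedure is
#' idempotent at a local optimum.
#'
#' @inheritParams entanglement
#' @return List with rotated `d1`, `d2` and the resulting
#'   `entanglement_score` (with `untangled = TRUE`).
#' @export
untangle <- function(d1, d2, L = 1.5) {
  best <- entanglement_value(leaf_order_labels(d1), leaf_order_labels(d2), L)
  repeat {
    improved <- FALSE
    for (t in 1:2) {
      tree <- if (t == 1) d1 else d2
      for (node in seq_len(nrow(tree$merge))) {
        cand <- flip_node(tree, node)
        v <- if (t == 1)
          entanglement_value(leaf_order_labels(cand), leaf_order_labels(d2), L)
        else
          entanglement_value(leaf_order_labels(d1), leaf_order_labels(cand), L)
        if (v < best - 1e-12) {
          best <- v
          if (t == 1) d1 <- cand else d2 <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(d1 = d1, d2 = d2,
       score = structure(list(value = best, L = L, untangled = TRUE),
                         class = "entanglement_score"))
}

flip_node <- function(tree, node) {
  tree$merge[node, ] <- tree$merge[node, 2:1]
  tree$order <- merge_order(tree$merge)
  tree
}

#' Export a dendrogram to Newick format
#'
#' @param d A `chrom_dendrogram`/`hclust` object.
#' @return A single Newick string (with branch lengths derived from merge
#'   heights).
#' @export
to_newick <- function(d) {
  h <- c(rep(0, length(d$labels)), d$height)  # leaf heights are 0
  node_str <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%g", d$labels[-node], parent_h))
    sprintf("(%s,%s):%g",
            node_str(d$merge[node, 1], d$height[node]),
            node_str(d$merge[node, 2], d$height[node]),
            parent_h - d$height[node])
  }
  root <- nrow(d$merge)
  sprintf("(%s,%s);",
          node_str(d$merge[root, 1], d$height[root]),
          node_str(d$merge[root, 2], d$height[root]))
}

#' Plot a tanglegram of two dendrograms
#'
#' Draws the two trees facing each other with connector lines between
#' matching labels.
#'
#' @inheritParams entanglement
#' @param main Plot title.
#' @return Invisibly, the entanglement score shown in the subtitle.
#' @export
plot_tanglegram <- function(d1, d2, L = 1.5, main = "") {
  l1 <- leaf_order_labels(d1); l2 <- leaf_order_labels(d2)
  n <- length(l1)
  e <- entanglement(d1, d2, L)
  graphics::plot(NULL, xlim = c(0, 3), ylim = c(0.5, n + 0.5), axes = FALSE,
                 xlab = "", ylab = "", main = main,
                 sub = sprintf("entanglement = %.3f", e$value))
  graphics::text(rep(0.9, n), seq_len(n), l1, adj = 1, cex = 0.8)
  graphics::text(rep(2.1, n), seq_len(n), l2, adj = 0, cex = 0.8)
  graphics::segments(1, seq_len(n), 2, match(l1, l2), col = "red3")
  invisible(e)
}
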
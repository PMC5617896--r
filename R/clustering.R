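#' Deterministic complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of gene rows by Euclidean distance with
#' complete (maximum) linkage — the parameters used for the expression
#' heatmaps. Ties are broken deterministically: among pairs at the minimal
#' distance, the pair whose member clusters have the lexicographically
#' smallest (min original leaf index, max original leaf index) is merged,
#' where a cluster is represented by the smallest original row index it
#' contains. The result is independent of row order up to leaf labels.
#'
#' @param x Wide tibble (`gene_id` + numeric columns), or a numeric matrix
#'   with rownames.
#' @param k Optional number of flat clusters to cut into.
#' @return An object of class `c("fr_hclust", "hclust")` — usable with
#'   [stats::cutree()], `plot()` etc. — with a `merges` tibble attached
#'   (`node_a`, `node_b`, `height`; negative = leaf, positive = earlier
#'   merge) and, when `k` is given, a `clusters` tibble (`gene_id`,
#'   `cluster`).
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"), v = c(0, 1, 10))
#' hclust_complete(m)$height  # 1, 10
hclust_complete <- function(x, k = NULL) {
  if (is.data.frame(x)) {
    labels <- as.character(x$gene_id)
    mat <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  } else {
    mat <- as.matrix(x)
    labels <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  n <- nrow(mat)
  if (n < 2) abort("Need at least 2 rows to cluster.")
  if (anyNA(mat)) abort("Matrix contains missing values.")

  D <- as.matrix(dist(mat))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  rep_idx <- seq_len(n)          # smallest original leaf index per cluster
  node_id <- -seq_len(n)         # hclust convention: leaves negative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    sub <- D
    sub[!active, ] <- Inf
    sub[, !active] <- Inf
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(pmin(rep_idx[cand[, 1]], rep_idx[cand[, 2]]),
                 pmax(rep_idx[cand[, 1]], rep_idx[cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ## record in hclust order (smaller node id first per stats::hclust
    ## convention: singletons before clusters, else by value)
    a <- node_id[i]; b <- node_id[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    height[step] <- m
    ## complete linkage: distance to the union is the max
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    rep_idx[i] <- min(rep_idx[i], rep_idx[j])
    node_id[i] <- step
  }

  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(merge[node, 1]), order_leaves(merge[node, 2]))
  }
  hc <- structure(
    list(merge = merge, height = height, order = order_leaves(n - 1),
         labels = labels, method = "complete",
         dist.method = "euclidean",
         call = match.call(),
         merges = tibble(node_a = merge[, 1], node_b = merge[, 2],
                         height = height)),
    class = c("fr_hclust", "hclust"))
  if (!is.null(k)) {
    cl <- cutree(hc, k = k)
    hc$clusters <- tibble(gene_id = labels, cluster = unname(cl))
  }
  hc
}

#' Cophenetic distances of a clustering
#'
#' Height at which each pair of leaves is first joined; for complete
#' linkage this is at least the pairwise Euclidean distance.
#'
#' @param hc `fr_hclust` (or any `hclust`) object.
#' @return A `dist` object.
#' @export
cophenetic_distances <- function(hc) stats::cophenetic(hc)

#' @method tidy fr_hclust
#' @export
tidy.fr_hclust <- function(x, ...) {
  out <- x$merges
  if (!is.null(x$clusters)) attr(out, "clusters") <- x$clusters
  out
}

#' @method glance fr_hclust
#' @export
glance.fr_hclust <- function(x, ...) {
  tibble(n_leaves = length(x$labels), n_merges = length(x$height),
         max_height = max(x$height))
}
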
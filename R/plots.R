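#' Volcano plot of differential-expression calls
#'
#' @param de Called DE tibble from [adjust_and_call()] /
#'   [de_all_contrasts()].
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2FC,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(down = "#2166AC", ns = "grey70",
                                            up = "#B2182B")) +
    ggplot2::facet_grid(timepoint ~ genotype) +
    ggplot2::labs(x = "log2 fold change (mutant / reference)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the dependency Venn regions
#'
#' @param venn Tibble from [venn_partition()].
#' @return A ggplot.
#' @export
plot_venn_counts <- function(venn) {
  ggplot2::ggplot(venn, ggplot2::aes(x = .data$region, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#4D9221") +
    ggplot2::labs(x = "dependency region", y = "genes") +
    ggplot2::theme_minimal()
}

#' Clustered expression heatmap
#'
#' Averaged-log expression values with gene rows in dendrogram order.
#'
#' @param mean_log Wide tibble from [mean_log_matrix()].
#' @param hc Optional `fr_hclust` for row ordering (computed if `NULL`).
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(mean_log, hc = NULL) {
  if (is.null(hc) && nrow(mean_log) >= 2) hc <- hclust_complete(mean_log)
  ord <- if (is.null(hc)) mean_log$gene_id else hc$labels[hc$order]
  long <- tidyr::pivot_longer(mean_log, -"gene_id",
                              names_to = "condition", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = ord)
  long$condition <- factor(long$condition,
                           levels = setdiff(names(mean_log), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log(FPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Simple motif plot (per-position letter probabilities)
#'
#' Stacked-bar rendition of a PWM, letter height proportional to
#' probability scaled by the position's information content.
#'
#' @param pwm `fr_pwm`, or a `width x 4` probability matrix.
#' @return A ggplot.
#' @export
plot_motif <- function(pwm) {
  probs <- if (inherits(pwm, "fr_pwm")) pwm$probs else as.matrix(pwm)
  colnames(probs) <- DNA4
  ic <- apply(probs, 1, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(position = seq_len(nrow(probs))),
                     as_tibble(probs)),
    -"position", names_to = "letter", values_to = "prob")
  df$height <- df$prob * ic[df$position]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$letter)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position", y = "bits", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot fr_zoops
#' @export
autoplot.fr_zoops <- function(object, rank = 1, ...) {
  plot_motif(zoops_pwm(object, rank))
}

#' @method autoplot fr_hclust
#' @export
autoplot.fr_hclust <- function(object, ...) {
  ## dendrogram as segments, leaves at integer x in plot order
  n <- length(object$labels)
  leaf_x <- setNames(seq_len(n), object$order)
  pos <- function(node) {
    if (node < 0) c(leaf_x[[as.character(-node)]], 0) else node_xy[node, ]
  }
  node_xy <- matrix(0, n - 1, 2)
  segs <- list()
  for (i in seq_len(n - 1)) {
    a <- pos(object$merge[i, 1]); b <- pos(object$merge[i, 2])
    h <- object$height[i]
    node_xy[i, ] <- c((a[1] + b[1]) / 2, h)
    segs[[i]] <- tibble(x = c(a[1], a[1], b[1]),
                        xend = c(a[1], b[1], b[1]),
                        y = c(a[2], h, h), yend = c(h, h, b[2]))
  }
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[object$order]) +
    ggplot2::labs(x = NULL, y = "height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
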
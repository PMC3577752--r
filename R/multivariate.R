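#' Double mean-centering of an expression matrix
#'
#' Subtracts gene (row) means, then array (column) means, one pass in that
#' fixed order; the order is part of the contract so downstream clustering
#' is reproducible.
#'
#' @param mat Numeric matrix without missing values.
#' @return Centered matrix of the same shape.
#' @export
mean_center <- function(mat) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  out <- mat - rowMeans(mat)
  sweep(out, 2, colMeans(out))
}

#' Hierarchical clustering of samples
#'
#' Clusters the samples (columns) of an expression matrix under Euclidean
#' distance or cosine dissimilarity (1 minus cosine similarity over the
#' gene vectors), with a configurable linkage (average by default, the
#' common choice for expression heatmaps).
#'
#' @param mat Numeric matrix, genes x samples.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param linkage Any method accepted by [stats::hclust()].
#' @return A `cluster_result`: the `hclust` tree, leaf order as sample
#'   ids, and the metric/linkage names.
#' @export
hierarchical_cluster <- function(mat, metric = c("euclidean", "cosine"),
                                 linkage = "average") {
  metric <- match.arg(metric)
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (metric == "euclidean") {
    d <- stats::dist(t(mat), method = "euclidean")
  } else {
    norms <- sqrt(colSums(mat^2))
    if (any(norms == 0)) {
      stop("zero-norm sample under cosine dissimilarity: ",
           paste(colnames(mat)[norms == 0], collapse = ", "), call. = FALSE)
    }
    cs <- crossprod(mat) / tcrossprod(norms)
    d <- stats::as.dist(1 - cs)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 metric = metric, linkage = linkage),
            class = "cluster_result")
}

#' Export a sample dendrogram as a Newick string
#' @param x A `cluster_result`.
#' @return Newick text (single line).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s, %s linkage) of %d samples\n",
              x$metric, x$linkage, length(x$leaf_order)))
  cat("leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' Plot a sample dendrogram
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @export
autoplot.cluster_result <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(2 * n - 1)                    # node -> x coordinate
  xpos[seq_len(n)] <- order(hc$order)           # leaves at their display slot
  segs <- vector("list", nrow(hc$merge))
  node_x <- function(k) if (k < 0) xpos[-k] else xpos[n + k]
  node_h <- function(k) if (k < 0) 0 else hc$height[k]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b); h <- hc$height[i]
    xpos[n + i] <- (xa + xb) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_h(a), h, h), yend = c(h, h, node_h(b))
    )
  }
  seg <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = sprintf("%s height", object$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Variance explained by principal components over samples
#'
#' PCA of the samples (columns) after gene-wise centering; returns the
#' fraction of total variance carried by each of the leading components.
#'
#' @param mat Numeric matrix, genes x samples, no missing values.
#' @param n_components Number of leading components to report (default 3).
#' @return A `pca_result` tibble with columns `component`,
#'   `variance_fraction`; all fractions (full rank) sum to 1.
#' @export
pca_variance_explained <- function(mat, n_components = 3L) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L, nrow(mat) >= 1L)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- v / sum(v)
  if (n_components > length(frac)) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    n_components, length(frac)), call. = FALSE)
    n_components <- length(frac)
  }
  out <- tibble::tibble(component = seq_len(n_components),
                        variance_fraction = frac[seq_len(n_components)])
  attr(out, "all_fractions") <- frac
  class(out) <- c("pca_result", class(out))
  out
}

#' Scree plot of variance fractions
#' @param object A `pca_result`.
#' @param ... Unused.
#' @export
autoplot.pca_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$component),
                                       y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Differentially expressed genes between two sample subgroups
#'
#' Per-gene two-sided pooled-variance t-test between two sample id lists
#' (the C4d-positive versus C4d-negative comparison in the rejection
#' setting), reporting genes below the raw p threshold. No multiple-testing
#' correction by default, matching the raw p < 0.05 usage of such
#' confirmatory subgroup scans; Benjamini-Hochberg is available via
#' `adjust`.
#'
#' @param mat Expression matrix, genes x samples.
#' @param group_a_ids,group_b_ids Sample id vectors, each of length >= 2.
#' @param p_threshold Raw (or adjusted, if `adjust`) p cutoff.
#' @param adjust Apply Benjamini-Hochberg before thresholding.
#' @return Tibble `gene`, `t`, `p` (and `p_adj` when `adjust`), one row per
#'   passing gene, ordered by p.
#' @export
subgroup_de_genes <- function(mat, group_a_ids, group_b_ids,
                              p_threshold = 0.05, adjust = FALSE) {
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L) {
    stop("both subgroups need at least two samples", call. = FALSE)
  }
  XA <- mat[, group_a_ids, drop = FALSE]
  XB <- mat[, group_b_ids, drop = FALSE]
  n1 <- ncol(XA); n2 <- ncol(XB)
  m1 <- rowMeans(XA); m2 <- rowMeans(XB)
  ss <- rowSums((XA - m1)^2) + rowSums((XB - m2)^2)
  se <- sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se == 0, 0, (m1 - m2) / se)
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  tab <- tibble::tibble(gene = rownames(mat), t = unname(t_stat), p = unname(p))
  if (adjust) {
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    tab <- dplyr::filter(tab, .data$p_adj < p_threshold)
  } else {
    tab <- dplyr::filter(tab, .data$p < p_threshold)
  }
  dplyr::arrange(tab, .data$p)
}
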
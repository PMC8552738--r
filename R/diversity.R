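# Alpha diversity, group tests, Bray-Curtis, PCoA, UPGMA.

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the numbers of
#' singleton and doubleton features. Reduces to observed richness when there
#' are no singletons.
#'
#' @param counts Non-negative integer vector of feature counts for one sample.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) rlang::abort("chao1 undefined for an all-zero sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over nonzero proportions. Natural log by default,
#' the ecology convention.
#'
#' @param counts Non-negative vector with at least one positive entry.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) rlang::abort("shannon undefined for an all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity table
#'
#' @param tbl Feature-table tibble of counts (typically rarefied).
#' @param base Log base passed to [shannon()].
#' @return Tibble with `sample_id`, `observed`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(tbl, base = exp(1)) {
  m <- feature_matrix(tbl)
  tibble::tibble(
    sample_id = colnames(m),
    observed = unname(colSums(m > 0)),
    chao1 = unname(apply(m, 2, chao1)),
    shannon = unname(apply(m, 2, shannon, base = base))
  )
}

#' Kruskal-Wallis H test on a diversity (or any numeric) column
#'
#' Tie-corrected H with a chi-square approximate p on k-1 degrees of freedom,
#' via [stats::kruskal.test()]. When every value is identical the statistic is
#' degenerate (all ties); the test then reports H = 0 and p = 1 rather than
#' NaN.
#'
#' @param data Data frame with the value and grouping columns.
#' @param value Name of the numeric column (string).
#' @param group Name of the grouping column (string).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(data, value, group) {
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) rlang::abort("kruskal_wallis needs at least 2 groups")
  if (length(unique(x)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L,
                          p_value = 1, n_groups = nlevels(g)))
  }
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n_groups = nlevels(g))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = 1 - 2 sum(min(u_i, v_i)) / (sum u_i + sum v_i)`; 0 for identical
#' samples, 1 for disjoint ones.
#'
#' @param tbl Feature-table tibble (counts or relative abundances).
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(tbl) {
  m <- feature_matrix(tbl)
  if (ncol(m) < 2L) rlang::abort("bray_curtis needs at least 2 samples")
  if (any(colSums(m) == 0)) {
    rlang::abort(paste0("Bray-Curtis undefined for all-zero sample(s): ",
                        paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres -d^2/2 and eigendecomposes it. Axes with positive
#' eigenvalues are kept; explained variance is each positive eigenvalue over
#' the sum of positive eigenvalues (negative eigenvalues, which semimetric
#' dissimilarities such as Bray-Curtis can produce, are excluded from the
#' denominator).
#'
#' @param d A `dist` object over samples.
#' @return Object of class `cavenet_pcoa`: list with `scores` (tibble,
#'   `sample_id` + `PCo1...`), `eigenvalues`, `explained` (percentages).
#' @export
pcoa_ordination <- function(d) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) rlang::abort("pcoa needs a dist over at least 3 samples")
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  ev <- sc$eig
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  scores <- tibble::as_tibble(coords)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = labels(d) %||% as.character(seq_len(n))), scores)
  structure(list(
    scores = scores,
    eigenvalues = ev[pos],
    explained = 100 * ev[pos] / sum(ev[pos])
  ), class = "cavenet_pcoa")
}

#' @export
print.cavenet_pcoa <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$scores), "samples,",
      length(x$eigenvalues), "positive axes\n")
  cat(sprintf("  PCo1 %.2f%%, PCo2 %.2f%% of variance\n",
              x$explained[1], if (length(x$explained) > 1) x$explained[2] else NA))
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param x A `cavenet_pcoa` object.
#' @param ... Unused.
#' @method tidy cavenet_pcoa
#' @export
tidy.cavenet_pcoa <- function(x, ...) x$scores

#' @rdname pcoa_ordination
#' @method glance cavenet_pcoa
#' @export
glance.cavenet_pcoa <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_axes = length(x$eigenvalues),
                 explained_1 = x$explained[1],
                 explained_2 = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' @rdname pcoa_ordination
#' @param object A `cavenet_pcoa` object.
#' @param colour_by Optional vector (length = samples) to colour points by.
#' @method autoplot cavenet_pcoa
#' @export
autoplot.cavenet_pcoa <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df$group <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2)) +
    ggplot2::geom_point(if (is.null(colour_by)) NULL else ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.2f%%)", object$explained[1]),
      y = sprintf("PCo2 (%.2f%%)", object$explained[2])) +
    ggplot2::theme_minimal()
  p
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates by unweighted average linkage. Merge heights are reported as
#' half the between-cluster average distance (molecular-clock convention), so
#' the leaf-to-leaf path length in the exported tree equals the cophenetic
#' distance.
#'
#' @param d A `dist` object.
#' @return Object of class `cavenet_upgma`: list with `hclust`, `phylo`
#'   (an [ape] tree with half-distance branch lengths), `leaf_ids`.
#' @export
upgma <- function(d) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) rlang::abort("upgma needs a dist over at least 2 samples")
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 leaf_ids = hc$labels), class = "cavenet_upgma")
}

#' @rdname upgma
#' @param x A `cavenet_upgma` object.
#' @param ... Unused.
#' @return For `tidy()`: a merge table with half-distance heights; negative
#'   entries in `cluster_a`/`cluster_b` are leaves (singletons), positive ones
#'   earlier merges, following [stats::hclust()] conventions.
#' @method tidy cavenet_upgma
#' @export
tidy.cavenet_upgma <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(step = seq_along(hc$height),
                 cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
                 height = hc$height / 2)
}

#' Write a dendrogram as newick
#' @param x A `cavenet_upgma` object.
#' @param path Output path.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "cavenet_upgma"))
  ape::write.tree(x$phylo, file = path)
  invisible(path)
}

#' Cophenetic distances implied by a UPGMA tree
#' @param x A `cavenet_upgma` object.
#' @return A `dist` of leaf-to-leaf path lengths.
#' @export
cophenetic_distances <- function(x) {
  stopifnot(inherits(x, "cavenet_upgma"))
  stats::cophenetic(x$hclust)
}
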
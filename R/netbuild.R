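# Signed cooccurrence network: Spearman screen, thresholding, topology,
# Louvain modules.

#' All-pairs Spearman correlation screen over features
#'
#' Mid-rank Spearman rho for every unordered feature pair, two-sided p from the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 df, and
#' Benjamini-Hochberg q over all pairs jointly. Constant features (zero
#' variance across samples) cannot be ranked informatively; their pairs are
#' excluded and the features reported in the `dropped` attribute.
#'
#' @param tbl Feature-table tibble (already rarefied/filtered).
#' @return Tibble of pairs `feature_a < feature_b` with `rho`, `p_value`, `q`;
#'   attribute `dropped` lists constant features; attribute `n_samples`.
#' @export
pairwise_spearman <- function(tbl) {
  m <- feature_matrix(tbl)
  n <- ncol(m)
  if (n < 4L) rlang::abort("pairwise_spearman needs at least 4 samples")
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  dropped <- rownames(m)[const]
  m <- m[!const, , drop = FALSE]
  if (nrow(m) < 2L) rlang::abort("fewer than 2 non-constant features")
  ranks <- t(apply(m, 1, rank))            # mid-ranks for ties
  rho <- stats::cor(t(ranks))              # Pearson on ranks = Spearman
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- tibble::tibble(
    feature_a = rownames(m)[idx[, 1]],
    feature_b = rownames(m)[idx[, 2]],
    rho = r,
    p_value = p,
    q = stats::p.adjust(p, method = "BH")
  )
  attr(out, "dropped") <- dropped
  attr(out, "n_samples") <- n
  out
}

#' Build a signed cooccurrence network from a correlation screen
#'
#' An edge joins two features when the correlation is strong
#' (`|rho| >= rho_min`) and significant (BH-adjusted `q < alpha` by default).
#' The strength threshold is applied to the absolute value so that strong
#' negative associations are kept as negative edges; the sign is stored as an
#' edge attribute. Nodes are edge endpoints only: features that pass the
#' filter but gain no edge do not appear in the graph.
#'
#' @param screen Pair tibble from [pairwise_spearman()].
#' @param rho_min Correlation-strength threshold (default 0.7).
#' @param alpha Significance level (default 0.05).
#' @param taxonomy Optional taxonomy tibble ([make_taxonomy()]); labels are
#'   attached to nodes.
#' @param use_adjusted Threshold the BH-adjusted `q` (default) or the raw p.
#' @return Object of class `cavenet_network`: list with `graph` (igraph,
#'   undirected, edge attributes `rho`, `weight` = |rho|, `sign`), `edges`
#'   tibble, `nodes` tibble, and the thresholds used.
#' @export
build_network <- function(screen, rho_min = 0.7, alpha = 0.05,
                          taxonomy = NULL, use_adjusted = TRUE) {
  stopifnot(rho_min >= 0, rho_min <= 1, alpha > 0, alpha <= 1)
  pcol <- if (use_adjusted) screen$q else screen$p_value
  keep <- abs(screen$rho) >= rho_min & pcol < alpha
  edges <- screen[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    near <- screen |>
      dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
      utils::head(5)
    rlang::abort(paste0(
      "no edge passes |rho| >= ", rho_min, " and ",
      if (use_adjusted) "q" else "p", " < ", alpha,
      "; strongest pairs: ",
      paste(sprintf("%s-%s rho=%.2f q=%.3g", near$feature_a, near$feature_b,
                    near$rho, near$q), collapse = "; ")))
  }
  edges <- edges |> dplyr::mutate(sign = ifelse(.data$rho > 0, "+", "-"),
                                  weight = abs(.data$rho))
  g <- igraph::graph_from_data_frame(
    edges[, c("feature_a", "feature_b", "rho", "q", "sign", "weight")],
    directed = FALSE)
  nodes <- tibble::tibble(feature_id = igraph::V(g)$name)
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes, taxonomy[, c("feature_id", "label")],
                              by = "feature_id")
    nodes$label[is.na(nodes$label)] <- "unclassified"
    igraph::V(g)$label <- nodes$label
  }
  structure(list(graph = g, edges = edges, nodes = nodes,
                 rho_min = rho_min, alpha = alpha, use_adjusted = use_adjusted),
            class = "cavenet_network")
}

#' Construct a `cavenet_network` directly from an edge tibble
#'
#' Mostly for tests and toy examples: builds the network object from explicit
#' edges without a correlation screen.
#'
#' @param edges Tibble with `feature_a`, `feature_b` and optionally `rho`
#'   (default 1).
#' @param taxonomy Optional taxonomy tibble.
#' @return A `cavenet_network`.
#' @export
network_from_edges <- function(edges, taxonomy = NULL) {
  if (!"rho" %in% names(edges)) edges$rho <- 1
  edges$q <- 0
  edges$sign <- ifelse(edges$rho > 0, "+", "-")
  edges$weight <- abs(edges$rho)
  g <- igraph::graph_from_data_frame(
    edges[, c("feature_a", "feature_b", "rho", "q", "sign", "weight")],
    directed = FALSE)
  nodes <- tibble::tibble(feature_id = igraph::V(g)$name)
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes, taxonomy[, c("feature_id", "label")],
                              by = "feature_id")
    nodes$label[is.na(nodes$label)] <- "unclassified"
    igraph::V(g)$label <- nodes$label
  }
  structure(list(graph = g, edges = tibble::as_tibble(edges), nodes = nodes,
                 rho_min = NA_real_, alpha = NA_real_, use_adjusted = TRUE),
            class = "cavenet_network")
}

#' @export
print.cavenet_network <- function(x, ...) {
  g <- x$graph
  cat("Signed cooccurrence network:", igraph::vcount(g), "nodes,",
      igraph::ecount(g), "edges (",
      sprintf("%.2f%% positive", 100 * mean(igraph::E(g)$sign == "+")), ")\n")
  invisible(x)
}

#' @rdname build_network
#' @param x A `cavenet_network`.
#' @param ... Unused.
#' @return For `tidy()`: the edge tibble.
#' @method tidy cavenet_network
#' @export
tidy.cavenet_network <- function(x, ...) x$edges

#' Detect modules by Louvain modularity maximization
#'
#' Greedy multilevel modularity optimization on the unsigned weighted graph
#' (weights = |rho|), deterministic for a fixed seed.
#'
#' @param net A `cavenet_network`.
#' @param seed Integer seed (Louvain visits nodes in randomized order).
#' @return List of class `cavenet_modules`: `membership` tibble
#'   (`feature_id`, `module`), `modularity` (Q of the returned partition),
#'   `n_modules`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- net$graph
  if (igraph::ecount(g) < 1L) rlang::abort("module detection needs at least 1 edge")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  structure(list(
    membership = tibble::tibble(feature_id = names(mem), module = as.integer(mem)),
    modularity = igraph::modularity(g, mem, weights = igraph::E(g)$weight),
    n_modules = length(unique(mem))
  ), class = "cavenet_modules")
}

#' @export
print.cavenet_modules <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules, Q =",
      sprintf("%.3f", x$modularity), "\n")
  invisible(x)
}

#' Modularity Q of an explicit partition
#'
#' `Q = sum_s (e_ss / m - (d_s / 2m)^2)` over modules, with edge weights
#' |rho|.
#'
#' @param net A `cavenet_network`.
#' @param membership Named vector or `membership` tibble mapping node to
#'   module.
#' @return Modularity Q.
#' @export
partition_modularity <- function(net, membership) {
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership$module, membership$feature_id)
  }
  g <- net$graph
  igraph::modularity(g, membership[igraph::V(g)$name],
                     weights = igraph::E(g)$weight)
}

#' Topology summary of a cooccurrence network
#'
#' The standard descriptive battery: node and edge counts, average path
#' length (APL, mean shortest path over connected pairs), average clustering
#' coefficient (ACC, mean local clustering with degree<2 nodes contributing
#' 0), diameter (largest finite eccentricity), modularity of the Louvain
#' partition, density `2E/(N(N-1))`, average degree `2E/N`, average weighted
#' degree (mean over nodes of the |rho|-strength), and the fraction of
#' positive edges. Path statistics are taken over connected pairs because
#' threshold graphs may be disconnected.
#'
#' @param net A `cavenet_network`.
#' @param modules Optional `cavenet_modules`; computed (with `seed`) if absent.
#' @param seed Seed forwarded to [detect_modules()].
#' @return One-row tibble: `nodes`, `edges`, `apl`, `acc`, `diameter`,
#'   `modularity`, `n_modules`, `density`, `avg_degree`,
#'   `avg_weighted_degree`, `positive_edge_fraction`.
#' @export
topology <- function(net, modules = NULL, seed = 1L) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n < 2L) rlang::abort("topology needs at least 2 nodes")
  if (is.null(modules)) modules <- detect_modules(net, seed = seed)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  tibble::tibble(
    nodes = n,
    edges = e,
    apl = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                                weights = NA),
    acc = mean(local_cc),
    diameter = igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                                weights = NA),
    modularity = modules$modularity,
    n_modules = modules$n_modules,
    density = 2 * e / (n * (n - 1)),
    avg_degree = 2 * e / n,
    avg_weighted_degree = mean(igraph::strength(g, weights = igraph::E(g)$weight)),
    positive_edge_fraction = mean(igraph::E(g)$sign == "+")
  )
}

#' @rdname topology
#' @param x A `cavenet_network`.
#' @param ... Passed to [topology()].
#' @method glance cavenet_network
#' @export
glance.cavenet_network <- function(x, ...) topology(x, ...)

#' Degree and density identities from node/edge counts
#'
#' For a simple undirected graph the average degree is `2E/N` and the density
#' `2E/(N(N-1))` — arithmetic identities that hold for any reported
#' node/edge counts, useful to cross-check published topology tables.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return Tibble with `nodes`, `edges`, `avg_degree`, `density`.
#' @export
degree_density_identities <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2, n_edges >= 0)
  tibble::tibble(nodes = n_nodes, edges = n_edges,
                 avg_degree = 2 * n_edges / n_nodes,
                 density = 2 * n_edges / (n_nodes * (n_nodes - 1)))
}

#' Module size census with large-module flags
#'
#' Large modules are those holding strictly more than `large_frac` of all
#' nodes (the conventional "over 5% of the total nodes" rule).
#'
#' @param modules A `cavenet_modules` (or its `membership` tibble).
#' @param large_frac Strict size-fraction threshold (default 0.05).
#' @return Tibble: `module`, `size`, `fraction`, `large`.
#' @export
module_census <- function(modules, large_frac = 0.05) {
  mem <- if (inherits(modules, "cavenet_modules")) modules$membership else modules
  total <- nrow(mem)
  mem |>
    dplyr::count(.data$module, name = "size") |>
    dplyr::mutate(fraction = .data$size / total,
                  large = .data$fraction > large_frac) |>
    dplyr::arrange(dplyr::desc(.data$size))
}

#' Export the network as a Gephi-loadable edge list CSV
#'
#' Columns `Source`, `Target`, `Weight` (|rho|), `Sign`.
#'
#' @param net A `cavenet_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  edges <- net$edges
  readr::write_csv(tibble::tibble(Source = edges$feature_a,
                                  Target = edges$feature_b,
                                  Weight = abs(edges$rho),
                                  Sign = ifelse(edges$rho > 0, "+", "-")),
                   path)
  invisible(path)
}

#' Export the network as GraphML with node attributes
#'
#' @param net A `cavenet_network`.
#' @param path Output path.
#' @param modules Optional `cavenet_modules`; module ids become a node
#'   attribute.
#' @export
write_graphml <- function(net, path, modules = NULL) {
  g <- net$graph
  if (!is.null(modules)) {
    mem <- stats::setNames(modules$membership$module, modules$membership$feature_id)
    igraph::V(g)$module <- as.integer(mem[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a topology summary TSV
#' @param topo One-row tibble from [topology()].
#' @param path Output path.
#' @export
write_topology <- function(topo, path) {
  readr::write_tsv(topo, path)
  invisible(path)
}
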
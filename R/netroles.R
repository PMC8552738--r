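# Zi-Pi node-role cartography and keystone taxa.
#
# Roles follow the classical cartography of module-based networks: Zi is the
# z-score of a node's degree inside its own module, Pi the participation
# coefficient 1 - sum_s (k_is/k_i)^2. Both are computed on the unweighted
# graph (degree counts).

#' Zi-Pi node roles and keystone flags
#'
#' For every node: within-module degree `k_is` (edges to its own module),
#' total degree `k_i`, within-module connectivity
#' `Zi = (k_is - mean_s) / sd_s` (mean/sd over the node's module; 0 when the
#' module's within-degree variance is zero, e.g. singleton modules),
#' among-module connectivity `Pi = 1 - sum_s (k_is/k_i)^2`, and the four-way
#' role classification:
#' peripherals (`Zi <= zi_thr` and `Pi <= pi_thr`), connectors
#' (`Zi <= zi_thr`, `Pi > pi_thr`), module hubs (`Zi > zi_thr`,
#' `Pi <= pi_thr`), network hubs (both exceeded). Connectors, module hubs and
#' network hubs are flagged keystone.
#'
#' @param net A `cavenet_network`.
#' @param modules A `cavenet_modules` partition (or its `membership` tibble)
#'   covering all nodes.
#' @param zi_thr Within-module connectivity threshold (default 2.5).
#' @param pi_thr Participation-coefficient threshold (default 0.62).
#' @param incomplete What to do with graph nodes absent from the partition:
#'   `"error"` (default) or `"singleton"` to place each in its own
#'   one-node module (useful when scoring against an external partition that
#'   covers only part of the graph).
#' @return Tibble of class `cavenet_roles`: `feature_id`, `module`, `degree`,
#'   `within_degree`, `zi`, `pi`, `role`, `keystone`, `label`.
#' @export
node_roles <- function(net, modules, zi_thr = 2.5, pi_thr = 0.62,
                       incomplete = c("error", "singleton")) {
  stopifnot(is.finite(zi_thr), is.finite(pi_thr))
  incomplete <- match.arg(incomplete)
  g <- net$graph
  mem <- if (inherits(modules, "cavenet_modules")) modules$membership else modules
  ids <- igraph::V(g)$name
  missing <- setdiff(ids, mem$feature_id)
  if (length(missing)) {
    if (incomplete == "error") {
      rlang::abort(paste0("partition does not cover node(s): ",
                          paste(utils::head(missing, 5), collapse = ", ")))
    }
    mem <- dplyr::bind_rows(mem, tibble::tibble(
      feature_id = missing,
      module = max(mem$module) + seq_along(missing)))
  }
  module_of <- stats::setNames(mem$module, mem$feature_id)[ids]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- adj[ids, ids, drop = FALSE]
  adj[adj > 1] <- 1                      # simple graph: degree counts
  mods <- sort(unique(module_of))
  # k[i, s] = number of edges from node i into module s
  k_im <- vapply(mods, function(s) {
    rowSums(adj[, module_of == s, drop = FALSE])
  }, numeric(length(ids)))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = length(ids))
  colnames(k_im) <- as.character(mods)
  k_i <- rowSums(k_im)
  own <- match(module_of, mods)
  k_is <- k_im[cbind(seq_along(ids), own)]
  zi <- vapply(seq_along(ids), function(i) {
    in_mod <- which(own == own[i])
    mu <- mean(k_is[in_mod])
    sdv <- stats::sd(k_is[in_mod])
    if (length(in_mod) < 2L || is.na(sdv) || sdv == 0) 0 else (k_is[i] - mu) / sdv
  }, numeric(1))
  pi <- ifelse(k_i == 0, 0, 1 - rowSums((k_im / pmax(k_i, 1))^2))
  role <- as.character(classify_roles(zi, pi, zi_thr = zi_thr, pi_thr = pi_thr))
  out <- tibble::tibble(
    feature_id = ids,
    module = unname(module_of),
    degree = unname(k_i),
    within_degree = unname(k_is),
    zi = zi,
    pi = unname(pi),
    role = factor(role, levels = c("peripheral", "connector", "module_hub", "network_hub")),
    keystone = role != "peripheral"
  )
  out$label <- if ("label" %in% names(net$nodes)) {
    stats::setNames(net$nodes$label, net$nodes$feature_id)[ids]
  } else NA_character_
  class(out) <- c("cavenet_roles", class(out))
  out
}

#' Classify nodes into the four Zi-Pi roles
#'
#' Both thresholds are inclusive below: peripherals have `Zi <= zi_thr` and
#' `Pi <= pi_thr`, connectors exceed only the Pi threshold, module hubs only
#' the Zi threshold, network hubs both.
#'
#' @param zi,pi Numeric vectors of within-module connectivity and
#'   participation coefficient.
#' @param zi_thr,pi_thr Thresholds (defaults 2.5 and 0.62).
#' @return Factor with levels peripheral, connector, module_hub, network_hub.
#' @export
classify_roles <- function(zi, pi, zi_thr = 2.5, pi_thr = 0.62) {
  role <- dplyr::case_when(
    zi <= zi_thr & pi <= pi_thr ~ "peripheral",
    zi <= zi_thr & pi > pi_thr ~ "connector",
    zi > zi_thr & pi <= pi_thr ~ "module_hub",
    TRUE ~ "network_hub"
  )
  factor(role, levels = c("peripheral", "connector", "module_hub", "network_hub"))
}

#' Role-class percentage summary
#'
#' Share of nodes in each of the four roles, as percentages to 2 decimals
#' (they sum to 100 up to rounding).
#'
#' @param roles A `cavenet_roles` tibble.
#' @return Tibble: `role`, `n`, `percent`.
#' @export
role_percentages <- function(roles) {
  total <- nrow(roles)
  roles |>
    dplyr::count(.data$role, .drop = FALSE) |>
    dplyr::mutate(percent = round(100 * .data$n / total, 2))
}

#' Keystone taxa summary
#'
#' Counts keystone nodes (connectors, module hubs, network hubs) per taxonomy
#' label and reports each label's share of all keystones as a percentage to
#' 2 decimals.
#'
#' @param roles A `cavenet_roles` tibble (with `label` filled, e.g. via the
#'   `taxonomy` argument of [build_network()]).
#' @return Tibble: `label`, `n_keystone`, `share_percent`, sorted by share.
#'   Empty (with a warning) when there is no keystone node.
#' @export
keystone_summary <- function(roles) {
  ks <- roles[roles$keystone, , drop = FALSE]
  if (nrow(ks) == 0L) {
    rlang::warn("no keystone node in this network")
    return(tibble::tibble(label = character(), n_keystone = integer(),
                          share_percent = numeric()))
  }
  ks$label[is.na(ks$label)] <- "unclassified"
  ks |>
    dplyr::count(.data$label, name = "n_keystone") |>
    dplyr::mutate(share_percent = round(100 * .data$n_keystone / sum(.data$n_keystone), 2)) |>
    dplyr::arrange(dplyr::desc(.data$share_percent))
}

#' Subnetwork around focal keystone nodes
#'
#' Induced subgraph on the keystone nodes carrying any of the focal taxonomy
#' labels plus their first neighbors — the view used to ask which partners a
#' keystone lineage connects to.
#'
#' @param net A `cavenet_network`.
#' @param roles A `cavenet_roles` tibble for `net`.
#' @param focal_labels Character vector of taxonomy labels (or feature ids).
#' @return A `cavenet_network` restricted to the neighborhood.
#' @export
keystone_subnetwork <- function(net, roles, focal_labels) {
  g <- net$graph
  focal <- roles$feature_id[roles$keystone &
                              (roles$label %in% focal_labels |
                                 roles$feature_id %in% focal_labels)]
  if (length(focal) == 0L) {
    rlang::abort(paste0("no keystone node matches label(s): ",
                        paste(focal_labels, collapse = ", ")))
  }
  nbr <- unique(unlist(igraph::adjacent_vertices(g, focal)))
  keep <- union(focal, igraph::V(g)$name[nbr])
  sub <- igraph::induced_subgraph(g, keep)
  edges <- net$edges[net$edges$feature_a %in% keep & net$edges$feature_b %in% keep, ]
  structure(list(graph = sub, edges = edges,
                 nodes = net$nodes[net$nodes$feature_id %in% keep, ],
                 rho_min = net$rho_min, alpha = net$alpha,
                 use_adjusted = net$use_adjusted),
            class = "cavenet_network")
}

#' Zi-Pi scatter plot of node roles
#'
#' @param roles A `cavenet_roles` tibble.
#' @param zi_thr,pi_thr Thresholds to draw as dashed guides (defaults 2.5 and
#'   0.62).
#' @return A ggplot object.
#' @export
plot_zipi <- function(roles, zi_thr = 2.5, pi_thr = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(.data$pi, .data$zi, colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_thr, linetype = "dashed") +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module connectivity (Zi)", colour = "Role") +
    ggplot2::theme_minimal()
}

#' Write the node-role table as TSV
#' @param roles A `cavenet_roles` tibble.
#' @param path Output path.
#' @export
write_roles <- function(roles, path) {
  readr::write_tsv(as.data.frame(roles), path)
  invisible(path)
}
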
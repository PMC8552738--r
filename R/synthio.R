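# Synthetic community generator with planted modules, connectors, and
# environmental gradients.
#
# Counts are generated as latent log-abundances driven by per-module Gaussian
# factors, mapped through a softmax to sample-wise composition, and drawn by
# multinomial sampling at a random depth: the data are compositional (as
# amplicon tables are) while the planted rank correlations stay analyzable.
# For a bivariate normal with Pearson correlation r the Spearman correlation
# is (6/pi) asin(r/2), so the factor loading is chosen as
# r = 2 sin(pi rho_s / 6) to hit the target Spearman rho_s on the latent
# scale; multinomial sampling at depth ~1e4 attenuates it only mildly.

#' Specification for a synthetic microbiome community
#'
#' Defaults mirror a 36-sample cave-rock amplicon study: ~900 retained
#' features of which 200 are correlated across 11 planted modules (one
#' dominant module standing for the USC-gamma clade), sequencing depth around
#' 10^4 reads per sample, and a small fraction of negatively loading features
#' so that a few percent of strong associations are negative.
#'
#' @param n_features Total features (default 900).
#' @param n_samples Samples (default 36).
#' @param n_modules Planted modules (default 11).
#' @param n_correlated Features that belong to modules (default 200); the
#'   rest are uncorrelated background.
#' @param within_module_rho Target Spearman correlation between members of a
#'   module on the latent scale, in (0, 1) (default 0.85).
#' @param n_connectors Features wired evenly into several modules
#'   (default 8).
#' @param connector_span Modules each connector loads on (default 3).
#' @param depth_range Integer range of reads per sample
#'   (default `c(9000, 11000)`).
#' @param dispersion Scale of the latent log-abundance noise (default 1);
#'   overdispersion enters through this factor noise.
#' @param env_effects Tibble `variable`, `module`, `effect`: numeric metadata
#'   variables driven by a module factor with the given effect size (slope on
#'   the z scale); unlisted variables are pure noise. Default: CH4 and CO2
#'   track the dominant module, pH tracks module 2.
#' @param negative_assoc_fraction Fraction of module members that load
#'   negatively on their factor (default 0.018, which yields a few percent of
#'   negative planted associations).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `syn_spec`.
#' @export
syn_spec <- function(n_features = 900, n_samples = 36, n_modules = 11,
                     n_correlated = 200, within_module_rho = 0.85,
                     n_connectors = 8, connector_span = 3,
                     depth_range = c(9000, 11000), dispersion = 1,
                     env_effects = NULL, negative_assoc_fraction = 0.018,
                     seed = 1L) {
  if (is.null(env_effects)) {
    env_effects <- tibble::tibble(variable = c("CH4", "CO2", "pH"),
                                  module = c(1L, 1L, 2L),
                                  effect = c(1.5, 1.2, 1.0))
  }
  spec <- list(n_features = n_features, n_samples = n_samples,
               n_modules = n_modules, n_correlated = n_correlated,
               within_module_rho = within_module_rho,
               n_connectors = n_connectors, connector_span = connector_span,
               depth_range = as.integer(depth_range), dispersion = dispersion,
               env_effects = env_effects,
               negative_assoc_fraction = negative_assoc_fraction,
               seed = as.integer(seed))
  if (n_modules < 1) rlang::abort("n_modules must be >= 1")
  if (!(within_module_rho > 0 && within_module_rho < 1)) {
    rlang::abort("within_module_rho must lie strictly in (0, 1)")
  }
  if (any(depth_range < 1) || depth_range[2] < depth_range[1]) {
    rlang::abort("depth_range must be a positive increasing range")
  }
  if (connector_span > n_modules) rlang::abort("connector_span exceeds n_modules")
  if (n_correlated + n_connectors > n_features) {
    rlang::abort("more correlated + connector features than total features")
  }
  if (n_correlated < 2 * n_modules) {
    rlang::abort("need at least 2 correlated features per module")
  }
  if (negative_assoc_fraction < 0 || negative_assoc_fraction > 1) {
    rlang::abort("negative_assoc_fraction must lie in [0, 1]")
  }
  structure(spec, class = "syn_spec")
}

# largest-remainder apportionment of n into weights w (all parts >= 2)
apportion_sizes <- function(n, w) {
  q <- n * w / sum(w)
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_rem <- order(q - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1
  }
  sizes
}

#' Generate a synthetic community with ground truth
#'
#' @param spec A [syn_spec()].
#' @return List with `counts` (feature-table tibble), `taxonomy`, `metadata`,
#'   and `truth`: list with `partition` (tibble `feature_id`, `module`; for
#'   connectors the first spanned module), `connectors` (tibble `feature_id`,
#'   `modules` list-column), `associations` (tibble of planted pairs with the
#'   latent signed Spearman correlation and a `connector_pair` flag),
#'   `factors` (samples x modules matrix of module factors), `env_effects`,
#'   and `seed`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "syn_spec"))
  set.seed(spec$seed)
  nf <- spec$n_features; ns <- spec$n_samples; nm <- spec$n_modules
  rho_s <- spec$within_module_rho
  r <- 2 * sin(pi * rho_s / 6)            # latent Pearson for target Spearman
  if (r >= 1) rlang::abort("infeasible within_module_rho: loading would exceed 1")
  a <- sqrt(r)

  feature_id <- sprintf("F%04d", seq_len(nf))
  # a mildly larger first module, the rest equal; taxonomic dominance comes
  # from labels spanning several modules, not from one giant module (a single
  # module holding most reads would couple everything through compositional
  # closure)
  sizes <- apportion_sizes(spec$n_correlated, c(2, rep(1, nm - 1)))
  module_of <- rep(NA_integer_, nf)
  module_of[seq_len(spec$n_correlated)] <- rep(seq_len(nm), times = sizes)
  conn_idx <- spec$n_correlated + seq_len(spec$n_connectors)
  # connectors span equal-sized modules (2..nm when possible) so their edges
  # are spread evenly; spanning the dominant module would skew participation
  # toward it by module size alone
  pool <- if (nm > spec$connector_span) 2:nm else 1:nm
  conn_modules <- lapply(seq_len(spec$n_connectors), function(i) {
    as.integer(pool[((i - 1 + seq_len(spec$connector_span) - 1) %% length(pool)) + 1])
  })

  # latent log-abundances
  factors <- matrix(stats::rnorm(nm * ns), nrow = nm)          # modules x samples
  eps <- matrix(stats::rnorm(nf * ns), nrow = nf)
  mu <- stats::rnorm(nf, mean = 0, sd = 1)
  corr_idx <- which(!is.na(module_of))
  mu[corr_idx] <- stats::rnorm(length(corr_idx), mean = 1.2, sd = 0.5)
  mu[conn_idx] <- stats::rnorm(length(conn_idx), mean = 1.2, sd = 0.5)
  loading_sign <- rep(1, nf)
  n_neg <- round(spec$negative_assoc_fraction * length(corr_idx))
  if (n_neg > 0) {
    loading_sign[sample(corr_idx, n_neg)] <- -1
  }
  lat <- mu + spec$dispersion * sqrt(1 - r) * eps
  for (i in corr_idx) {
    lat[i, ] <- lat[i, ] + spec$dispersion * loading_sign[i] * a * factors[module_of[i], ]
  }
  for (j in seq_along(conn_idx)) {
    i <- conn_idx[j]
    f <- colSums(factors[conn_modules[[j]], , drop = FALSE]) / sqrt(spec$connector_span)
    lat[i, ] <- lat[i, ] + spec$dispersion * a * f
  }

  # compositional sampling at varying depth
  depths <- sample(seq(spec$depth_range[1], spec$depth_range[2]), ns, replace = TRUE)
  counts <- vapply(seq_len(ns), function(jj) {
    p <- exp(lat[, jj]); p <- p / sum(p)
    as.numeric(stats::rmultinom(1, depths[jj], p))
  }, numeric(nf))
  rownames(counts) <- feature_id
  colnames(counts) <- sprintf("S%02d", seq_len(ns))

  # taxonomy: the USC-gamma label dominates by covering most modules (as the
  # dominant methanotroph clade dominates real cave networks); the remaining
  # modules cycle through minor clade labels
  minor_pool <- c("Deep-sea 2", "JRC-3", "USCalpha", "JRC-1", "Deep-sea 4",
                  "Gaiella", "Povalibacter", "Bacillus", "Aciditerrimonas",
                  "Methyloceanibacter")
  n_dom <- max(1L, round(0.82 * nm))
  mod_label <- c(rep("USCgamma", n_dom),
                 minor_pool[((seq_len(nm - n_dom) - 1) %% length(minor_pool)) + 1])
  lab <- rep("unclassified", nf)
  lab[corr_idx] <- mod_label[module_of[corr_idx]]
  lab[conn_idx] <- mod_label[vapply(conn_modules, `[`, integer(1), 1)]
  taxonomy <- make_taxonomy(feature_id,
                            ifelse(lab == "unclassified", "unclassified",
                                   paste("Bacteria", lab, sep = ";")))

  # metadata: 3 caves x 2 sites x crust/rock x triplicates
  sample_id <- colnames(counts)
  cave <- rep(c("PLD", "LHD", "XCT"), each = ceiling(ns / 3))[seq_len(ns)]
  site <- paste0(cave, rep(rep(1:2, each = ceiling(ns / 6)), 3)[seq_len(ns)])
  niche <- rep(c("crust", "rock"), length.out = ns)
  env_vars <- c("pH", "Cl", "SO4", "K", "Na", "CaSi", "MgSi", "CH4", "CO2")
  z <- matrix(stats::rnorm(length(env_vars) * ns), nrow = ns,
              dimnames = list(sample_id, env_vars))
  for (k in seq_len(nrow(spec$env_effects))) {
    v <- spec$env_effects$variable[k]
    m <- spec$env_effects$module[k]
    b <- spec$env_effects$effect[k]
    if (!v %in% env_vars || m > nm) next
    z[, v] <- b * factors[m, ] + stats::rnorm(ns)
  }
  # affine maps to plausible units (do not change correlation structure)
  units <- list(pH = c(8, 0.3), Cl = c(6, 2), SO4 = c(20, 5), K = c(8, 2),
                Na = c(7, 2), CaSi = c(8, 2), MgSi = c(2, 1),
                CH4 = c(2, 0.5), CO2 = c(800, 150))
  metadata <- tibble::tibble(sample_id = sample_id, cave = cave, site = site,
                             niche = niche)
  for (v in env_vars) metadata[[v]] <- units[[v]][1] + units[[v]][2] * z[, v]

  # planted associations: all same-module member pairs (latent Spearman
  # rho_s, sign = product of loading signs); connector-member pairs carry the
  # attenuated rho_s / sqrt(span) and are flagged.
  assoc <- list()
  for (m in seq_len(nm)) {
    members <- which(module_of == m)
    if (length(members) >= 2) {
      pr <- t(utils::combn(members, 2))
      assoc[[length(assoc) + 1]] <- tibble::tibble(
        feature_a = feature_id[pr[, 1]], feature_b = feature_id[pr[, 2]],
        rho_latent = rho_s * loading_sign[pr[, 1]] * loading_sign[pr[, 2]],
        connector_pair = FALSE)
    }
  }
  for (j in seq_along(conn_idx)) {
    members <- which(module_of %in% conn_modules[[j]])
    if (length(members)) {
      assoc[[length(assoc) + 1]] <- tibble::tibble(
        feature_a = pmin(feature_id[conn_idx[j]], feature_id[members]),
        feature_b = pmax(feature_id[conn_idx[j]], feature_id[members]),
        rho_latent = rho_s / sqrt(spec$connector_span) * loading_sign[members],
        connector_pair = TRUE)
    }
  }
  associations <- dplyr::bind_rows(assoc)

  truth <- list(
    partition = tibble::tibble(
      feature_id = feature_id[c(corr_idx, conn_idx)],
      module = c(module_of[corr_idx],
                 vapply(conn_modules, `[`, integer(1), 1))),
    connectors = tibble::tibble(feature_id = feature_id[conn_idx],
                                modules = conn_modules),
    associations = associations,
    factors = t(factors),
    env_effects = spec$env_effects,
    seed = spec$seed
  )
  list(counts = as_feature_table(counts), taxonomy = taxonomy,
       metadata = metadata, truth = truth)
}

#' Adjusted Rand index between two partitions
#'
#' Closed-form ARI from the contingency table; 1 for identical partitions
#' (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Partition label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
ari_score <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

#' Recovery scores of inferred structure against planted truth
#'
#' @param truth The `truth` element of [generate_community()] output.
#' @param partition Optional inferred partition (`cavenet_modules` or
#'   membership tibble): scored by adjusted Rand index over shared ids.
#' @param edges Optional inferred edge tibble (`feature_a`, `feature_b`):
#'   precision/recall against planted non-connector associations.
#' @param roles Optional `cavenet_roles` tibble: planted-connector recall
#'   (fraction of planted connectors present in the network and classified
#'   connector).
#' @return Tibble `metric`, `value`.
#' @export
truth_metrics <- function(truth, partition = NULL, edges = NULL, roles = NULL) {
  out <- list()
  if (!is.null(partition)) {
    mem <- if (inherits(partition, "cavenet_modules")) partition$membership else partition
    shared <- intersect(mem$feature_id, truth$partition$feature_id)
    if (length(shared) == 0L) rlang::abort("partition and truth share no feature ids")
    inf <- stats::setNames(mem$module, mem$feature_id)[shared]
    tru <- stats::setNames(truth$partition$module, truth$partition$feature_id)[shared]
    out$ari <- ari_score(inf, tru)
    out$n_shared <- length(shared)
  }
  if (!is.null(edges)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    planted <- truth$associations[!truth$associations$connector_pair, ]
    truth_keys <- key(planted$feature_a, planted$feature_b)
    edge_keys <- key(edges$feature_a, edges$feature_b)
    out$edge_precision <- if (length(edge_keys)) mean(edge_keys %in% truth_keys) else NA_real_
    out$edge_recall <- if (length(truth_keys)) mean(truth_keys %in% edge_keys) else NA_real_
  }
  if (!is.null(roles)) {
    conn <- truth$connectors$feature_id
    found <- roles$feature_id[roles$role == "connector"]
    out$connector_recall <- mean(conn %in% found)
  }
  if (length(out) == 0L) rlang::abort("supply at least one of partition/edges/roles")
  tibble::tibble(metric = names(out), value = unlist(out, use.names = FALSE))
}

#' Write all generator outputs in the pipeline's TSV dialects
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(community$counts, file.path(dir, "feature_table.tsv"))
  write_taxonomy(community$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(community$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(community$truth$partition, file.path(dir, "truth_partition.tsv"))
  readr::write_tsv(community$truth$associations, file.path(dir, "truth_associations.tsv"))
  readr::write_tsv(
    tibble::tibble(feature_id = community$truth$connectors$feature_id,
                   modules = vapply(community$truth$connectors$modules,
                                    paste, character(1), collapse = ",")),
    file.path(dir, "truth_connectors.tsv"))
  invisible(dir)
}
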
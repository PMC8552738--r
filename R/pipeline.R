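# End-to-end orchestration: config, run_all, artifact writing.

#' Analysis configuration
#'
#' Houses every tunable threshold of the pipeline with the conventional
#' defaults: prevalence filter at mean relative abundance > 0.1% and
#' occurrence > 20%, edge threshold |rho| >= 0.7 at BH-adjusted p < 0.05,
#' Zi/Pi role thresholds 2.5 and 0.62, 9,999 Mantel permutations, and the
#' "over 5% of nodes" large-module rule.
#'
#' @param rarefaction_depth Reads per sample after rarefaction (required;
#'   there is no universal default — choose at or below the smallest sample
#'   total).
#' @param seed Integer seed used for rarefaction, permutations, and module
#'   detection.
#' @param min_mean_relabund,min_occurrence Prevalence-filter thresholds
#'   (defaults 0.001 and 0.2, strict).
#' @param rho_min Edge correlation-strength threshold (default 0.7).
#' @param alpha Edge significance level (default 0.05).
#' @param p_adjust `"BH"` (default) to threshold adjusted q, `"none"` for raw
#'   p.
#' @param zi_thr,pi_thr Role thresholds (defaults 2.5, 0.62).
#' @param n_perm Mantel permutations (default 9999).
#' @param large_module_frac Strict large-module fraction (default 0.05).
#' @param mantel_variables Metadata columns for the Mantel screen (default:
#'   all numeric columns).
#' @param output_dir Where [run_all()] writes artifacts (default: a temp
#'   directory).
#' @return List of class `cavenet_config`.
#' @export
analysis_config <- function(rarefaction_depth, seed = 1L,
                            min_mean_relabund = 0.001, min_occurrence = 0.2,
                            rho_min = 0.7, alpha = 0.05, p_adjust = "BH",
                            zi_thr = 2.5, pi_thr = 0.62, n_perm = 9999,
                            large_module_frac = 0.05,
                            mantel_variables = NULL,
                            output_dir = tempfile("cavenet_run_")) {
  cfg <- list(rarefaction_depth = as.integer(rarefaction_depth),
              seed = as.integer(seed),
              min_mean_relabund = min_mean_relabund,
              min_occurrence = min_occurrence,
              rho_min = rho_min, alpha = alpha, p_adjust = p_adjust,
              zi_thr = zi_thr, pi_thr = pi_thr, n_perm = as.integer(n_perm),
              large_module_frac = large_module_frac,
              mantel_variables = mantel_variables,
              output_dir = output_dir)
  validate_config(cfg)
  structure(cfg, class = "cavenet_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) rlang::abort(paste0("invalid config: ", msg))
  chk(length(cfg$rarefaction_depth) == 1 && cfg$rarefaction_depth >= 1,
      "rarefaction_depth must be a positive integer")
  chk(cfg$min_mean_relabund >= 0 && cfg$min_mean_relabund <= 1,
      "min_mean_relabund must lie in [0,1]")
  chk(cfg$min_occurrence >= 0 && cfg$min_occurrence <= 1,
      "min_occurrence must lie in [0,1]")
  chk(cfg$rho_min >= 0 && cfg$rho_min <= 1, "rho_min must lie in [0,1]")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must lie in (0,1]")
  chk(cfg$p_adjust %in% c("BH", "none"), "p_adjust must be 'BH' or 'none'")
  chk(is.finite(cfg$zi_thr) && is.finite(cfg$pi_thr), "role thresholds must be finite")
  chk(cfg$n_perm >= 99, "n_perm must be >= 99")
  chk(cfg$large_module_frac >= 0 && cfg$large_module_frac <= 1,
      "large_module_frac must lie in [0,1]")
  invisible(TRUE)
}

#' Write / read a configuration as YAML
#'
#' The file representation round-trips losslessly.
#'
#' @param cfg A `cavenet_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(analysis_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Run the full pipeline from tables to network roles
#'
#' Orchestrates rarefaction, prevalence filtering, alpha/beta diversity with
#' PCoA and UPGMA, the Mantel screen against environmental variables, the
#' Spearman/BH cooccurrence network, topology, module detection, Zi-Pi roles
#' and keystone summaries, writing every intermediate artifact to
#' `cfg$output_dir` together with a run log recording seeds, thresholds and
#' package versions.
#'
#' @param cfg A `cavenet_config`.
#' @param counts Feature-table tibble of raw counts.
#' @param taxonomy Taxonomy tibble (optional but recommended).
#' @param metadata Metadata tibble with `sample_id` (optional; Mantel screen
#'   is skipped without it).
#' @return List of class `cavenet_run`: `rarefied`, `filtered`, `alpha`,
#'   `bray`, `pcoa`, `upgma`, `mantel`, `screen`, `network`, `modules`,
#'   `topology`, `census`, `roles`, `role_percent`, `keystones`, `config`,
#'   `output_dir`.
#' @export
run_all <- function(cfg, counts, taxonomy = NULL, metadata = NULL) {
  stopifnot(inherits(cfg, "cavenet_config"))
  validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "': ", conditionMessage(e)))
    })
  }
  if (!is.null(metadata)) stage("metadata", check_metadata_complete(counts, metadata))

  rarefied <- stage("rarefy", rarefy_counts(counts, cfg$rarefaction_depth, seed = cfg$seed))
  filtered <- stage("filter", prevalence_filter(rarefied, cfg$min_mean_relabund,
                                                cfg$min_occurrence))
  alpha <- stage("alpha_diversity", alpha_diversity(rarefied))
  bray <- stage("bray_curtis", bray_curtis(rarefied))
  ord <- stage("pcoa", pcoa_ordination(bray))
  tree <- stage("upgma", upgma(bray))

  mant <- NULL
  if (!is.null(metadata)) {
    vars <- cfg$mantel_variables
    if (is.null(vars)) {
      vars <- setdiff(names(metadata)[vapply(metadata, is.numeric, logical(1))],
                      "sample_id")
    }
    if (length(vars)) {
      meta_ord <- metadata[match(labels(bray), metadata$sample_id), ]
      mant <- stage("mantel", mantel_screen(bray, meta_ord, vars,
                                            n_perm = cfg$n_perm, seed = cfg$seed))
    }
  }

  screen <- stage("pairwise_spearman", pairwise_spearman(filtered))
  net <- stage("build_network",
               build_network(screen, rho_min = cfg$rho_min, alpha = cfg$alpha,
                             taxonomy = taxonomy,
                             use_adjusted = cfg$p_adjust == "BH"))
  modules <- stage("detect_modules", detect_modules(net, seed = cfg$seed))
  topo <- stage("topology", topology(net, modules = modules))
  census <- stage("module_census", module_census(modules, cfg$large_module_frac))
  roles <- stage("node_roles", node_roles(net, modules, zi_thr = cfg$zi_thr,
                                          pi_thr = cfg$pi_thr))
  role_pct <- role_percentages(roles)
  keystones <- withCallingHandlers(keystone_summary(roles),
                                   warning = function(w) invokeRestart("muffleWarning"))

  out <- cfg$output_dir
  write_feature_table(rarefied, file.path(out, "rarefied.tsv"))
  write_feature_table(filtered, file.path(out, "filtered.tsv"))
  readr::write_tsv(alpha, file.path(out, "alpha_diversity.tsv"))
  readr::write_tsv(tidy(ord), file.path(out, "pcoa_coordinates.tsv"))
  write_newick(tree, file.path(out, "upgma.nwk"))
  if (!is.null(mant)) readr::write_tsv(mant, file.path(out, "mantel.tsv"))
  write_edge_list(net, file.path(out, "edges.csv"))
  write_graphml(net, file.path(out, "network.graphml"), modules = modules)
  write_topology(topo, file.path(out, "topology.tsv"))
  readr::write_tsv(census, file.path(out, "module_census.tsv"))
  write_roles(roles, file.path(out, "node_roles.tsv"))
  readr::write_tsv(role_pct, file.path(out, "role_percentages.tsv"))
  readr::write_tsv(keystones, file.path(out, "keystone_summary.tsv"))
  writeLines(c(
    paste0("cavenet ", as.character(utils::packageVersion("cavenet"))),
    paste0("R ", R.version.string),
    paste0("run at ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed ", cfg$seed),
    paste0("rarefaction_depth ", cfg$rarefaction_depth),
    paste0("filter > ", cfg$min_mean_relabund, " mean relabund, > ",
           cfg$min_occurrence, " occurrence"),
    paste0("edges |rho| >= ", cfg$rho_min, ", ",
           if (cfg$p_adjust == "BH") "BH q" else "raw p", " < ", cfg$alpha),
    paste0("roles Zi > ", cfg$zi_thr, " / Pi > ", cfg$pi_thr),
    paste0("mantel permutations ", cfg$n_perm)
  ), file.path(out, "run_log.txt"))

  structure(list(rarefied = rarefied, filtered = filtered, alpha = alpha,
                 bray = bray, pcoa = ord, upgma = tree, mantel = mant,
                 screen = screen, network = net, modules = modules,
                 topology = topo, census = census, roles = roles,
                 role_percent = role_pct, keystones = keystones,
                 config = cfg, output_dir = out),
            class = "cavenet_run")
}

#' @export
print.cavenet_run <- function(x, ...) {
  cat("cavenet run:", x$topology$nodes, "nodes,", x$topology$edges,
      "edges,", x$topology$n_modules, "modules, Q =",
      sprintf("%.3f", x$topology$modularity), "\n")
  cat("artifacts in", x$output_dir, "\n")
  invisible(x)
}

#' @rdname run_all
#' @param x A `cavenet_run`.
#' @param ... Unused.
#' @return For `glance()`: the one-row topology tibble.
#' @method glance cavenet_run
#' @export
glance.cavenet_run <- function(x, ...) x$topology
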
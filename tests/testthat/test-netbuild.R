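test_that("pairwise_spearman matches per-pair oracles and BH hand values", {
  set.seed(10)
  m <- matrix(rpois(6 * 10, 8), nrow = 6,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  scr <- pairwise_spearman(as_feature_table(m))
  expect_equal(nrow(scr), choose(6, 2))
  for (k in sample(nrow(scr), 5)) {
    a <- m[scr$feature_a[k], ]; b <- m[scr$feature_b[k], ]
    ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(scr$rho[k], unname(ct$estimate), tolerance = 1e-12)
  }
  expect_equal(scr$q, oracle_bh(scr$p_value), tolerance = 1e-12)
  expect_true(all(scr$q >= scr$p_value - 1e-15))

  # BH step-up hand case
  expect_equal(oracle_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(p.adjust(c(0.005, 0.01, 0.03, 0.04), "BH"),
               c(0.02, 0.02, 0.04, 0.04))

  # monotone pair and constant-feature exclusion
  mm <- rbind(f1 = 1:8, f2 = (1:8)^2, f3 = rep(4, 8), f4 = rpois(8, 5))
  colnames(mm) <- paste0("s", 1:8)
  scr2 <- pairwise_spearman(as_feature_table(mm))
  expect_equal(scr2$rho[scr2$feature_a == "f1" & scr2$feature_b == "f2"], 1)
  expect_false("f3" %in% c(scr2$feature_a, scr2$feature_b))
  expect_equal(attr(scr2, "dropped"), "f3")
})

test_that("build_network applies |rho| and q thresholds exactly", {
  screen <- tibble::tibble(
    feature_a = paste0("a", 1:5), feature_b = paste0("b", 1:5),
    rho = c(0.69, -0.8, 0.75, 0.9, 0.71),
    p_value = c(1e-4, 1e-3, 0.2, 1e-5, 0.04),
    q = c(0.001, 0.01, 0.3, 0.001, 0.06))
  net <- build_network(screen, rho_min = 0.7, alpha = 0.05)
  got <- paste(net$edges$feature_a, net$edges$feature_b)

  # exhaustive threshold evaluation over the pairs
  want <- with(screen, paste(feature_a, feature_b)[abs(rho) >= 0.7 & q < 0.05])
  expect_setequal(got, want)
  expect_false("a1 b1" %in% got)        # rho 0.69: boundary is strict on 0.7
  expect_true("a2 b2" %in% got)         # rho -0.8 kept as a negative edge
  expect_equal(net$edges$sign[net$edges$feature_a == "a2"], "-")
  # nodes are edge endpoints only
  expect_equal(sort(net$nodes$feature_id), sort(unique(c(net$edges$feature_a,
                                                         net$edges$feature_b))))
  expect_error(build_network(screen, rho_min = 0.99), "no edge")

  raw <- build_network(screen, rho_min = 0.7, alpha = 0.05, use_adjusted = FALSE)
  expect_true("a5 b5" %in% paste(raw$edges$feature_a, raw$edges$feature_b))
})

test_that("topology identities and closed forms hold", {
  tri <- network_from_edges(tibble::tibble(feature_a = c("a", "b", "c"),
                                           feature_b = c("b", "c", "a")))
  topo <- topology(tri)
  expect_equal(topo$acc, 1)
  expect_equal(topo$apl, 1)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$density, 1)
  expect_equal(topo$avg_degree, 2)
  expect_equal(topo$positive_edge_fraction, 1)

  idt <- degree_density_identities(200, 1861)
  expect_equal(idt$avg_degree, 18.61)
  expect_equal(idt$density, 2 * 1861 / (200 * 199))
})

test_that("APL, ACC and diameter equal brute-force oracles on small graphs", {
  for (seed in 1:10) {
    n <- sample(4:12, 1)
    net <- random_network(n, p = runif(1, 0.2, 0.6), seed = seed + 100)
    adj <- adjacency_of(net)
    topo <- topology(net)
    expect_equal(topo$apl, oracle_apl(adj), tolerance = 1e-12,
                 label = paste("APL seed", seed))
    expect_equal(topo$diameter, oracle_diameter(adj),
                 label = paste("diameter seed", seed))
    expect_equal(topo$acc, oracle_acc(adj), tolerance = 1e-12,
                 label = paste("ACC seed", seed))
    expect_equal(topo$density, 2 * topo$edges / (topo$nodes * (topo$nodes - 1)))
    expect_equal(topo$avg_degree, 2 * topo$edges / topo$nodes)
  }
})

test_that("module detection: components, cliques, and planted blocks", {
  two_tri <- network_from_edges(tibble::tibble(
    feature_a = c("a", "b", "c", "x", "y", "z"),
    feature_b = c("b", "c", "a", "y", "z", "x")))
  mod <- detect_modules(two_tri, seed = 1)
  expect_equal(mod$n_modules, 2)
  expect_equal(mod$modularity, 0.5)
  # partition equals the connected components
  mem <- setNames(mod$membership$module, mod$membership$feature_id)
  expect_equal(length(unique(mem[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mem[c("x", "y", "z")])), 1)

  clique <- network_from_edges(tibble::tibble(
    feature_a = c("a", "a", "a", "b", "b", "c"),
    feature_b = c("b", "c", "d", "c", "d", "d")))
  modc <- detect_modules(clique, seed = 1)
  expect_equal(modc$n_modules, 1)
  expect_equal(modc$modularity, 0)

  # returned partition beats the trivial partitions
  set.seed(11)
  net <- random_network(12, 0.35, seed = 77)
  best <- detect_modules(net, seed = 2)
  ids <- net$nodes$feature_id
  singletons <- tibble::tibble(feature_id = ids, module = seq_along(ids))
  lumped <- tibble::tibble(feature_id = ids, module = 1L)
  expect_gte(best$modularity, partition_modularity(net, singletons) - 1e-12)
  expect_gte(best$modularity, partition_modularity(net, lumped) - 1e-12)
})

test_that("module census sums to N and flags large modules strictly", {
  mem <- tibble::tibble(feature_id = sprintf("f%03d", 1:200),
                        module = rep(1:3, c(10, 11, 179)))
  cen <- module_census(mem, large_frac = 0.05)
  expect_equal(sum(cen$size), 200)
  expect_false(cen$large[cen$module == 1])   # 10/200 = 5.0%: not large
  expect_true(cen$large[cen$module == 2])    # 11/200 > 5%
})

test_that("network exports are loadable", {
  net <- random_network(8, 0.4, seed = 5)
  mod <- detect_modules(net, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(names(back), c("Source", "Target", "Weight", "Sign"))
  expect_equal(nrow(back), nrow(net$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml, modules = mod)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_true("module" %in% igraph::vertex_attr_names(g2))
})
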
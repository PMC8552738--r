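# an 8-node toy with two hand-assigned modules used in several blocks
toy_role_graph <- function() {
  edges <- tibble::tibble(
    feature_a = c("a", "a", "a", "b", "c", "e", "e", "f", "a", "d"),
    feature_b = c("b", "c", "d", "c", "d", "f", "g", "g", "e", "h"))
  net <- network_from_edges(edges)
  mem <- tibble::tibble(feature_id = letters[1:8],
                        module = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  list(net = net, mem = mem)
}

test_that("Zi and Pi match direct formula evaluation on the toy graph", {
  tg <- toy_role_graph()
  roles <- node_roles(tg$net, tg$mem)
  adj <- adjacency_of(tg$net)
  ids <- rownames(adj)
  oracle <- oracle_zipi(adj, setNames(tg$mem$module, tg$mem$feature_id)[ids])
  got <- roles[match(ids, roles$feature_id), ]
  expect_equal(got$zi, oracle$zi, tolerance = 1e-12)
  expect_equal(got$pi, oracle$pi, tolerance = 1e-12)

  # closed forms: all edges within own module -> Pi = 0
  b <- roles[roles$feature_id == "b", ]
  expect_equal(b$pi, 0)
  # degree split 2/2 across two modules -> Pi = 0.5
  d <- roles[roles$feature_id == "d", ]
  expect_equal(d$degree, 3)
  e_node <- roles[roles$feature_id == "e", ]
  expect_equal(e_node$pi, 1 - (1 / 9 + 4 / 9))
})

test_that("Zi and Pi match enumeration oracles on random graphs", {
  for (seed in 1:8) {
    net <- random_network(10, 0.4, seed = seed + 300)
    mod <- detect_modules(net, seed = 1)
    roles <- node_roles(net, mod)
    adj <- adjacency_of(net)
    ids <- rownames(adj)
    mem <- setNames(mod$membership$module, mod$membership$feature_id)[ids]
    oracle <- oracle_zipi(adj, mem)
    got <- roles[match(ids, roles$feature_id), ]
    expect_equal(got$zi, oracle$zi, tolerance = 1e-12)
    expect_equal(got$pi, oracle$pi, tolerance = 1e-12)
    expect_true(all(got$pi >= 0 & got$pi < 1))
    # Zi has mean ~0 within modules of size >= 2 with nonzero variance
    for (s in unique(mem)) {
      zs <- got$zi[mem == s]
      if (length(zs) >= 2 && any(zs != 0)) expect_equal(mean(zs), 0, tolerance = 1e-9)
    }
  }
})

test_that("degree-2/2 split across modules yields Pi exactly one half", {
  edges <- tibble::tibble(feature_a = rep("hub", 4),
                          feature_b = c("m1a", "m1b", "m2a", "m2b"))
  extra <- tibble::tibble(feature_a = c("m1a", "m2a"), feature_b = c("m1b", "m2b"))
  net <- network_from_edges(dplyr::bind_rows(edges, extra))
  mem <- tibble::tibble(feature_id = c("hub", "m1a", "m1b", "m2a", "m2b"),
                        module = c(1L, 1L, 1L, 2L, 2L))
  roles <- node_roles(net, mem)
  expect_equal(roles$pi[roles$feature_id == "hub"], 0.5)
})

test_that("role classification honors the threshold boundaries inclusively", {
  singleton_net <- network_from_edges(tibble::tibble(feature_a = "a", feature_b = "b"))
  mem <- tibble::tibble(feature_id = c("a", "b"), module = 1:2)
  base <- node_roles(singleton_net, mem)
  expect_true(all(base$role == "peripheral"))
  expect_true(all(base$zi == 0))          # singleton modules: Zi = 0 by convention

  expect_equal(as.character(classify_roles(2.5, 0.62)), "peripheral")
  expect_equal(as.character(classify_roles(3.0, 0.7)), "network_hub")
  expect_equal(as.character(classify_roles(0, 0.63)), "connector")
  expect_equal(as.character(classify_roles(2.6, 0.1)), "module_hub")
  expect_equal(as.character(classify_roles(2.5000001, 0.62)), "module_hub")
})

test_that("a planted within-module star is a module hub; keystone flags follow", {
  # module 1: hub wired to 11 spokes that are otherwise sparsely connected
  spokes <- sprintf("s%02d", 1:11)
  edges <- dplyr::bind_rows(
    tibble::tibble(feature_a = "hub", feature_b = spokes),
    tibble::tibble(feature_a = spokes[1:10], feature_b = spokes[2:11]),
    tibble::tibble(feature_a = c("o1", "o2", "o3"), feature_b = c("o2", "o3", "o1")))
  net <- network_from_edges(edges)
  mem <- tibble::tibble(feature_id = c("hub", spokes, "o1", "o2", "o3"),
                        module = c(rep(1L, 12), rep(2L, 3)))
  roles <- node_roles(net, mem)
  hub <- roles[roles$feature_id == "hub", ]
  expect_gt(hub$zi, 2.5)
  expect_equal(as.character(hub$role), "module_hub")
  expect_true(hub$keystone)
  expect_false(any(roles$keystone[roles$role == "peripheral"]))
  expect_equal(sum(role_percentages(roles)$n), nrow(roles))
})

test_that("role classification is invariant to node relabeling", {
  net <- random_network(10, 0.45, seed = 55)
  mod <- detect_modules(net, seed = 3)
  roles <- node_roles(net, mod)
  # relabel nodes by permuting ids consistently in edges and membership
  ids <- net$nodes$feature_id
  new_ids <- setNames(sprintf("R%02d", seq_along(ids)), ids)
  edges2 <- tibble::tibble(feature_a = unname(new_ids[net$edges$feature_a]),
                           feature_b = unname(new_ids[net$edges$feature_b]))
  net2 <- network_from_edges(edges2)
  mem2 <- tibble::tibble(feature_id = unname(new_ids[mod$membership$feature_id]),
                         module = mod$membership$module)
  roles2 <- node_roles(net2, mem2)
  m <- match(unname(new_ids[roles$feature_id]), roles2$feature_id)
  expect_equal(roles$zi, roles2$zi[m])
  expect_equal(roles$pi, roles2$pi[m])
  expect_equal(as.character(roles$role), as.character(roles2$role[m]))
})

test_that("keystone summary reports shares to two decimals and conserves 100%", {
  roles <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:50),
    role = factor(c(rep("connector", 42), rep("module_hub", 1), rep("peripheral", 7)),
                  levels = c("peripheral", "connector", "module_hub", "network_hub")),
    keystone = c(rep(TRUE, 43), rep(FALSE, 7)),
    label = c(rep("USCgamma", 32), rep("other", 18)))
  ks <- keystone_summary(roles)
  expect_equal(ks$share_percent[ks$label == "USCgamma"], 74.42)  # 32 of 43
  expect_equal(sum(ks$share_percent), 100, tolerance = 0.02)

  one <- roles; one$label <- "USCgamma"
  expect_equal(keystone_summary(one)$share_percent, 100)

  none <- roles; none$keystone <- FALSE
  expect_warning(out <- keystone_summary(none), "no keystone")
  expect_equal(nrow(out), 0)
})

test_that("keystone subnetwork is the focal nodes plus first neighbors", {
  tg <- toy_role_graph()
  roles <- node_roles(tg$net, tg$mem)
  roles$keystone <- TRUE                # treat all as keystone for the geometry check
  sub <- keystone_subnetwork(tg$net, roles, "e")
  nbrs <- igraph::neighbors(tg$net$graph, "e")$name
  expect_setequal(sub$nodes$feature_id, union("e", nbrs))

  all_sub <- keystone_subnetwork(tg$net, roles, roles$feature_id)
  expect_setequal(all_sub$nodes$feature_id, roles$feature_id)
  expect_equal(igraph::ecount(all_sub$graph), igraph::ecount(tg$net$graph))

  expect_error(keystone_subnetwork(tg$net, roles, "missing_label"), "no keystone")
})
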
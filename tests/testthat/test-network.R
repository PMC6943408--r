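# Exhaustive shortest-path oracle (Floyd-Warshall) for small unweighted
# graphs, independent of igraph.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

test_that("top-feature selection keeps the n most abundant genera", {
  cfg <- sim_config(seed = 71)
  mb <- simulate_microbiome(cfg)
  top <- select_top_features(mb$counts, mb$taxonomy, "genus", n = 50)
  expect_equal(ncol(top), 50)
  agg <- aggregate_taxa(mb$counts, mb$taxonomy, "genus")
  tot <- sort(colSums(agg), decreasing = TRUE)
  expect_true(min(colSums(top)) >= max(tot[-(1:50)]))
  expect_message(select_top_features(toy_otu(), n = 50), "available")
})

test_that("network edges pass both the correlation and significance cuts", {
  cfg <- sim_config(seed = 72)
  mb <- simulate_microbiome(cfg)
  top <- select_top_features(mb$counts, mb$taxonomy, "genus", n = 50)
  net <- build_network(top, rho_cut = 0.6, p_cut = 0.01)
  expect_s3_class(net, "co_network")
  expect_true(all(abs(net$edges$rho) > 0.6))
  expect_true(all(net$edges$p <= 0.01))
  expect_identical(net$edges$sign,
                   ifelse(net$edges$rho > 0, "positive", "negative"))
  # each surviving edge reproduces spearman_test on the raw columns
  for (k in seq_len(min(5, nrow(net$edges)))) {
    st <- spearman_test(top[, net$edges$source[k]],
                        top[, net$edges$target[k]])
    expect_equal(st$rho, net$edges$rho[k])
    expect_equal(st$p, net$edges$p[k])
  }
  # a stricter rho cut can only shrink the edge set
  net2 <- build_network(top, rho_cut = 0.8, p_cut = 0.01)
  expect_lte(nrow(net2$edges), nrow(net$edges))
})

test_that("constant taxa are excluded from the network with a warning", {
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
  x <- cbind(x, flat = 3)
  expect_warning(net <- build_network(x, rho_cut = 0.5, p_cut = 0.5),
                 "constant")
  expect_false("flat" %in% net$nodes$taxon)
})

test_that("betweenness, diameter and path length match the oracle on a small graph", {
  # path graph a-b-c-d-e plus chord b-d: hand-checkable topology,
  # supplied as a hand-built co_network object
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                 c("b", "d"))
  nodes <- data.frame(taxon = letters[1:5], phylum = NA_character_,
                      mean_abundance = 1, stringsAsFactors = FALSE)
  ed <- data.frame(source = edges[, 1], target = edges[, 2],
                   rho = 0.9, p = 0.001, sign = "positive",
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  net <- structure(list(nodes = nodes, edges = ed, graph = g,
                        rho_cut = 0.6, p_cut = 0.01),
                   class = "co_network")
  met <- network_metrics(net, major_module_min = 10, keystone_k = 3)
  adj <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- 1
    adj[edges[k, 2], edges[k, 1]] <- 1
  }
  sp <- floyd_warshall(adj)
  expect_equal(met$diameter, max(sp))
  expect_equal(met$average_path_length, mean(sp[upper.tri(sp)]))
  # betweenness by hand: every shortest path is unique here;
  # b carries (a,c), (a,d), (a,e); d carries (a,e), (b,e), (c,e)
  bm <- met$node_metrics
  expect_equal(bm$betweenness[bm$taxon == "b"], 3)
  expect_equal(bm$betweenness[bm$taxon == "d"], 3)
  expect_equal(bm$betweenness[bm$taxon == "a"], 0)
  expect_setequal(met$keystone_taxa[1:2], c("b", "d"))
  expect_equal(met$transitivity,
               igraph::transitivity(g, type = "global"))
})

test_that("two separated cliques give modularity 1/2 and two modules", {
  # two disjoint 5-cliques: greedy modularity must find both, and the
  # analytic modularity of k equal cliques is 1 - 1/k = 0.5
  make_clique_edges <- function(members) {
    cmb <- t(combn(members, 2))
    data.frame(source = cmb[, 1], target = cmb[, 2], rho = 0.9, p = 1e-4,
               sign = "positive", stringsAsFactors = FALSE)
  }
  ed <- rbind(make_clique_edges(paste0("x", 1:5)),
              make_clique_edges(paste0("y", 1:5)))
  nodes <- data.frame(taxon = c(paste0("x", 1:5), paste0("y", 1:5)),
                      phylum = NA_character_, mean_abundance = 1,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  net <- structure(list(nodes = nodes, edges = ed, graph = g,
                        rho_cut = 0.6, p_cut = 0.01), class = "co_network")
  met <- network_metrics(net, major_module_min = 4)
  expect_equal(met$modularity, 0.5)
  expect_equal(met$n_major_modules, 2)
  expect_equal(met$n_components, 2)
  expect_equal(sort(met$module_sizes, decreasing = TRUE), c(5L, 5L))
  # members of the same clique share a module
  expect_equal(length(unique(met$modules[paste0("x", 1:5)])), 1)
  expect_equal(length(unique(met$modules[paste0("y", 1:5)])), 1)
})

test_that("planted co-abundance modules are recovered from default networks", {
  # module isolation config: design effects off so the only correlation
  # structure is the planted modules
  cfg <- sim_config(seed = 73, species_effect = 0, class_effect = 0,
                    biomarker_fold = 1)
  mb <- simulate_microbiome(cfg)
  top <- select_top_features(mb$counts, mb$taxonomy, "genus", n = 50)
  net <- build_network(top, rho_cut = 0.6, p_cut = 0.01)
  met <- network_metrics(net)
  truth <- mb$truth$modules
  major <- names(truth)[truth %in% which(mb$truth$module_type == "major")]
  got_mod <- met$modules[intersect(major, names(met$modules))]
  # genera of the same planted major module land in the same detected
  # module for the overwhelming majority of members
  for (m in unique(truth[names(got_mod)])) {
    mem <- got_mod[names(truth)[truth == m & names(truth) %in%
                                  names(got_mod)]]
    expect_gte(max(table(mem)) / length(mem), 0.8)
  }
  expect_error(network_metrics(build_network(
    matrix(rnorm(40), 10, 4,
           dimnames = list(paste0("s", 1:10), paste0("t", 1:4))),
    rho_cut = 0.99, p_cut = 1e-9)), "no edges")
})

test_that("graphml export round-trips node and edge counts", {
  cfg <- sim_config(seed = 74)
  mb <- simulate_microbiome(cfg)
  top <- select_top_features(mb$counts, mb$taxonomy, "genus", n = 30)
  net <- build_network(top, rho_cut = 0.6, p_cut = 0.01)
  p <- tempfile(fileext = ".graphml")
  write_graphml(net, p)
  back <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), nrow(net$edges))
})
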
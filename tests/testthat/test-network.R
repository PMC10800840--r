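test_that("network building keeps perfectly concordant taxa and filters by
           prevalence", {
  set.seed(22)
  n <- 30
  base <- sort(runif(n, 1, 99))
  # composition chosen so each taxon's relative abundance is monotone in base
  m <- cbind(t1 = base, t2 = base * 2 + 5, t3 = 100 - base,
             t4 = c(9, rep(0, n - 1)))
  rownames(m) <- sprintf("S%02d", 1:n)
  net <- build_network(as_community(m), min_prevalence = 0.2)
  # t4 present in 1/30 samples: excluded before testing
  expect_false("t4" %in% net$nodes$taxon_id)
  # t1-t2 share rank order: rho = 1 edge retained
  e <- net$edges
  pair <- e[(e$taxon1 == "t1" & e$taxon2 == "t2") |
              (e$taxon1 == "t2" & e$taxon2 == "t1"), ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$rho, 1)
  expect_identical(pair$sign, "positive")

  expect_error(build_network(as_community(m[1:3, ])), "at least 4")
})

test_that("constant taxa are skipped with a warning", {
  set.seed(23)
  m <- cbind(t1 = runif(10, 1, 9), t2 = runif(10, 1, 9), t3 = rep(4, 10))
  rownames(m) <- paste0("S", 1:10)
  # constant relative abundance requires a constant row-sum context; build one
  m <- round(m * 10)
  m[, 3] <- rowSums(m[, 1:2]) # t3 rel abundance constant = 0.5
  expect_warning(net <- build_network(as_community(m), min_prevalence = 0),
                 "constant")
  expect_false("t3" %in% net$nodes$taxon_id)
})

test_that("edge set is invariant to sample order and monotone abundance
           transforms", {
  set.seed(24)
  sig <- matrix(runif(20 * 3, 1, 100), 20, 3)
  m <- cbind(sig, sig + matrix(runif(20 * 3, 0, 5), 20, 3),
             matrix(runif(20 * 6, 1, 100), 20, 6))
  dimnames(m) <- list(sprintf("S%02d", 1:20), paste0("t", 1:12))
  comm <- as_community(round(m))
  net1 <- build_network(comm, r_min = 0.4)
  net2 <- build_network(comm[sample(20), ], r_min = 0.4)
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$taxon1, e$taxon2), pmax(e$taxon1, e$taxon2)))
  }
  expect_identical(key(net1), key(net2))

  # per-sample depth rescaling cancels in the internal total-sum scaling,
  # and spearman ignores any remaining monotone distortion of magnitudes
  m <- comm_matrix(comm)
  net3 <- build_network(as_community(m * runif(20, 1, 50)), r_min = 0.4)
  expect_gt(nrow(net1$edges), 0)
  expect_identical(key(net1), key(net3))
})

test_that("topology metrics are exact on hand-built graphs", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  topo <- network_topology(as_co_network(tri))
  expect_equal(topo$avg_clustering, 1)
  expect_equal(topo$avg_path_length, 1)
  expect_equal(topo$avg_degree, 2)

  path <- igraph::make_graph(~ a - b, b - c)
  topo2 <- network_topology(as_co_network(path))
  expect_equal(topo2$avg_clustering, 0)
  expect_equal(topo2$avg_path_length, 4 / 3)

  # two components: path length on the larger, coverage reported
  two <- igraph::make_graph(~ a - b, b - c, a - c, d - e)
  topo3 <- network_topology(as_co_network(two))
  expect_equal(topo3$largest_component, 3L)
  expect_equal(topo3$component_coverage, 3 / 5)
  expect_equal(topo3$avg_path_length, 1)

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- c("a", "b", "c")
  topo4 <- network_topology(as_co_network(empty))
  expect_true(topo4$empty)
})

test_that("module detection splits disjoint cliques and is seed-stable", {
  cl1 <- expand.grid(a = paste0("x", 1:4), b = paste0("x", 1:4))
  cl1 <- cl1[as.integer(cl1$a) < as.integer(cl1$b), ]
  cl2 <- expand.grid(a = paste0("y", 1:4), b = paste0("y", 1:4))
  cl2 <- cl2[as.integer(cl2$a) < as.integer(cl2$b), ]
  g <- igraph::graph_from_data_frame(rbind(cl1, cl2), directed = FALSE)
  net <- as_co_network(g)
  mods <- detect_modules(net, seed = 3)
  expect_equal(length(unique(mods$module)), 2)
  split_by <- split(mods$taxon_id, mods$module)
  expect_true(setequal(split_by[[1]], paste0("x", 1:4)) ||
                setequal(split_by[[1]], paste0("y", 1:4)))
  expect_identical(detect_modules(net, seed = 3), mods)

  single <- igraph::make_graph(~ a - b)
  net1 <- as_co_network(single)
  m1 <- detect_modules(net1, seed = 1)
  expect_lte(length(unique(m1$module)), 2)
  expect_true(is.finite(attr(m1, "modularity")))
})

test_that("zi-pi roles match the worked examples and the brute-force oracle", {
  # star inside module 1 plus a bridge node splitting 2/2 across modules
  edges <- rbind(
    data.frame(a = "hub", b = paste0("m1_", 1:6)),
    data.frame(a = "m1_1", b = "m1_2"),
    data.frame(a = "bridge", b = c("m1_1", "m1_2", "m2_1", "m2_2")),
    data.frame(a = "m2_1", b = "m2_2"),
    data.frame(a = "m2_1", b = "m2_3"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- as_co_network(g)
  mods <- tibble::tibble(
    taxon_id = igraph::V(g)$name,
    module = ifelse(grepl("^m2", igraph::V(g)$name), 2L, 1L))
  mods$module[mods$taxon_id == "bridge"] <- 1L
  roles <- zi_pi(net, mods)
  bridge <- roles[roles$taxon_id == "bridge", ]
  expect_equal(bridge$pi, 0.5)  # degree 4 split 2/2 -> 1 - 2*(0.5^2)
  hub <- roles[roles$taxon_id == "hub", ]
  expect_equal(hub$pi, 0)       # all links inside its own module

  # oracle agreement on random planted-module graphs
  for (seed in c(31, 32)) {
    set.seed(seed)
    n <- 30
    mod <- sample(1:3, n, replace = TRUE)
    pm <- ifelse(outer(mod, mod, "=="), 0.5, 0.08)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, pm[upper.tri(pm)])
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    net <- as_co_network(g)
    mods <- tibble::tibble(taxon_id = paste0("v", 1:n), module = mod)
    roles <- zi_pi(net, mods)
    ref <- oracle_zipi(adj[roles$taxon_id, roles$taxon_id],
                       mods$module[match(roles$taxon_id, mods$taxon_id)])
    expect_lt(max(abs(roles$zi - ref$zi)), 1e-10)
    expect_lt(max(abs(roles$pi - ref$pi)), 1e-10)
  }
})

test_that("keystone calls follow the zi >= 2.5 and/or pi >= 0.62 rule", {
  # hand-tuned fake: inject role table thresholds directly through a graph
  # with a clear hub
  g <- igraph::make_star(12, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("n", 1:12)
  net <- as_co_network(g)
  mods <- tibble::tibble(taxon_id = paste0("n", 1:12), module = 1L)
  roles <- zi_pi(net, mods)
  centre <- roles[roles$taxon_id == "n1", ]
  expect_gt(centre$zi, 2.5)
  expect_identical(centre$role, "module_hub")
  expect_true(centre$keystone)
  expect_true(all(!roles$keystone[roles$zi < 2.5 & roles$pi < 0.62]))
})
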
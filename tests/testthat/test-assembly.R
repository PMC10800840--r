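three_leaf_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("betaMNTD matches hand-computed values on the three-leaf tree", {
  tree <- three_leaf_tree()
  pd <- phylo_distances(tree)
  # disjoint single-taxon communities: d(A,C) = 4 both ways
  m <- rbind(S1 = c(1, 0, 0), S2 = c(0, 0, 1))
  colnames(m) <- c("A", "B", "C")
  b <- beta_mntd(as_community(m), pd)
  expect_equal(b["S1", "S2"], 4)

  # {A: .5, B: .5} vs {A: 1}: 0.5*(0.5*0 + 0.5*2 + 1*0) = 0.5
  m2 <- rbind(S1 = c(1, 1, 0), S2 = c(2, 0, 0))
  colnames(m2) <- c("A", "B", "C")
  b2 <- beta_mntd(as_community(m2), pd)
  expect_equal(b2["S1", "S2"], 0.5)

  # identical communities
  m3 <- rbind(S1 = c(3, 1, 2), S2 = c(3, 1, 2))
  colnames(m3) <- c("A", "B", "C")
  expect_equal(beta_mntd(as_community(m3), pd)["S1", "S2"], 0)
})

test_that("betaMNTD agrees exactly with the brute-force oracle and picante", {
  for (seed in c(5, 6, 7)) {
    comm <- random_comm(6, 10, seed = seed)
    tree <- simulate_tree(10, seed = seed)
    pd <- phylo_distances(tree)
    m <- comm_matrix(comm)
    D <- unclass(pd)[colnames(m), colnames(m)]
    for (weighted in c(TRUE, FALSE)) {
      ours <- beta_mntd(comm, pd, weighted = weighted)
      expect_lt(max(abs(unclass(ours) - oracle_bmntd(m, D, weighted))), 1e-10)
    }
    if (requireNamespace("picante", quietly = TRUE)) {
      ref <- as.matrix(picante::comdistnt(m, D, abundance.weighted = TRUE))
      ours <- beta_mntd(comm, pd, weighted = TRUE)
      expect_lt(max(abs(unclass(ours) - ref[rownames(m), rownames(m)])), 1e-10)
    }
  }
})

test_that("betaNTI centers correctly and handles degenerate nulls", {
  # star phylogeny: every taxa shuffle leaves betaMNTD unchanged
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- rbind(S1 = c(1, 1, 0, 0), S2 = c(0, 0, 1, 1))
  colnames(m) <- c("A", "B", "C", "D")
  expect_warning(z <- bnti(as_community(m), star, n_null = 49, seed = 1),
                 "zero null spread")
  expect_true(is.na(z["S1", "S2"]))

  # invariance to taxon relabeling with matched tree relabels
  comm <- random_comm(5, 8, seed = 9)
  tree <- simulate_tree(8, seed = 9)
  z1 <- suppressWarnings(bnti(comm, tree, n_null = 99, seed = 4))
  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  comm_p <- comm[, c(1, 1 + perm)]
  z2 <- suppressWarnings(bnti(comm_p, tree, n_null = 99, seed = 4))
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-12)
})

test_that("betaNTI detects variable selection between env clusters", {
  tree <- simulate_tree(100, seed = 7)
  sc <- assembly_scenario(n_taxa = 100, reads_per_sample = 1000,
                          selection_strength = 5,
                          niche_conservatism_sigma = 1, seed = 7)
  env <- rep(c(-1.5, 1.5), each = 10)
  comm <- simulate_selection(sc, tree, env)
  z <- bnti(comm, tree, n_null = 199, seed = 1)
  between <- outer(env, env, "!=")[upper.tri(z)]
  zz <- z[upper.tri(z)]
  expect_gt(mean(zz[between] > 2, na.rm = TRUE), 0.5)
})

test_that("RCbray is symmetric, bounded, seed-stable, and centred on
           data generated by its own null process", {
  pool <- {
    set.seed(51)
    p <- rlnorm(40, 0, 1); p / sum(p)
  }
  m <- make_null_process_communities(30, pool, richness = 25, total = 200,
                                     occupancy_weight = rep(1, 40), seed = 52)
  comm <- as_community(m)
  rc <- raup_crick_bray(comm, n_null = 299, seed = 3)
  expect_true(all(abs(rc) <= 1))
  expect_equal(unclass(rc), t(unclass(rc)), ignore_attr = TRUE)
  expect_identical(unclass(raup_crick_bray(comm, n_null = 299, seed = 3)),
                   unclass(rc))
  expect_lt(abs(mean(rc[upper.tri(rc)])), 0.15)

  expect_error(raup_crick_bray(as_community(comm_matrix(comm) / 3)), "integer")
})

test_that("the five-process rule maps the full (betaNTI, RC) grid exactly", {
  thr <- process_thresholds()
  grid <- tibble::tribble(
    ~bnti, ~rc,    ~expected,
    -3,     0.99,  "homogeneous_selection",  # selection takes precedence
    -2.01,  0,     "homogeneous_selection",
     3,    -0.99,  "variable_selection",
     2.01,  0.5,   "variable_selection",
     0.5,  -0.99,  "homogenizing_dispersal",
    -1,     0.97,  "dispersal_limitation",
     1,     0.2,   "drift",
     0,     0,     "drift",
     1.99,  0.94,  "drift",
    -1.99, -0.94,  "drift")
  expect_identical(ecoassembly:::classify_pair(grid$bnti, grid$rc, thr),
                   grid$expected)

  # fractions partition: sum to 100 per group
  n <- 6
  bz <- matrix(rnorm(n * n), n, n); bz <- (bz + t(bz)) / 2; diag(bz) <- 0
  rz <- matrix(runif(n * n, -1, 1), n, n); rz <- (rz + t(rz)) / 2; diag(rz) <- 0
  labs <- paste0("S", 1:n)
  cls <- classify_processes(
    ecoassembly:::new_pairwise_matrix(bz, labs, "beta_nti"),
    ecoassembly:::new_pairwise_matrix(rz, labs, "raup_crick_bray"),
    thr, tibble::tibble(sample_id = labs, group = rep(c("x", "y"), each = 3)))
  sums <- tapply(cls$fractions$percent, cls$fractions$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("NCM predicted frequency is monotone, saturating, and banded", {
  sc <- assembly_scenario(n_taxa = 150, reads_per_sample = 1000,
                          migration_rate = 0.15, seed = 14)
  comm <- simulate_neutral(sc, n_samples = 40)
  fit <- fit_ncm(comm)
  tx <- dplyr::arrange(fit$taxa, mean_relative_abundance)
  expect_true(all(diff(tx$predicted_frequency) >= -1e-12))
  expect_true(all(tx$predicted_frequency >= 0 & tx$predicted_frequency <= 1))
  expect_setequal(unique(tx$band), intersect(c("above", "within", "below"),
                                             unique(tx$band)))
  # abundant taxa at large Nm have predicted frequency near 1
  expect_gt(max(tx$predicted_frequency), 0.99)
  # the band covers most taxa under the generating model
  expect_gt(mean(tx$band == "within"), 0.5)

  m <- comm_matrix(comm)
  expect_error(fit_ncm(as_community(m[, 1:5])), "at least 10")
})

test_that("pNST is clamped, reproducible, and rejects tiny groups", {
  tree <- simulate_tree(30, seed = 16)
  sc <- assembly_scenario(n_taxa = 30, reads_per_sample = 300,
                          migration_rate = 0.3, seed = 16)
  comm <- simulate_neutral(sc, n_samples = 9)
  meta <- tibble::tibble(sample_id = comm$sample_id,
                         group = rep(c("a", "b", "c"), each = 3))
  ns <- pnst(comm, tree, meta, n_null = 99, seed = 2)
  expect_true(all(ns$pairs$pnst >= 0 & ns$pairs$pnst <= 1))
  ns2 <- pnst(comm, tree, meta, n_null = 99, seed = 2)
  expect_identical(ns$group_means, ns2$group_means)

  meta_bad <- tibble::tibble(sample_id = comm$sample_id,
                             group = c(rep("a", 7), "b", "b"))
  expect_error(pnst(comm, tree, meta_bad, n_null = 9, seed = 1), "fewer than 3")
})
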
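test_that("alpha diversity matches closed-form values", {
  m <- rbind(S1 = c(5, 3, 1, 1, 2),
             S2 = c(4, 4, 4, 4, 0),
             S3 = c(7, 0, 0, 0, 0))
  colnames(m) <- paste0("t", 1:5)
  out <- alpha_diversity(as_community(m))

  # S1: F1 = 2, F2 = 1 -> bias-corrected chao1 = 5 + 2*1/(2*2) = 5.5
  expect_equal(out$richness[1], 5L)
  expect_equal(out$chao1[1], 5.5)
  # uniform over 4 taxa
  expect_equal(out$shannon[2], log(4), tolerance = 1e-12)
  expect_equal(out$simpson[2], 0.75, tolerance = 1e-12)
  expect_equal(out$pielou[2], 1, tolerance = 1e-12)
  # single taxon
  expect_equal(out$shannon[3], 0)
  expect_equal(out$simpson[3], 0)
  expect_true(all(out$chao1 >= out$richness))

  expect_error(alpha_diversity(as_community(m / 2)), "integer")
})

test_that("classic chao1 form differs from bias-corrected as expected", {
  x <- c(5, 3, 1, 1, 2)  # F1 = 2, F2 = 1
  m <- rbind(S1 = x); colnames(m) <- paste0("t", 1:5)
  classic <- alpha_diversity(as_community(m), chao1_form = "classic")
  expect_equal(classic$chao1, 5 + 4 / 2)
})

test_that("beta distances match their formulas and degenerate cases", {
  m <- rbind(S1 = c(6, 0, 4), S2 = c(2, 2, 0), S3 = c(6, 0, 4))
  colnames(m) <- c("a", "b", "c")
  comm <- as_community(m)
  bc <- beta_distance(comm, "bray_curtis")
  expect_equal(bc["S1", "S2"], 1 - 4 / 14, tolerance = 1e-12)
  # presence sets {a,c} vs {a,b}: jaccard = 1 - 1/3
  jc <- beta_distance(comm, "jaccard")
  expect_equal(jc["S1", "S2"], 1 - 1 / 3, tolerance = 1e-12)
  for (metric in c("bray_curtis", "jaccard", "euclidean", "manhattan")) {
    d <- beta_distance(comm, metric)
    expect_equal(d["S1", "S3"], 0)
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_true(all(diag(d) == 0))
  }
})

test_that("bray-curtis is scale-invariant when sequencing depths are equal", {
  comm <- random_comm(6, 12, seed = 31)
  m <- comm_matrix(comm)
  m <- round(m * (60 / rowSums(m)))  # near-equal depths
  m[, 1] <- m[, 1] + (60 - rowSums(m))  # exact equal depths
  comm_eq <- as_community(m)
  raw <- beta_distance(comm_eq, "bray_curtis")
  rel <- beta_distance(to_relative_abundance(comm_eq), "bray_curtis")
  expect_equal(unclass(raw), unclass(rel), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("upgma agglomerates by average linkage with height = d/2", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(attr(tree, "merge_heights"), c(1, 4))
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 8)

  # two samples: single merge at d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(attr(upgma(d2), "merge_heights"), 1.5)

  # equal distances: deterministic under the lexicographic tie rule
  de <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])); diag(de) <- 0
  t1 <- upgma(de); t2 <- upgma(de)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(abs(attr(t1, "merge_heights") - 0.5) < 1e-12))

  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))), "NaN|NA")
})

test_that("upgma agrees with hclust average linkage on generic matrices", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 7
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
    tree <- upgma(d)
    hc <- stats::hclust(as.dist(d), method = "average")
    # upgma cophenetic distance = 2 * merge height = hclust cophenetic height
    expect_equal(ape::cophenetic.phylo(tree)[paste0("S", 1:n), paste0("S", 1:n)],
                 as.matrix(stats::cophenetic(hc))[paste0("S", 1:n), paste0("S", 1:n)],
                 tolerance = 1e-9)
    expect_true(all(diff(attr(tree, "merge_heights")) >= -1e-12))
  }
})

test_that("beta partitioning reproduces the worked set-algebra examples", {
  # nested pair: A = {a,b,c,d}, B = {a,b}
  m <- rbind(A = c(1, 1, 1, 1), B = c(1, 1, 0, 0))
  colnames(m) <- letters[1:4]
  bp <- partition_beta(as_community(m), "baselga_sorensen")
  expect_equal(bp$replacement["A", "B"], 0)
  expect_equal(bp$total["A", "B"], 2 / 6, tolerance = 1e-12)
  expect_equal(bp$richness_difference["A", "B"], 2 / 6, tolerance = 1e-12)

  # A = {a,b}, B = {a,c} under podani: a=1, b=1, c=1
  m2 <- rbind(A = c(1, 1, 0), B = c(1, 0, 1))
  colnames(m2) <- letters[1:3]
  bp2 <- partition_beta(as_community(m2), "podani_jaccard")
  expect_equal(bp2$total["A", "B"], 2 / 3, tolerance = 1e-12)
  expect_equal(bp2$replacement["A", "B"], 2 / 3, tolerance = 1e-12)
  expect_equal(bp2$richness_difference["A", "B"], 0)

  # identical samples: all components zero
  m3 <- rbind(A = c(1, 1, 0), B = c(1, 1, 0))
  colnames(m3) <- letters[1:3]
  for (fam in c("baselga_sorensen", "podani_jaccard")) {
    bp3 <- partition_beta(as_community(m3), fam)
    expect_equal(max(abs(bp3$total)), 0)
  }
})

test_that("partition components are additive and within [0,1] on random data", {
  for (seed in c(11, 12)) {
    comm <- random_comm(6, 15, seed = seed)
    for (fam in c("baselga_sorensen", "podani_jaccard")) {
      bp <- partition_beta(comm, fam)
      expect_lt(max(abs(bp$replacement + bp$richness_difference - bp$total)), 1e-10)
      expect_true(all(bp$total >= 0 & bp$total <= 1))
      expect_true(all(bp$replacement >= -1e-15 & bp$replacement <= 1))
      expect_true(all(bp$richness_difference >= -1e-15 & bp$richness_difference <= 1))
    }
  }
})

test_that("group summaries average within-group pairs only", {
  comm <- random_comm(8, 20, seed = 41)
  groups <- tibble::tibble(sample_id = comm$sample_id,
                           group = rep(c("w", "s"), each = 4))
  bp <- partition_beta(comm, "baselga_sorensen", groups = groups)
  expect_setequal(bp$group_summary$group, c("w", "s"))
  # replacement% + richness% = 100
  expect_equal(bp$group_summary$replacement_pct +
                 bp$group_summary$richness_difference_pct,
               c(100, 100), tolerance = 1e-9)
  # check one group by hand
  ids <- groups$sample_id[groups$group == "w"]
  sel <- upper.tri(matrix(0, 4, 4))
  mt <- mean(bp$total[ids, ids][sel])
  mr <- mean(bp$replacement[ids, ids][sel])
  row <- bp$group_summary[bp$group_summary$group == "w", ]
  expect_equal(row$replacement_pct, 100 * mr / mt, tolerance = 1e-9)
})
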
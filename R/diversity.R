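#' Per-sample alpha diversity
#'
#' Computes richness, Chao1, ACE, Shannon (natural log), Simpson
#' (1 - sum p^2), and Pielou evenness for every sample. Chao1 uses the
#' bias-corrected form `S + F1 (F1 - 1) / (2 (F2 + 1))` by default (defined
#' even when no doubletons exist); the classic form `S + F1^2 / (2 F2)` is
#' available behind `chao1_form = "classic"`. ACE uses the usual rare-taxon
#' cutoff of 10. Chao1/ACE require integer counts.
#'
#' @param comm Community tibble of counts.
#' @param chao1_form `"bias_corrected"` (default) or `"classic"`.
#' @return Tibble with one row per sample.
#' @export
alpha_diversity <- function(comm, chao1_form = c("bias_corrected", "classic")) {
  chao1_form <- match.arg(chao1_form)
  m <- comm_matrix(comm)
  if (any(rowSums(m) == 0)) {
    stop("empty sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    stop("chao1/ACE require integer counts")
  }
  m <- round(m)
  est <- t(apply(m, 1, chao_ace_one, chao1_form = chao1_form))
  rel <- m / rowSums(m)
  shannon <- apply(rel, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  richness <- rowSums(m > 0)
  tibble::tibble(
    sample_id = rownames(m),
    richness = as.integer(richness),
    chao1 = unname(est[, 1]),
    ace = unname(est[, 2]),
    shannon = unname(shannon),
    simpson = unname(apply(rel, 1, function(p) 1 - sum(p^2))),
    pielou = unname(ifelse(richness > 1, shannon / log(richness), NA_real_)))
}

# Chao1 and ACE for one count vector; vegan::estimateR supplies both
# estimators, the classic Chao1 falls back to the closed form.
chao_ace_one <- function(x, chao1_form) {
  est <- suppressWarnings(vegan::estimateR(x))
  chao1 <- est[["S.chao1"]]
  if (chao1_form == "classic") {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
  }
  c(chao1 = chao1, ace = est[["S.ACE"]])
}

#' Pairwise beta-diversity distances
#'
#' Bray-Curtis, Jaccard (on presence/absence), Euclidean, or Manhattan
#' dissimilarities between samples, via [vegan::vegdist()].
#'
#' @param comm Community tibble.
#' @param metric One of `"bray_curtis"`, `"jaccard"`, `"euclidean"`,
#'   `"manhattan"`.
#' @return A `pairwise_matrix`.
#' @export
beta_distance <- function(comm,
                          metric = c("bray_curtis", "jaccard", "euclidean",
                                     "manhattan")) {
  metric <- match.arg(metric)
  m <- comm_matrix(comm)
  if (metric %in% c("bray_curtis", "jaccard") && any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  d <- switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    jaccard = vegan::vegdist(m > 0, method = "jaccard"),
    euclidean = vegan::vegdist(m, method = "euclidean"),
    manhattan = vegan::vegdist(m, method = "manhattan"))
  new_pairwise_matrix(as.matrix(d), rownames(m), metric)
}

#' UPGMA (average-linkage) clustering of a dissimilarity matrix
#'
#' Agglomerates by unweighted average linkage with node height = merge
#' distance / 2, so tip-to-node path lengths are ultrametric. Ties in the
#' minimum inter-cluster distance are broken deterministically by the
#' lexicographic order of the clusters' smallest member labels.
#'
#' @param dist A `pairwise_matrix` (or square symmetric matrix with labels).
#' @return An [ape::phylo] dendrogram with branch lengths.
#' @export
upgma <- function(dist) {
  d <- as.matrix(dist)
  if (anyNA(d)) stop("NaN/NA in distance matrix")
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2) stop("need at least 2 items")
  # active clusters: newick fragment, height, size, representative label
  cl <- lapply(seq_len(n), function(i) {
    list(newick = labs[i], height = 0, size = 1, rep = labs[i])
  })
  act <- seq_len(n)
  heights <- numeric(0)
  while (length(act) > 1) {
    best <- NULL
    for (ai in seq_along(act)) {
      for (bi in seq_along(act)) {
        if (bi <= ai) next
        i <- act[ai]; j <- act[bi]
        key <- sort(c(cl[[i]]$rep, cl[[j]]$rep))
        cand <- list(d = d[i, j], key = key, i = i, j = j)
        if (is.null(best) || cand$d < best$d - 1e-15 ||
            (abs(cand$d - best$d) <= 1e-15 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    heights <- c(heights, h)
    newick <- sprintf("(%s:%.12g,%s:%.12g)",
                      cl[[i]]$newick, h - cl[[i]]$height,
                      cl[[j]]$newick, h - cl[[j]]$height)
    # unweighted average linkage update on the stored matrix
    ni <- cl[[i]]$size; nj <- cl[[j]]$size
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (ni * d[i, k] + nj * d[j, k]) / (ni + nj)
    }
    cl[[i]] <- list(newick = newick, height = h, size = ni + nj,
                    rep = min(cl[[i]]$rep, cl[[j]]$rep))
    act <- setdiff(act, j)
  }
  tree <- ape::read.tree(text = paste0(cl[[act]]$newick, ";"))
  attr(tree, "merge_heights") <- heights
  tree
}

#' Partition beta diversity into replacement and richness-difference parts
#'
#' Presence/absence decomposition of pairwise dissimilarity. Two families:
#' `"baselga_sorensen"` — total = Sorensen, replacement = Simpson turnover
#' `min(b,c) / (a + min(b,c))`, richness difference = total - replacement
#' (nestedness-resultant); `"podani_jaccard"` — total = Jaccard, replacement
#' = `2 min(b,c) / (a+b+c)`, richness difference = `|b-c| / (a+b+c)`. The two
#' families disagree numerically, so the family is a mandatory explicit
#' argument. Group summaries (percent of dissimilarity due to each component,
#' `mean component / mean total * 100` over within-group pairs) are computed
#' when `groups` is given.
#'
#' @param comm Community tibble.
#' @param family `"baselga_sorensen"` or `"podani_jaccard"`.
#' @param groups Optional metadata tibble (`sample_id`, `group`) for
#'   within-group percentage summaries.
#' @return List of class `"beta_partition"` with `total`, `replacement`,
#'   `richness_difference` pairwise matrices and a `group_summary` tibble.
#' @export
partition_beta <- function(comm, family = c("baselga_sorensen", "podani_jaccard"),
                           groups = NULL) {
  family <- match.arg(family)
  pa <- comm_matrix(comm) > 0
  labs <- rownames(pa)
  n <- nrow(pa)
  tot <- repl <- rich <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sum(pa[i, ] & pa[j, ])
      b <- sum(pa[i, ] & !pa[j, ])
      cc <- sum(!pa[i, ] & pa[j, ])
      if (family == "baselga_sorensen") {
        t_ij <- if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
        r_ij <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
        n_ij <- t_ij - r_ij
      } else {
        s <- a + b + cc
        t_ij <- if (s == 0) 0 else (b + cc) / s
        r_ij <- if (s == 0) 0 else 2 * min(b, cc) / s
        n_ij <- if (s == 0) 0 else abs(b - cc) / s
      }
      tot[i, j] <- tot[j, i] <- t_ij
      repl[i, j] <- repl[j, i] <- r_ij
      rich[i, j] <- rich[j, i] <- n_ij
    }
  }
  out <- list(
    family = family,
    total = new_pairwise_matrix(tot, labs, paste0(family, "_total")),
    replacement = new_pairwise_matrix(repl, labs, paste0(family, "_replacement")),
    richness_difference = new_pairwise_matrix(rich, labs,
                                              paste0(family, "_richness_difference")),
    group_summary = NULL)
  if (!is.null(groups)) {
    groups <- validate_metadata(groups)
    gs <- lapply(split(groups$sample_id, groups$group), function(ids) {
      ids <- intersect(ids, labs)
      if (length(ids) < 2) return(NULL)
      sel <- upper.tri(matrix(0, length(ids), length(ids)))
      mt <- mean(out$total[ids, ids][sel])
      tibble::tibble(
        mean_total = mt,
        replacement_pct = 100 * mean(out$replacement[ids, ids][sel]) / mt,
        richness_difference_pct = 100 * mean(out$richness_difference[ids, ids][sel]) / mt)
    })
    out$group_summary <- dplyr::bind_rows(gs, .id = "group")
  }
  structure(out, class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("beta-diversity partition (%s), %d samples\n",
              x$family, nrow(x$total)))
  if (!is.null(x$group_summary)) print(x$group_summary)
  invisible(x)
}

#' Tidy a beta partition into one row per pair
#' @param x A `beta_partition`.
#' @param ... Unused.
#' @return Tibble with pair ids and the three components.
#' @export
tidy.beta_partition <- function(x, ...) {
  tidy.pairwise_matrix(x$total) |>
    dplyr::rename(total = "value") |>
    dplyr::mutate(replacement = upper_vec(x$replacement),
                  richness_difference = upper_vec(x$richness_difference),
                  family = x$family, metric = NULL)
}
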
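#' Cophenetic distances from a rooted tree
#'
#' @param tree An [ape::phylo] tree.
#' @return A `pairwise_matrix` of patristic (cophenetic) distances over tips.
#' @export
phylo_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  new_pairwise_matrix(d[order(rownames(d)), order(rownames(d))],
                      sort(rownames(d)), "cophenetic")
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair (k, l), the abundance-weighted mean phylogenetic
#' distance from each taxon in one community to its nearest taxon in the
#' other:
#' `0.5 * [ sum_i f_ik min_j d_ij + sum_j f_jl min_i d_ij ]`,
#' minima over taxa present in the other community (a taxon present in both
#' contributes distance 0). Relative abundances are computed internally.
#'
#' @param comm Community tibble.
#' @param phylo_dist `pairwise_matrix` of cophenetic distances covering the
#'   table's taxa (see [phylo_distances()]).
#' @param weighted If `FALSE`, taxa are weighted equally (1/richness) instead
#'   of by relative abundance.
#' @return A `pairwise_matrix` of betaMNTD values.
#' @export
beta_mntd <- function(comm, phylo_dist, weighted = TRUE) {
  m <- comm_matrix(comm)
  taxa <- colnames(m)
  if (!all(taxa %in% rownames(phylo_dist))) {
    stop("taxa missing from phylogenetic distances: ",
         paste(utils::head(setdiff(taxa, rownames(phylo_dist)), 5), collapse = ", "))
  }
  if (any(rowSums(m) == 0)) {
    stop("sample(s) with no taxa present: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  f <- if (weighted) m / rowSums(m) else (m > 0) / rowSums(m > 0)
  D <- unclass(phylo_dist)[taxa, taxa]
  b <- bmntd_pairwise(f, D, seq_along(taxa) - 1L)
  new_pairwise_matrix(b, rownames(m), "beta_mntd")
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of [beta_mntd()] against the taxa-shuffle null:
#' tip labels are permuted across the whole tree (equivalently, rows and
#' columns of the cophenetic matrix are permuted jointly), betaMNTD is
#' recomputed for each replicate, and
#' `betaNTI = (observed - mean_null) / sd_null` per sample pair.
#' `|betaNTI| >= 2` signals deterministic selection (negative: homogeneous
#' selection; positive: variable selection). A pair whose null spread is zero
#' (e.g. on a star phylogeny) is reported as `NA` with a warning rather than
#' +/-Inf.
#'
#' @param comm Community tibble.
#' @param tree Tree covering the table's taxa.
#' @param n_null Number of null replicates (default 999).
#' @param seed Integer seed.
#' @param weighted Abundance-weight the betaMNTD (default `TRUE`).
#' @return A `pairwise_matrix` of betaNTI values, with the observed betaMNTD
#'   in attribute `"observed"`.
#' @export
bnti <- function(comm, tree, n_null = 999, seed = 1, weighted = TRUE) {
  m <- comm_matrix(comm)
  m <- m[, sort(colnames(m)), drop = FALSE]  # canonical taxon order: the
  taxa <- colnames(m)                        # null stream is label-invariant
  f <- if (weighted) m / rowSums(m) else (m > 0) / rowSums(m > 0)
  D <- unclass(phylo_distances(tree))
  if (!all(taxa %in% rownames(D))) stop("tree does not cover all taxa")
  D <- D[taxa, taxa]
  nt <- length(taxa)
  obs <- bmntd_pairwise(f, D, seq_len(nt) - 1L)
  perms <- local_seed(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(nt) - 1L, integer(nt)))
  })
  mom <- bmntd_null_moments(f, D, perms)
  mu <- mom$sum / n_null
  sd_null <- sqrt(pmax(mom$sumsq / n_null - mu^2, 0) * n_null / (n_null - 1))
  z <- (obs - mu) / sd_null
  degenerate <- upper.tri(z) & (sd_null < 1e-12)
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) with zero null spread; betaNTI undefined")
    z[sd_null < 1e-12] <- NA_real_
  }
  diag(z) <- 0
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  out <- new_pairwise_matrix(z, rownames(m), "beta_nti")
  attr(out, "observed") <- new_pairwise_matrix(obs, rownames(m), "beta_mntd")
  out
}

#' Bray-Curtis-based Raup-Crick (RCbray)
#'
#' Probabilistic-assembly null: each null sample draws its observed richness
#' of taxa with probability proportional to occurrence frequency across all
#' samples, seeds each drawn taxon with one individual, and distributes the
#' remaining reads multinomially with probability proportional to pooled
#' relative abundance. Per pair,
#' `RC = 2 [ P(null BC < obs BC) + 0.5 P(null BC = obs BC) ] - 1`, bounded in
#' \[-1, 1\] and exactly 0 in expectation under a perfectly exchangeable null
#' (ties carry half weight). Null communities are drawn independently per
#' sample within each replicate, so a full null Bray-Curtis matrix is
#' computed per replicate.
#'
#' @param comm Community tibble of integer counts.
#' @param n_null Number of null replicates (default 999).
#' @param seed Integer seed.
#' @return A `pairwise_matrix` of RCbray values.
#' @export
raup_crick_bray <- function(comm, n_null = 999, seed = 1) {
  m <- comm_matrix(comm)
  if (any(abs(m - round(m)) > 1e-8)) stop("RCbray requires integer counts")
  m <- round(m)
  ns <- nrow(m); nt <- ncol(m)
  rich <- rowSums(m > 0)
  if (any(rich == 0)) stop("sample(s) with no taxa present")
  if (any(rich > nt)) stop("richness exceeds taxon pool")
  tot <- rowSums(m)
  occ <- colSums(m > 0)
  pool <- colSums(m) / sum(m)
  obs_bc <- as.matrix(vegan::vegdist(m, method = "bray"))
  n_less <- n_eq <- matrix(0, ns, ns)
  local_seed(seed, {
    for (r in seq_len(n_null)) {
      null <- matrix(0L, ns, nt)
      for (s in seq_len(ns)) {
        drawn <- sample.int(nt, rich[s], prob = occ)
        cnt <- rep(1L, rich[s])
        extra <- tot[s] - rich[s]
        if (extra > 0) {
          cnt <- cnt + rmultinom(1, extra, pool[drawn])[, 1]
        }
        null[s, drawn] <- cnt
      }
      bc <- as.matrix(vegan::vegdist(null, method = "bray"))
      n_less <- n_less + (bc < obs_bc - 1e-12)
      n_eq <- n_eq + (abs(bc - obs_bc) <= 1e-12)
    }
  })
  rc <- 2 * (n_less + 0.5 * n_eq) / n_null - 1
  diag(rc) <- 0
  new_pairwise_matrix(rc, rownames(m), "raup_crick_bray")
}

#' Thresholds for the five-process classification
#'
#' @param bnti_cut |betaNTI| cut separating deterministic from stochastic
#'   pairs (default 2).
#' @param rc_cut |RCbray| cut separating dispersal processes from drift
#'   (default 0.95).
#' @param pnst_cut pNST value above which stochasticity is called dominant
#'   (default 0.5).
#' @return List of class `"process_thresholds"`.
#' @export
process_thresholds <- function(bnti_cut = 2, rc_cut = 0.95, pnst_cut = 0.5) {
  stopifnot(bnti_cut > 0, rc_cut > 0, pnst_cut > 0, pnst_cut < 1)
  structure(list(bnti_cut = bnti_cut, rc_cut = rc_cut, pnst_cut = pnst_cut),
            class = "process_thresholds")
}

process_levels <- c("homogeneous_selection", "variable_selection",
                    "homogenizing_dispersal", "dispersal_limitation", "drift")

#' Classify sample pairs into the five assembly processes
#'
#' Per pair: `betaNTI < -bnti_cut` -> homogeneous selection;
#' `betaNTI > +bnti_cut` -> variable selection; otherwise
#' `RCbray < -rc_cut` -> homogenizing dispersal,
#' `RCbray > +rc_cut` -> dispersal limitation, else drift. (Selection takes
#' precedence over the RCbray rules.) Pairs with undefined betaNTI are
#' excluded and counted. Fractions are reported pooled over all pairs and
#' per metadata group (within-group pairs); the pooled row is labelled
#' `"pooled"`.
#'
#' @param bnti `pairwise_matrix` from [bnti()].
#' @param rc `pairwise_matrix` from [raup_crick_bray()].
#' @param thresholds A [process_thresholds()].
#' @param metadata Optional metadata tibble (`sample_id`, `group`).
#' @return List of class `"process_classification"` with `pairs` (tibble of
#'   per-pair values and labels) and `fractions` (tibble of percentages per
#'   group, including the pooled row).
#' @export
classify_processes <- function(bnti, rc, thresholds = process_thresholds(),
                               metadata = NULL) {
  rc <- check_shared_labels(bnti, rc)
  labs <- rownames(bnti)
  idx <- which(upper.tri(bnti), arr.ind = TRUE)
  pairs <- tibble::tibble(
    sample1 = labs[idx[, 1]], sample2 = labs[idx[, 2]],
    bnti = bnti[idx], rc_bray = rc[idx])
  pairs$process <- classify_pair(pairs$bnti, pairs$rc_bray, thresholds)
  n_undef <- sum(is.na(pairs$bnti))
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    g <- setNames(as.character(metadata$group), metadata$sample_id)
    pairs$group1 <- unname(g[pairs$sample1])
    pairs$group2 <- unname(g[pairs$sample2])
  }
  frac_of <- function(df, label) {
    df <- df[!is.na(df$process), ]
    if (nrow(df) == 0) return(NULL)
    tb <- table(factor(df$process, levels = process_levels))
    tibble::tibble(group = label, process = names(tb),
                   n_pairs = as.integer(tb),
                   percent = 100 * as.integer(tb) / nrow(df))
  }
  fr <- frac_of(pairs, "pooled")
  if (!is.null(metadata)) {
    within <- pairs[!is.na(pairs$group1) & pairs$group1 == pairs$group2, ]
    per_group <- purrr::imap(split(within, within$group1), frac_of)
    fr <- dplyr::bind_rows(fr, dplyr::bind_rows(per_group))
  }
  structure(list(pairs = pairs, fractions = fr,
                 thresholds = thresholds, n_undefined = n_undef),
            class = "process_classification")
}

classify_pair <- function(bnti, rc, thresholds) {
  dplyr::case_when(
    is.na(bnti) ~ NA_character_,
    bnti < -thresholds$bnti_cut ~ "homogeneous_selection",
    bnti > thresholds$bnti_cut ~ "variable_selection",
    rc < -thresholds$rc_cut ~ "homogenizing_dispersal",
    rc > thresholds$rc_cut ~ "dispersal_limitation",
    TRUE ~ "drift")
}

#' @export
print.process_classification <- function(x, ...) {
  cat(sprintf("process classification: %d pairs (%d undefined)\n",
              nrow(x$pairs), x$n_undefined))
  print(x$fractions)
  invisible(x)
}

#' @rdname classify_processes
#' @param x A `process_classification`.
#' @param ... Unused.
#' @export
tidy.process_classification <- function(x, ...) x$pairs

#' @rdname classify_processes
#' @export
glance.process_classification <- function(x, ...) {
  tidyr::pivot_wider(dplyr::filter(x$fractions, .data$group == "pooled"),
                     id_cols = "group", names_from = "process",
                     values_from = "percent")
}

#' Fit the Sloan neutral community model
#'
#' Relates each taxon's occurrence frequency across samples to its mean
#' relative abundance p. With N the mean read depth and detection limit
#' d = 1/N, the model predicts occurrence frequency
#' `F(p) = 1 - B(d; N m p, N m (1 - p))` (regularized incomplete beta
#' function); the migration rate m is fit by least squares of observed
#' frequency on F. `Nm = N * m` is the reported metacommunity-size x
#' migration product; `R^2 = 1 - SSE/SST` is the fit goodness. The 95%
#' prediction band is the Clopper-Pearson (beta-quantile) binomial interval
#' of the predicted frequency at n = number of samples, and each taxon is
#' flagged above / within / below the band.
#'
#' @param comm Community tibble of counts.
#' @param ci_level Band coverage (default 0.95).
#' @param detection_limit `NULL` for the standard `d = 1/N`; the string
#'   `"multinomial"` for `d = log(2)/N`, the abundance at which multinomial
#'   read sampling detects a taxon with probability 1/2 (appropriate when
#'   occurrence is derived from counts, since `P(detect | x) = 1-(1-x)^N`
#'   is not a sharp threshold at `1/N`); or a numeric override.
#' @return List of class `"ncm_fit"`; see [tidy.ncm_fit()] /
#'   [glance.ncm_fit()].
#' @export
fit_ncm <- function(comm, ci_level = 0.95, detection_limit = NULL) {
  m <- comm_matrix(comm)
  rel <- m / rowSums(m)
  p <- colMeans(rel)
  keep <- p > 0
  if (sum(keep) < 10) stop("need at least 10 taxa with nonzero mean abundance")
  p <- p[keep]
  freq <- colMeans(m[, keep, drop = FALSE] > 0)
  n_reads <- mean(rowSums(m))
  d <- if (is.null(detection_limit)) {
    1 / n_reads
  } else if (identical(detection_limit, "multinomial")) {
    log(2) / n_reads
  } else {
    as.numeric(detection_limit)
  }
  predict_freq <- function(mm) {
    pbeta(d, n_reads * mm * p, n_reads * mm * (1 - p), lower.tail = FALSE)
  }
  sse_of <- function(mm) sum((freq - predict_freq(mm))^2)
  opt <- optimize(sse_of, interval = c(1e-6, 1))
  m_hat <- opt$minimum
  pred <- predict_freq(m_hat)
  sst <- sum((freq - mean(freq))^2)
  r2 <- 1 - opt$objective / sst
  n_samp <- nrow(m)
  alpha <- 1 - ci_level
  lower <- qbeta(alpha / 2, n_samp * pred, n_samp - n_samp * pred + 1)
  upper <- qbeta(1 - alpha / 2, n_samp * pred + 1, n_samp - n_samp * pred)
  band <- dplyr::case_when(freq > upper ~ "above", freq < lower ~ "below",
                           TRUE ~ "within")
  structure(list(
    m = m_hat, N = n_reads, Nm = n_reads * m_hat, r_squared = r2,
    detection_limit = d, ci_level = ci_level, n_samples = n_samp,
    taxa = tibble::tibble(taxon_id = names(p), mean_relative_abundance = unname(p),
                          observed_frequency = unname(freq),
                          predicted_frequency = unname(pred),
                          lower = lower, upper = upper, band = band)),
    class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: m = %.4f, Nm = %.1f, R^2 = %.3f (%d taxa, %d samples)\n",
              x$m, x$Nm, x$r_squared, nrow(x$taxa), x$n_samples))
  print(table(x$taxa$band))
  invisible(x)
}

#' Tidy / glance methods for a Sloan NCM fit
#' @param x An `ncm_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per taxon with observed and predicted
#'   frequencies and band position; `glance()`: one row with m, Nm, R^2.
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @rdname tidy.ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(m = x$m, Nm = x$Nm, N = x$N, r_squared = x$r_squared,
                 detection_limit = x$detection_limit,
                 n_taxa = nrow(x$taxa), n_samples = x$n_samples)
}

#' Phylogenetic normalized stochasticity ratio (pNST)
#'
#' Quantifies the relative importance of stochastic assembly per group from
#' phylogenetic beta diversity. For each within-group sample pair the
#' observed betaMNTD D is compared with its taxa-shuffle null expectation E
#' (same null as [bnti()]); after scaling all values by the largest observed
#' or null betaMNTD (so the maximum dissimilarity is 1), the normalized
#' stochasticity ratio is
#' `D >= E: (Dmax - D) / (Dmax - E)`; `D < E: D / E`,
#' i.e. 1 when the observation matches the null expectation and 0 at the
#' deterministic extremes. Group pNST is the mean over within-group pairs,
#' clamped to \[0, 1\]. Values above 0.5 are conventionally read as
#' stochasticity-dominated assembly.
#'
#' @param comm Community tibble.
#' @param tree Tree covering the taxa.
#' @param metadata Metadata tibble (`sample_id`, `group`); every group needs
#'   at least 3 samples.
#' @param n_null Number of null replicates (default 1000).
#' @param seed Integer seed.
#' @param weighted Abundance-weight betaMNTD (default `TRUE`).
#' @return List of class `"nst_result"` with per-pair values and group means.
#' @export
pnst <- function(comm, tree, metadata, n_null = 1000, seed = 1,
                 weighted = TRUE) {
  metadata <- validate_metadata(metadata)
  m <- comm_matrix(comm)
  counts <- table(metadata$group[metadata$sample_id %in% rownames(m)])
  if (any(counts < 3)) {
    stop("group(s) with fewer than 3 samples: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  m <- m[, sort(colnames(m)), drop = FALSE]
  taxa <- colnames(m)
  f <- if (weighted) m / rowSums(m) else (m > 0) / rowSums(m > 0)
  D <- unclass(phylo_distances(tree))
  if (!all(taxa %in% rownames(D))) stop("tree does not cover all taxa")
  D <- D[taxa, taxa]
  nt <- length(taxa)
  obs <- bmntd_pairwise(f, D, seq_len(nt) - 1L)
  perms <- local_seed(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(nt) - 1L, integer(nt)))
  })
  mom <- bmntd_null_moments(f, D, perms)
  e_null <- mom$sum / n_null
  dmax <- max(mom$max, max(obs))
  dd <- obs / dmax
  ee <- e_null / dmax
  nst_mat <- ifelse(dd >= ee, (1 - dd) / (1 - ee), dd / ee)
  nst_mat <- pmin(pmax(nst_mat, 0), 1)
  labs <- rownames(m)
  g <- setNames(as.character(metadata$group), metadata$sample_id)
  idx <- which(upper.tri(nst_mat), arr.ind = TRUE)
  pairs <- tibble::tibble(
    sample1 = labs[idx[, 1]], sample2 = labs[idx[, 2]],
    group1 = unname(g[labs[idx[, 1]]]), group2 = unname(g[labs[idx[, 2]]]),
    beta_mntd = obs[idx], null_expectation = e_null[idx],
    pnst = nst_mat[idx])
  within <- pairs[pairs$group1 == pairs$group2 & !is.na(pairs$group1), ]
  group_means <- within |>
    dplyr::group_by(group = .data$group1) |>
    dplyr::summarise(mean_pnst = mean(.data$pnst), n_pairs = dplyr::n(),
                     .groups = "drop")
  structure(list(pairs = within, group_means = group_means,
                 n_null = n_null, seed = seed, d_max = dmax),
            class = "nst_result")
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("pNST (%d null replicates)\n", x$n_null))
  print(x$group_means)
  invisible(x)
}

#' @rdname pnst
#' @param x An `nst_result`.
#' @param ... Unused.
#' @export
tidy.nst_result <- function(x, ...) x$pairs

#' @rdname pnst
#' @export
glance.nst_result <- function(x, ...) x$group_means
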
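#' Great-circle distance matrix between samples
#'
#' Haversine distances (Earth radius 6,371,000 m) from the metadata's
#' `longitude` / `latitude` columns. Samples with missing coordinates are
#' dropped with a warning.
#'
#' @param metadata Metadata tibble with `sample_id`, `longitude`, `latitude`.
#' @return A `pairwise_matrix` in meters.
#' @export
haversine_matrix <- function(metadata) {
  metadata <- validate_metadata(metadata)
  if (!all(c("longitude", "latitude") %in% names(metadata))) {
    stop("metadata needs 'longitude' and 'latitude' columns")
  }
  ok <- complete.cases(metadata$longitude, metadata$latitude)
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " sample(s) with missing coordinates")
    metadata <- metadata[ok, ]
  }
  xy <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  })
  new_pairwise_matrix(d, metadata$sample_id, "haversine_m")
}

#' Distance-decay regression of community dissimilarity
#'
#' Ordinary least squares of the unraveled upper-triangle community
#' dissimilarities on the matching geographic distances. Reports slope
#' (dissimilarity per meter), intercept, correlation r, and the OLS p-value.
#' Because pairwise distances are not independent, an optional Mantel
#' permutation test (permuting sample labels of one matrix) is available via
#' `mantel_perms > 0`; it is off by default, matching common practice of
#' reporting the OLS fit.
#'
#' @param comm_dist `pairwise_matrix` of community dissimilarities.
#' @param geo_dist `pairwise_matrix` of geographic distances (same labels).
#' @param mantel_perms Number of Mantel permutations (0 = skip).
#' @param seed Seed for the Mantel permutations.
#' @return List of class `"decay_fit"`.
#' @export
distance_decay <- function(comm_dist, geo_dist, mantel_perms = 0, seed = 1) {
  geo_dist <- check_shared_labels(comm_dist, geo_dist)
  n <- nrow(comm_dist)
  if (n < 3) stop("need at least 3 samples")
  y <- upper_vec(as.matrix(comm_dist))
  x <- upper_vec(as.matrix(geo_dist))
  if (var(x) == 0) stop("zero variance in geographic distances")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  r <- if (var(y) == 0) 0 else cor(x, y)
  p <- if (var(y) == 0) 1 else sm$coefficients[2, 4]
  mantel_p <- NA_real_
  if (mantel_perms > 0) {
    mt <- local_seed(seed, vegan::mantel(as.dist(as.matrix(geo_dist)),
                                         as.dist(as.matrix(comm_dist)),
                                         permutations = mantel_perms))
    mantel_p <- mt$signif
  }
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = r, p_value = p, n_pairs = length(y),
                 mantel_p = mantel_p, mantel_perms = mantel_perms,
                 data = tibble::tibble(distance = x, dissimilarity = y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("distance-decay: slope = %.3e per m, r = %.3f, p = %.3g (%d pairs)\n",
              x$slope, x$r, x$p_value, x$n_pairs))
  if (!is.na(x$mantel_p)) cat(sprintf("Mantel p = %.3g\n", x$mantel_p))
  invisible(x)
}

#' @rdname distance_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname distance_decay
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 p_value = x$p_value, n_pairs = x$n_pairs,
                 mantel_p = x$mantel_p)
}

#' Per-group distance-decay fits
#'
#' Convenience wrapper running [distance_decay()] inside each metadata group.
#'
#' @param comm Community tibble.
#' @param metadata Metadata tibble with `group`, `longitude`, `latitude`.
#' @param metric Community dissimilarity metric (see [beta_distance()]).
#' @param mantel_perms,seed Passed to [distance_decay()].
#' @return Tibble with one row per group (glance columns).
#' @export
distance_decay_by_group <- function(comm, metadata, metric = "bray_curtis",
                                    mantel_perms = 0, seed = 1) {
  metadata <- validate_metadata(metadata)
  m <- comm_matrix(comm)
  purrr::imap(split(metadata$sample_id, metadata$group), function(ids, grp) {
    ids <- intersect(ids, rownames(m))
    if (length(ids) < 3) return(NULL)
    cd <- beta_distance(as_community(m[ids, , drop = FALSE]), metric)
    gd <- haversine_matrix(metadata[match(ids, metadata$sample_id), ])
    dplyr::mutate(glance(distance_decay(cd, gd, mantel_perms, seed)),
                  group = grp, .before = 1)
  }) |> dplyr::bind_rows()
}
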
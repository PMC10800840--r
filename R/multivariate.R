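#' Iterative variance-inflation-factor screen
#'
#' Computes VIF_k = 1 / (1 - R^2_k) from regressing each variable on the
#' others and iteratively removes the variable with the largest VIF until all
#' VIFs fall below `threshold` (default 10). A perfectly collinear variable
#' (infinite VIF) is removed with a warning, not an error.
#'
#' @param env Data frame of numeric variables (an optional `sample_id` column
#'   is ignored).
#' @param threshold Removal threshold; variables with VIF >= threshold drop.
#' @return Tibble with columns `variable`, `vif` (value at the step the
#'   variable was evaluated last), `retained`.
#' @export
vif_screen <- function(env, threshold = 10) {
  env <- dplyr::select(tibble::as_tibble(env), -dplyr::any_of("sample_id"))
  env <- dplyr::select(env, dplyr::where(is.numeric))
  if (ncol(env) < 2) stop("need at least 2 variables")
  if (nrow(env) <= ncol(env)) stop("need more samples than variables")
  vars <- names(env)
  removed <- character(0)
  final_vif <- setNames(rep(NA_real_, length(vars)), vars)
  active <- vars
  repeat {
    if (length(active) < 2) break
    vifs <- vapply(active, function(v) {
      r2 <- suppressWarnings(summary(lm(
        stats::reformulate(sprintf("`%s`", setdiff(active, v)),
                           sprintf("`%s`", v)), data = env)))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    final_vif[active] <- vifs
    if (max(vifs) < threshold) break
    worst <- active[which.max(vifs)]
    if (is.infinite(max(vifs))) {
      warning("perfectly collinear variable removed: ", worst)
    }
    removed <- c(removed, worst)
    active <- setdiff(active, worst)
  }
  tibble::tibble(variable = vars, vif = unname(final_vif[vars]),
                 retained = !vars %in% removed)
}

#' Distance-based redundancy analysis (db-RDA / CPCoA)
#'
#' Embeds the dissimilarity matrix by principal coordinates (negative
#' eigenvalues discarded, with a note when present) and constrains the
#' coordinates on the supplied variables via [vegan::capscale()]. A factor
#' constraint gives constrained PCoA (CPCoA); `condition` partials out a
#' grouping factor first. Term significance is assessed by permutation of
#' residuals under the reduced model ([vegan::anova.cca()], p-values of the
#' form (b+1)/(m+1)); per-variable squared correlations with the ordination
#' space come from [vegan::envfit()].
#'
#' @param community_dist A `pairwise_matrix` of dissimilarities.
#' @param env Data frame of constraining variables, rows aligned to the
#'   distance labels (an optional `sample_id` column is matched and dropped).
#' @param condition Optional name of a column in `env` to partial out.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation streams.
#' @return List of class `"dbrda_fit"`.
#' @export
dbrda_fit <- function(community_dist, env, condition = NULL, n_perm = 999,
                      seed = 1) {
  labs <- rownames(community_dist)
  env <- tibble::as_tibble(env)
  if ("sample_id" %in% names(env)) {
    if (!all(labs %in% env$sample_id)) stop("env rows do not cover samples")
    env <- env[match(labs, env$sample_id), , drop = FALSE]
    env$sample_id <- NULL
  } else if (nrow(env) != length(labs)) {
    stop("env rows do not align with the distance matrix")
  }
  if (!is.null(condition) && length(unique(env[[condition]])) < 2) {
    condition <- NULL  # a one-level factor constrains nothing
  }
  terms <- setdiff(names(env), condition)
  constant <- vapply(env[terms], function(v) length(unique(v)) < 2, logical(1))
  terms <- terms[!constant]
  if (length(terms) + length(condition) > length(labs) - 1) {
    stop("more constraints than samples - 1")
  }
  d <- as.dist(as.matrix(community_dist))
  rhs <- if (length(terms) > 0) {
    paste(sprintf("`%s`", terms), collapse = " + ")
  } else "1"
  if (!is.null(condition)) {
    rhs <- paste(rhs, sprintf("+ Condition(`%s`)", condition))
  }
  fml <- stats::as.formula(paste("d ~", rhs))
  dat <- as.data.frame(env)
  fit <- local_seed(seed, vegan::capscale(fml, data = dat))
  imag <- if (is.null(fit$CA$imaginary.chi)) 0 else fit$CA$imaginary.chi
  neg <- imag != 0
  # proportion of the real (positive-eigenvalue) inertia; the imaginary part
  # of a non-euclidean dissimilarity is discarded
  constrained_prop <- if (is.null(fit$CCA)) 0 else
    fit$CCA$tot.chi / (fit$tot.chi - imag)
  eig <- if (is.null(fit$CCA)) numeric(0) else fit$CCA$eig
  term_sig <- NULL
  if (length(terms) > 0 && n_perm > 0) {
    an <- local_seed(seed + 1,
      stats::anova(fit, by = "terms", permutations = n_perm))
    term_sig <- tibble::tibble(term = gsub("`", "", rownames(an)),
                               variance = an$SumOfSqs,
                               f = an$F, p_value = an$`Pr(>F)`) |>
      dplyr::filter(.data$term != "Residual")
  }
  factor_fit <- NULL
  num_terms <- terms[vapply(env[terms], is.numeric, logical(1))]
  if (length(num_terms) > 0 && n_perm > 0) {
    ef <- local_seed(seed + 2,
      vegan::envfit(fit, env[num_terms], permutations = n_perm))
    factor_fit <- tibble::tibble(factor = names(ef$vectors$r),
                                 r2 = unname(ef$vectors$r),
                                 p_value = unname(ef$vectors$pvals))
  }
  sc <- if (is.null(fit$CCA)) {
    matrix(numeric(0), nrow = length(labs), ncol = 0)
  } else {
    vegan::scores(fit, display = "sites",
                  choices = seq_along(eig))
  }
  structure(list(model = fit,
                 site_scores = tibble::as_tibble(as.data.frame(sc)) |>
                   dplyr::mutate(sample_id = labs, .before = 1),
                 constrained_proportion = unname(constrained_prop),
                 axis_eigenvalues = unname(sort(eig, decreasing = TRUE)),
                 term_significance = term_sig,
                 factor_fit = factor_fit,
                 negative_eigenvalues_discarded = neg,
                 n_perm = n_perm, seed = seed),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat(sprintf("db-RDA: constrained proportion %.3f (%d constrained axes)\n",
              x$constrained_proportion, length(x$axis_eigenvalues)))
  if (x$negative_eigenvalues_discarded) {
    cat("note: negative PCoA eigenvalues were discarded\n")
  }
  if (!is.null(x$term_significance)) print(x$term_significance)
  invisible(x)
}

#' @rdname dbrda_fit
#' @param x A `dbrda_fit`.
#' @param ... Unused.
#' @export
tidy.dbrda_fit <- function(x, ...) {
  out <- x$term_significance %||%
    tibble::tibble(term = character(0), variance = numeric(0),
                   f = numeric(0), p_value = numeric(0))
  if (!is.null(x$factor_fit)) {
    out <- dplyr::full_join(out,
      dplyr::rename(x$factor_fit, term = "factor", envfit_r2 = "r2",
                    envfit_p = "p_value"), by = "term")
  }
  out
}

#' @rdname dbrda_fit
#' @export
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(constrained_proportion = x$constrained_proportion,
                 n_axes = length(x$axis_eigenvalues),
                 negative_eigenvalues_discarded = x$negative_eigenvalues_discarded,
                 n_perm = x$n_perm)
}

#' Correlation table with FDR adjustment and significance stars
#'
#' All pairwise correlations between columns of `x` and columns of `y`
#' (Spearman by default), Benjamini-Hochberg adjusted across the whole table.
#' Stars follow the convention: `*` 0.01 <= p < 0.05, `**` 0.005 <= p < 0.01,
#' `***` 0.001 <= p < 0.005, `****` p < 0.001 — applied to the adjusted
#' p-value when `fdr = "bh"`. A constant variable yields a record with `NA`
#' coefficient and a warning.
#'
#' @param x,y Data frames of numeric variables (optional `sample_id` columns
#'   are dropped; rows must align).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param fdr `"bh"` (default) or `"none"`.
#' @return Tibble with `x`, `y`, `estimate`, `p_value`, `p_adjusted`, `stars`.
#' @export
correlation_table <- function(x, y, method = c("spearman", "pearson"),
                              fdr = c("bh", "none")) {
  method <- match.arg(method)
  fdr <- match.arg(fdr)
  x <- dplyr::select(tibble::as_tibble(x), -dplyr::any_of("sample_id"))
  y <- dplyr::select(tibble::as_tibble(y), -dplyr::any_of("sample_id"))
  if (nrow(x) != nrow(y)) stop("x and y must have the same rows")
  grid <- tidyr::crossing(xv = names(x), yv = names(y))
  rows <- purrr::pmap(grid, function(xv, yv) {
    xx <- x[[xv]]; yy <- y[[yv]]
    ok <- complete.cases(xx, yy)
    if (sum(ok) < 4) stop("need at least 4 paired observations for ", xv, " vs ", yv)
    if (sd(xx[ok]) == 0 || sd(yy[ok]) == 0) {
      warning("constant variable in pair ", xv, " vs ", yv)
      return(tibble::tibble(x = xv, y = yv, estimate = NA_real_,
                            p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(xx[ok], yy[ok], method = method,
                                    exact = FALSE))
    tibble::tibble(x = xv, y = yv, estimate = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (fdr == "bh") p.adjust(out$p_value, "BH") else out$p_value
  p_star <- if (fdr == "bh") out$p_adjusted else out$p_value
  out$stars <- significance_stars(p_star)
  out
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "****",
    p < 0.005 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "")
}

#' LMG relative-importance decomposition of a linear model
#'
#' Decomposes the full-model R^2 of `response ~ predictors` into
#' non-negative per-predictor shares by averaging, over all orderings of the
#' predictors, the increase in R^2 when each predictor enters. Computed by
#' exact enumeration over predictor subsets (2^k models), so the shares sum
#' to the full-model R^2 exactly; limited to 12 predictors.
#'
#' @param response Numeric vector.
#' @param predictors Data frame of numeric predictors (optional `sample_id`
#'   dropped).
#' @return List of class `"lmg_importance"` with a `shares` tibble and
#'   `full_model_r2`.
#' @export
lmg_importance <- function(response, predictors) {
  predictors <- dplyr::select(tibble::as_tibble(predictors),
                              -dplyr::any_of("sample_id"))
  k <- ncol(predictors)
  if (k < 1) stop("need at least one predictor")
  if (k > 12) stop("exact LMG enumeration limited to 12 predictors")
  X <- as.matrix(predictors)
  if (qr(cbind(1, X))$rank < k + 1) stop("singular design")
  y <- response
  # R^2 of every predictor subset, indexed by bitmask
  r2 <- numeric(2^k)
  for (mask in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0)
    r2[mask + 1] <- summary(lm(y ~ X[, idx, drop = FALSE]))$r.squared
  }
  lfact <- lfactorial(0:k)
  shares <- vapply(seq_len(k), function(j) {
    bit_j <- bitwShiftL(1L, j - 1L)
    total <- 0
    for (mask in 0:(2^k - 1)) {
      if (bitwAnd(mask, bit_j) != 0) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0)
      w <- exp(lfact[s + 1] + lfact[k - s] - lfact[k + 1])
      total <- total + w * (r2[mask + bit_j + 1] - r2[mask + 1])
    }
    total
  }, numeric(1))
  structure(list(shares = tibble::tibble(predictor = names(predictors),
                                         share = shares),
                 full_model_r2 = r2[2^k]),
            class = "lmg_importance")
}

#' @export
print.lmg_importance <- function(x, ...) {
  cat(sprintf("LMG decomposition, full-model R^2 = %.4f\n", x$full_model_r2))
  print(x$shares)
  invisible(x)
}

#' @rdname lmg_importance
#' @param x An `lmg_importance`.
#' @param ... Unused.
#' @export
tidy.lmg_importance <- function(x, ...) x$shares

#' @rdname lmg_importance
#' @export
glance.lmg_importance <- function(x, ...) {
  tibble::tibble(full_model_r2 = x$full_model_r2,
                 n_predictors = nrow(x$shares))
}
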
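#' Coerce a sample-by-taxon abundance matrix to a community tibble
#'
#' A community table is the package's universal input: a tibble whose first
#' column is `sample_id` and whose remaining columns are numeric taxon
#' abundances (reads or relative abundances), one row per sample.
#'
#' @param x Numeric matrix with sample row names and taxon column names, or a
#'   data frame already in community layout.
#' @return A validated community tibble.
#' @export
as_community <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input needs sample row names and taxon column names")
    }
    x <- tibble::as_tibble(as.data.frame(x), rownames = "sample_id")
  }
  x <- tibble::as_tibble(x)
  validate_community(x)
}

#' Extract the numeric abundance matrix from a community tibble
#'
#' @param comm Community tibble (`sample_id` + taxon columns).
#' @return Numeric matrix, rows = samples (named), columns = taxa (named).
#' @export
comm_matrix <- function(comm) {
  comm <- validate_community(comm)
  m <- as.matrix(comm[, setdiff(names(comm), "sample_id"), drop = FALSE])
  rownames(m) <- comm$sample_id
  storage.mode(m) <- "double"
  m
}

validate_community <- function(comm) {
  if (!is.data.frame(comm)) stop("community table must be a data frame")
  if (!"sample_id" %in% names(comm)) {
    stop("community table must have a 'sample_id' column")
  }
  comm <- dplyr::relocate(tibble::as_tibble(comm), "sample_id")
  taxa <- setdiff(names(comm), "sample_id")
  if (nrow(comm) < 1L || length(taxa) < 1L) stop("empty community table")
  if (anyDuplicated(comm$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(comm$sample_id[duplicated(comm$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon ids: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  vals <- as.matrix(comm[, taxa, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(comm[taxa], is.numeric, logical(1)))
    stop("non-numeric abundance column(s): ", paste(taxa[bad], collapse = ", "))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing abundance at sample '%s', taxon '%s'",
                 comm$sample_id[idx[1]], taxa[idx[2]]))
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 comm$sample_id[idx[1]], taxa[idx[2]]))
  }
  comm
}

#' Read a community table from TSV
#'
#' Expects one header row and one id column. The canonical layout is samples
#' as rows; a taxa-as-rows file is transposed on read so downstream code sees
#' a single layout.
#'
#' @param path Path to a tab-delimited file.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @return Community tibble.
#' @export
read_community_table <- function(path,
                                 orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty community table: ", path)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(raw[[bad + 1]]))))[1]
    stop(sprintf("non-numeric cell at row id '%s', column '%s'",
                 ids[ifelse(is.na(row), 1L, row)], names(raw)[bad + 1]))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(mat) <- ids
  if (orientation == "taxa_as_rows") mat <- t(mat)
  as_community(mat)
}

#' Write a community table as TSV (samples as rows)
#'
#' @param comm Community tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(comm, path) {
  comm <- validate_community(comm)
  utils::write.table(comm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: rejects duplicate leaf
#' labels and (by default) missing branch lengths.
#'
#' @param path Newick file.
#' @param missing_lengths_as_zero If `TRUE`, absent branch lengths become 0
#'   instead of an error.
#' @return An [ape::phylo] tree.
#' @export
read_community_tree <- function(path, missing_lengths_as_zero = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (!missing_lengths_as_zero) stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!missing_lengths_as_zero) stop("tree has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  tree
}

#' Convert counts to relative abundance (total-sum scaling)
#'
#' Each sample row is divided by its total so rows sum to 1. Idempotent.
#'
#' @param comm Community tibble.
#' @return Community tibble of relative abundances.
#' @export
to_relative_abundance <- function(comm) {
  m <- comm_matrix(comm)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero sample row(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  }
  as_community(m / tot)
}

#' Align a community table, sample metadata, and an optional tree
#'
#' Restricts samples to the intersection of the table and the metadata, and
#' taxa to the tree's leaves when a tree is given. Sample and taxon order is
#' canonicalized (sorted), so the result does not depend on input ordering.
#'
#' @param comm Community tibble.
#' @param metadata Data frame with a `sample_id` column (see
#'   [read_sample_metadata()]).
#' @param tree Optional [ape::phylo] tree whose tips cover the taxa to keep.
#' @return A list with elements `community`, `metadata`, `tree`, and `dropped`
#'   (lists of dropped sample and taxon ids).
#' @export
align_inputs <- function(comm, metadata, tree = NULL) {
  comm <- validate_community(comm)
  metadata <- validate_metadata(metadata)
  keep_samples <- sort(intersect(comm$sample_id, metadata$sample_id))
  if (length(keep_samples) == 0L) {
    stop("no samples shared between community table and metadata")
  }
  dropped_samples <- sort(union(setdiff(comm$sample_id, keep_samples),
                                setdiff(metadata$sample_id, keep_samples)))
  taxa <- sort(setdiff(names(comm), "sample_id"))
  dropped_taxa <- character(0)
  if (!is.null(tree)) {
    keep_taxa <- sort(intersect(taxa, tree$tip.label))
    if (length(keep_taxa) == 0L) stop("no taxa shared between table and tree")
    dropped_taxa <- setdiff(taxa, keep_taxa)
    taxa <- keep_taxa
    if (length(setdiff(tree$tip.label, taxa)) > 0) {
      tree <- ape::keep.tip(tree, taxa)
    }
  }
  m <- comm_matrix(comm)[keep_samples, taxa, drop = FALSE]
  meta <- metadata[match(keep_samples, metadata$sample_id), , drop = FALSE]
  list(community = as_community(m),
       metadata = meta,
       tree = tree,
       dropped = list(samples = dropped_samples, taxa = dropped_taxa))
}

#' Read sample metadata from TSV
#'
#' Expects at least `sample_id` and `group` columns; `latitude` / `longitude`
#' and environmental variables (e.g. NH4-N, NO2-N, NO3-N, PO4-P, pH) are kept
#' as supplied.
#'
#' @param path Tab-delimited metadata file.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  if (!is.data.frame(meta) || !"sample_id" %in% names(meta)) {
    stop("metadata must be a data frame with a 'sample_id' column")
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if ("latitude" %in% names(meta) &&
      any(abs(meta$latitude) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if ("longitude" %in% names(meta) &&
      any(abs(meta$longitude) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  meta
}

# Classed square matrix used for every pairwise dissimilarity/statistic.
new_pairwise_matrix <- function(values, labels, metric_name) {
  stopifnot(nrow(values) == length(labels), ncol(values) == length(labels))
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("pairwise_matrix", class(values)),
            metric = metric_name)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise matrix (%s), %d labels\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Tidy a pairwise matrix into one row per (unordered) pair
#'
#' @param x A pairwise matrix as returned by e.g. [beta_distance()].
#' @param ... Unused.
#' @return Tibble with columns `item1`, `item2`, `value`, `metric`.
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(item1 = labs[idx[, 1]], item2 = labs[idx[, 2]],
                 value = x[idx], metric = attr(x, "metric") %||% NA_character_)
}

upper_vec <- function(m) m[upper.tri(m)]

check_shared_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("matrices do not share labels")
    b <- b[rownames(a), rownames(a)]
  }
  b
}
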
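#' Build an FDR-filtered co-occurrence network
#'
#' Computes all pairwise correlations between taxa on relative abundance
#' (Spearman by default), adjusts p-values by Benjamini-Hochberg over all
#' tested pairs, and keeps an edge iff `|rho| >= r_min` and adjusted
#' `p < alpha`; the correlation sign is retained. Taxa present in fewer than
#' `min_prevalence` of samples are excluded before testing (set 0 to test
#' every taxon); constant taxa are skipped with a warning. The `r_min = 0.7`
#' default reads the common "R^2 value > 0.7" filter as a threshold on the
#' correlation coefficient itself.
#'
#' @param comm Community tibble of counts or relative abundances.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param r_min Minimum |correlation| for an edge.
#' @param alpha Maximum BH-adjusted p for an edge.
#' @param min_prevalence Minimum fraction of samples a taxon must occur in.
#' @param taxonomy Optional tibble (`taxon_id`, `phylum`) carried onto nodes.
#' @return List of class `"co_network"` with `graph` (igraph), `edges`,
#'   `nodes` tibbles.
#' @export
build_network <- function(comm, method = c("spearman", "pearson"),
                          r_min = 0.7, alpha = 0.05, min_prevalence = 0.2,
                          taxonomy = NULL) {
  method <- match.arg(method)
  m <- comm_matrix(comm)
  if (nrow(m) < 4) stop("need at least 4 samples")
  rel <- m / rowSums(m)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  rel <- rel[, keep, drop = FALSE]
  constant <- apply(rel, 2, function(x) sd(x) == 0)
  if (any(constant)) {
    warning("skipping ", sum(constant), " constant taxon/taxa")
    rel <- rel[, !constant, drop = FALSE]
  }
  taxa <- colnames(rel)
  nt <- length(taxa)
  if (nt < 2) stop("fewer than 2 taxa pass the prevalence filter")
  rho <- cor(rel, method = method)
  n <- nrow(rel)
  # t-approximation p-values, as the usual correlation-matrix routines report
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  pmat <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble::tibble(
    taxon1 = taxa[idx[, 1]], taxon2 = taxa[idx[, 2]],
    rho = rho[idx], p_value = pmat[idx])
  edges$p_adjusted <- p.adjust(edges$p_value, "BH")
  edges <- edges[abs(edges$rho) >= r_min & edges$p_adjusted < alpha, ]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon1", "taxon2", "rho", "p_adjusted", "sign")],
    directed = FALSE,
    vertices = data.frame(name = taxa))
  nodes <- tibble::tibble(taxon_id = taxa,
                          relative_abundance = colMeans(rel),
                          prevalence = prev[taxa],
                          degree = igraph::degree(g)[taxa])
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes,
      dplyr::select(taxonomy, "taxon_id", "phylum"), by = "taxon_id")
  }
  structure(list(graph = g, edges = edges, nodes = nodes,
                 method = method, r_min = r_min, alpha = alpha,
                 min_prevalence = min_prevalence),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (|rho| >= %.2f, BH p < %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$r_min, x$alpha))
  invisible(x)
}

#' Louvain module detection on a co-occurrence network
#'
#' Louvain community detection on absolute edge weights at resolution 1,
#' deterministic given the seed. Isolated nodes become singleton modules.
#'
#' @param net A `co_network`.
#' @param seed Integer seed.
#' @return Tibble (`taxon_id`, `module`) with attribute `"modularity"`.
#' @export
detect_modules <- function(net, seed = 1) {
  g <- net$graph
  if (igraph::ecount(g) < 1) stop("network has no edges")
  cl <- local_seed(seed,
    igraph::cluster_louvain(g, weights = abs(igraph::E(g)$rho), resolution = 1))
  out <- tibble::tibble(taxon_id = igraph::V(g)$name,
                        module = as.integer(igraph::membership(cl)))
  attr(out, "modularity") <- igraph::modularity(cl)
  out
}

#' Topology summary of a co-occurrence network
#'
#' Unweighted metrics on the simple graph: node and edge counts, average
#' degree, average local clustering coefficient (degree < 2 nodes count 0),
#' average shortest path length over the largest connected component (with
#' the component's coverage reported), and the positive-edge fraction.
#'
#' @param net A `co_network`.
#' @param modules Optional module assignment from [detect_modules()], to
#'   report modularity alongside.
#' @return One-row tibble.
#' @export
network_topology <- function(net, modules = NULL) {
  g <- net$graph
  nn <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (ne == 0) {
    return(tibble::tibble(n_nodes = nn, n_edges = 0L, avg_degree = 0,
                          avg_clustering = 0, avg_path_length = NA_real_,
                          largest_component = 0L, component_coverage = 0,
                          positive_edge_fraction = NA_real_,
                          modularity = NA_real_, empty = TRUE))
  }
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  tibble::tibble(
    n_nodes = nn, n_edges = ne,
    avg_degree = 2 * ne / nn,
    avg_clustering = mean(cc),
    avg_path_length = igraph::mean_distance(sub),
    largest_component = max(comp$csize),
    component_coverage = max(comp$csize) / nn,
    positive_edge_fraction = mean(net$edges$sign == "positive"),
    modularity = if (is.null(modules)) NA_real_ else attr(modules, "modularity"),
    empty = FALSE)
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' `Zi = (k_own - mean(k_own)) / sd(k_own)` over the node's module, where
#' `k_own` is the within-module degree (modules with zero spread get Zi = 0,
#' flagged); `Pi = 1 - sum_s (k_s / k)^2` over modules s. Roles follow the
#' usual cartography: module hub (Zi >= 2.5, Pi < 0.62), connector
#' (Zi < 2.5, Pi >= 0.62), network hub (both), peripheral (neither);
#' keystone taxa are nodes with Zi >= 2.5 and/or Pi >= 0.62. Isolated nodes
#' get Pi = 0 and are flagged.
#'
#' @param net A `co_network`.
#' @param modules Module assignment from [detect_modules()].
#' @param zi_cut,pi_cut Role thresholds (defaults 2.5 and 0.62).
#' @return Tibble with `taxon_id`, `module`, `degree`, `zi`, `pi`, `role`,
#'   `keystone`, `flagged`.
#' @export
zi_pi <- function(net, modules, zi_cut = 2.5, pi_cut = 0.62) {
  g <- net$graph
  taxa <- igraph::V(g)$name
  mod <- modules$module[match(taxa, modules$taxon_id)]
  if (anyNA(mod)) stop("modules do not cover every node")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  k <- rowSums(adj)
  k_by_mod <- vapply(sort(unique(mod)), function(s) {
    rowSums(adj[, mod == s, drop = FALSE])
  }, numeric(length(taxa)))
  colnames(k_by_mod) <- sort(unique(mod))
  k_own <- k_by_mod[cbind(seq_along(taxa), match(mod, sort(unique(mod))))]
  zi <- numeric(length(taxa))
  zero_sd <- logical(length(taxa))
  for (s in sort(unique(mod))) {
    sel <- mod == s
    mu <- mean(k_own[sel]); sdev <- sd(k_own[sel])
    if (length(which(sel)) < 2 || is.na(sdev) || sdev == 0) {
      zi[sel] <- 0
      zero_sd[sel] <- TRUE
    } else {
      zi[sel] <- (k_own[sel] - mu) / sdev
    }
  }
  pi <- unname(ifelse(k == 0, 0, 1 - rowSums((k_by_mod / pmax(k, 1))^2)))
  role <- dplyr::case_when(
    zi >= zi_cut & pi >= pi_cut ~ "network_hub",
    zi >= zi_cut ~ "module_hub",
    pi >= pi_cut ~ "connector",
    TRUE ~ "peripheral")
  tibble::tibble(taxon_id = taxa, module = mod, degree = as.integer(k),
                 zi = zi, pi = pi, role = role,
                 keystone = zi >= zi_cut | pi >= pi_cut,
                 flagged = zero_sd | k == 0)
}

#' Write a co-occurrence network to GraphML and edge-list TSV
#'
#' @param net A `co_network`.
#' @param path_graphml,path_edges Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, path_graphml = NULL, path_edges = NULL) {
  if (!is.null(path_graphml)) {
    igraph::write_graph(net$graph, path_graphml, format = "graphml")
  }
  if (!is.null(path_edges)) {
    utils::write.table(net$edges, path_edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = path_graphml, edges = path_edges))
}
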
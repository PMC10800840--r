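#' Default pipeline configuration
#'
#' @param table,tree,metadata Input paths (TSV table, Newick tree, TSV
#'   metadata); all three may be `NULL` when `simulate_seed` is given, in
#'   which case the synthetic estuary survey is generated in-run.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in dependency order; any
#'   subset of `c("diversity", "multivariate", "assembly", "spatial",
#'   "network")`.
#' @param n_null Null replicates for betaNTI / RCbray.
#' @param n_null_pnst Null replicates for pNST.
#' @param n_perm Permutations for db-RDA tests.
#' @param seed Master seed recorded in the manifest and reused by every
#'   stochastic stage.
#' @param thresholds A [process_thresholds()].
#' @param beta_family Partitioning family for [partition_beta()].
#' @param r_min,alpha,min_prevalence Network filter parameters.
#' @param simulate_seed If non-`NULL`, generate inputs with
#'   [simulate_estuary_survey()] using this seed.
#' @return A config list of class `"run_config"`.
#' @export
run_config <- function(table = NULL, tree = NULL, metadata = NULL,
                       out_dir = "ecoassembly_run",
                       stages = c("diversity", "multivariate", "assembly",
                                  "spatial", "network"),
                       n_null = 199, n_null_pnst = 199, n_perm = 199,
                       seed = 1, thresholds = process_thresholds(),
                       beta_family = "baselga_sorensen",
                       r_min = 0.7, alpha = 0.05, min_prevalence = 0.2,
                       simulate_seed = NULL) {
  structure(list(table = table, tree = tree, metadata = metadata,
                 out_dir = out_dir, stages = stages, n_null = n_null,
                 n_null_pnst = n_null_pnst, n_perm = n_perm, seed = seed,
                 thresholds = thresholds, beta_family = beta_family,
                 r_min = r_min, alpha = alpha,
                 min_prevalence = min_prevalence,
                 simulate_seed = simulate_seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- if (!is.null(y$thresholds)) do.call(process_thresholds, y$thresholds)
         else process_thresholds()
  y$thresholds <- thr
  do.call(run_config, y)
}

env_columns <- function(metadata) {
  setdiff(names(metadata)[vapply(metadata, is.numeric, logical(1))],
          c("latitude", "longitude"))
}

#' Run the full community-assembly pipeline
#'
#' Executes the requested stages in dependency order (io -> diversity ->
#' multivariate -> assembly -> spatial -> network), writes every stage's
#' result as TSV under `config$out_dir`, and records a `manifest.json` with
#' the package version, seeds, parameters, and per-file MD5 checksums, so a
#' rerun with the same config is byte-identical for every seeded stage. A
#' stage failure raises an error naming the stage; outputs of completed
#' stages are retained.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, name)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  results <- list()

  # io
  bundle <- stage("io", {
    if (!is.null(config$simulate_seed)) {
      fx <- simulate_estuary_survey(seed = config$simulate_seed)
      ape::write.tree(fx$tree, out("tree.nwk"))
      write_community_table(fx$community, out("table.tsv"))
      emit(fx$metadata, "metadata.tsv")
      align_inputs(fx$community, fx$metadata, fx$tree)
    } else {
      if (is.null(config$table) || is.null(config$metadata)) {
        stop("config needs 'table' and 'metadata' paths (or simulate_seed)")
      }
      tree <- NULL
      if (!is.null(config$tree)) {
        tree <- read_community_tree(config$tree)
      } else if ("assembly" %in% config$stages) {
        stop("the assembly stage requires a tree")
      }
      align_inputs(read_community_table(config$table),
                   read_sample_metadata(config$metadata), tree)
    }
  })
  comm <- bundle$community
  meta <- bundle$metadata
  tree <- bundle$tree

  if ("diversity" %in% config$stages) {
    results$diversity <- stage("diversity", {
      alpha <- alpha_diversity(comm)
      emit(alpha, "alpha_diversity.tsv")
      part <- partition_beta(comm, config$beta_family, groups = meta)
      emit(part$group_summary, "beta_partition_groups.tsv")
      emit(tidy(part), "beta_partition_pairs.tsv")
      bc <- beta_distance(comm, "bray_curtis")
      ape::write.tree(upgma(bc), out("upgma_bray_curtis.nwk"))
      list(alpha = alpha, partition = part, bray = bc)
    })
  }

  if ("multivariate" %in% config$stages) {
    results$multivariate <- stage("multivariate", {
      ev <- env_columns(meta)
      env <- meta[, c("sample_id", ev)]
      vif <- vif_screen(env)
      emit(vif, "vif.tsv")
      bc <- results$diversity$bray %||% beta_distance(comm, "bray_curtis")
      ord <- dbrda_fit(bc, env[, c("sample_id", vif$variable[vif$retained])],
                       n_perm = config$n_perm, seed = config$seed)
      emit(tidy(ord), "dbrda_terms.tsv")
      emit(ord$site_scores, "dbrda_scores.tsv")
      alpha <- results$diversity$alpha %||% alpha_diversity(comm)
      ct <- correlation_table(env, alpha[, c("richness", "chao1", "shannon",
                                             "simpson")])
      emit(ct, "env_alpha_correlations.tsv")
      imp <- lmg_importance(alpha$shannon, env[, vif$variable[vif$retained]])
      emit(tidy(imp), "lmg_shannon.tsv")
      list(vif = vif, ordination = ord, correlations = ct, lmg = imp)
    })
  }

  if ("assembly" %in% config$stages) {
    results$assembly <- stage("assembly", {
      if (is.null(tree)) stop("tree required")
      z <- bnti(comm, tree, n_null = config$n_null, seed = config$seed)
      rcb <- raup_crick_bray(comm, n_null = config$n_null,
                             seed = config$seed + 1)
      emit(tidy(z), "bnti.tsv")
      emit(tidy(rcb), "rcbray.tsv")
      cls <- classify_processes(z, rcb, config$thresholds, meta)
      emit(cls$pairs, "pair_labels.tsv")
      emit(cls$fractions, "fractions.tsv")
      fits <- purrr::imap(split(meta$sample_id, meta$group), function(ids, grp) {
        sub <- as_community(comm_matrix(comm)[ids, , drop = FALSE])
        dplyr::mutate(glance(fit_ncm(sub)), group = grp, .before = 1)
      }) |> dplyr::bind_rows()
      emit(fits, "ncm_fit.tsv")
      ns <- pnst(comm, tree, meta, n_null = config$n_null_pnst,
                 seed = config$seed + 2)
      emit(ns$group_means, "pnst.tsv")
      list(bnti = z, rc = rcb, classification = cls, ncm = fits, pnst = ns)
    })
  }

  if ("spatial" %in% config$stages) {
    results$spatial <- stage("spatial", {
      decay <- distance_decay_by_group(comm, meta, seed = config$seed)
      emit(decay, "decay.tsv")
      decay
    })
  }

  if ("network" %in% config$stages) {
    results$network <- stage("network", {
      nets <- purrr::imap(split(meta$sample_id, meta$group), function(ids, grp) {
        sub <- as_community(comm_matrix(comm)[ids, , drop = FALSE])
        net <- build_network(sub, r_min = config$r_min, alpha = config$alpha,
                             min_prevalence = config$min_prevalence)
        if (igraph::ecount(net$graph) > 0) {
          mods <- detect_modules(net, seed = config$seed)
          roles <- zi_pi(net, mods)
          topo <- network_topology(net, mods)
          emit(roles, sprintf("network_%s_nodes.tsv", grp))
          write_network(net,
                        path_graphml = out(sprintf("network_%s.graphml", grp)),
                        path_edges = out(sprintf("network_%s_edges.tsv", grp)))
          written <<- c(written, sprintf("network_%s.graphml", grp),
                        sprintf("network_%s_edges.tsv", grp))
        } else {
          topo <- network_topology(net)
        }
        dplyr::mutate(topo, group = grp, .before = 1)
      })
      topo <- dplyr::bind_rows(nets)
      emit(topo, "network_topology.tsv")
      topo
    })
  }

  manifest <- list(
    package = "ecoassembly",
    version = as.character(utils::packageVersion("ecoassembly")),
    seed = config$seed, n_null = config$n_null, n_perm = config$n_perm,
    stages = config$stages,
    dropped = bundle$dropped,
    checksums = as.list(tools::md5sum(file.path(config$out_dir,
                                                unique(written)))))
  names(manifest$checksums) <- unique(written)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 out_dir = config$out_dir))
}
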
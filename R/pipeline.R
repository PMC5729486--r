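#' Configuration for the full analysis pipeline
#'
#' Collects every input path, seed, replicate count and convention flag of
#' the end-to-end workflow in one serializable list, so a run can be
#' reproduced from its manifest alone.
#'
#' @param matrices Directory of adjacency-matrix CSV files (one per species),
#'   or a named list of [anatomical_network()] objects.
#' @param tree Path to a Newick tree, an `ape::phylo`, or `NULL` (phylogenetic
#'   stages are then skipped with a notice).
#' @param covariates Path to a covariate CSV or a data frame, or `NULL`.
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_seeds Annealing restarts for the consensus partition.
#' @param n_perm Permutations for signal and D-PGLS tests.
#' @param n_boot Bootstrap resamples for CV intervals.
#' @param n_sim Brownian-motion simulations for the DTT envelope.
#' @param l_convention,sd_type,pca_scale Convention flags (see
#'   [network-metrics] and [phylomorphospace()]).
#' @return A list of class `necknet_config`.
#' @export
necknet_config <- function(matrices, tree = NULL, covariates = NULL,
                           out_dir = tempfile("necknet_run_"), seed = 1,
                           n_seeds = 20, n_perm = 999, n_boot = 10000,
                           n_sim = 1000, l_convention = "pair_mean",
                           sd_type = "population", pca_scale = TRUE) {
  structure(list(matrices = matrices, tree = tree, covariates = covariates,
                 out_dir = out_dir, seed = seed, n_seeds = n_seeds,
                 n_perm = n_perm, n_boot = n_boot, n_sim = n_sim,
                 l_convention = l_convention, sd_type = sd_type,
                 pca_scale = pca_scale),
            class = "necknet_config")
}

#' Run the full anatomical-network workflow
#'
#' Executes every stage of the analysis on a set of species networks:
#' network parameters (written as `params.csv`), consensus connectivity
#' modules per species with Q, jackknife error and per-module significance
#' (`modules.json`), the coefficient-of-variation report (`cv_report.json`),
#' and - when a tree is supplied - the phylogenetic-signal table
#' (`signal.json`) and the disparity-through-time analysis (`dtt.json`).
#' A manifest (`manifest.json`) records the configuration, seeds and package
#' version. Stages that lack their inputs are skipped with a notice; stage
#' failures are reported with the stage name.
#'
#' @param config A [necknet_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "necknet_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  networks <- stage("read_networks", {
    if (is.character(config$matrices)) {
      files <- list.files(config$matrices, pattern = "\\.(csv|tsv)$",
                          full.names = TRUE)
      if (length(files) == 0) abort("no matrix files found")
      nets <- map(files, read_adjacency_matrix)
      names(nets) <- map_chr(nets, "species")
      nets
    } else config$matrices
  })

  partitions <- stage("modules", {
    imap(networks, function(net, nm) {
      consensus_modules(net, seeds = config$seed + seq_len(config$n_seeds))
    })
  })

  params <- stage("metrics", {
    network_parameter_table(networks, partitions,
                            convention = config$l_convention,
                            sd_type = config$sd_type)
  })
  readr::write_csv(params, file.path(config$out_dir, "params.csv"))

  modules_json <- imap(partitions, function(p, nm) {
    list(species = nm, Q = p$Q, Q_error = p$Q_error,
         strongly_modular = is_strongly_modular(p$Q, p$Q_error),
         membership = as.list(p$membership),
         module_stats = p$module_stats)
  })
  jsonlite::write_json(modules_json, file.path(config$out_dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cvrep <- stage("variability", {
    cv_report(params[, c("N", "K", "D", "C", "L", "H", "P")],
              n_boot = config$n_boot, seed = config$seed)
  })
  jsonlite::write_json(
    list(cv = cvrep$cv,
         mslrt = cvrep$mslrt[c("statistic", "df", "p_value")],
         pairwise = cvrep$pairwise$pairs),
    file.path(config$out_dir, "cv_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  signal <- dtt <- NULL
  tree <- config$tree
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.null(tree)) {
    notices <- c(notices, "no tree supplied; signal and DTT stages skipped")
  } else {
    mism <- check_tree_tips(tree, params$species)
    if (nrow(mism) > 0) {
      abort(sprintf("tree/species mismatch: %s",
                    paste(mism$name, collapse = ", ")))
    }
    X <- trait_matrix(params, traits = c("N", "K", "D", "C", "L", "H", "P"))
    signal <- stage("signal", {
      signal_table(tree, X, n_perm = config$n_perm, seed = config$seed)
    })
    jsonlite::write_json(signal, file.path(config$out_dir, "signal.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dtt <- stage("dtt", {
      dtt_bm(tree, X, n_sim = config$n_sim, seed = config$seed,
             use_pca = config$pca_scale)
    })
    jsonlite::write_json(
      c(glance(dtt), list(curve = tidy(dtt))),
      file.path(config$out_dir, "dtt.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("necknet")),
    config = config[setdiff(names(config), c("matrices", "tree", "covariates"))],
    species = names(networks),
    has_tree = !is.null(tree),
    notices = notices,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (msg in notices) message(msg)
  invisible(list(networks = networks, partitions = partitions,
                 params = params, cv_report = cvrep, signal = signal,
                 dtt = dtt, manifest = manifest, out_dir = config$out_dir))
}
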
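# End-to-end orchestration: simulate (or load) inputs, run the kinetic and
# taxonomic feature chain into the flavour random-forest stage, or the
# network reduction chain, with a deterministic run report and an md5
# output manifest.

write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  listcols <- vapply(df, is.list, logical(1))
  for (j in which(listcols)) {
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

manifest_of <- function(paths) {
  tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Save / load a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `path` (writer) or the reconstructed `sim_config` (reader).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$kinetic_params <- as.data.frame(lst$kinetic_params)
  lst$taxa_spec <- as.data.frame(lst$taxa_spec)
  lst$noise_sd <- as.list(lst$noise_sd)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$kinetic_params <- tibble::as_tibble(as.data.frame(lst$kinetic_params))
  lst$taxa_spec <- tibble::as_tibble(as.data.frame(lst$taxa_spec))
  lst$noise_sd <- unlist(lst$noise_sd)
  do.call(sim_config, lst)
}

# Build the default planted sensory specification over the computed,
# normalized feature columns: three attributes, each driven by one
# feature, so the flavour stage has a known recovery target.
default_sensory_spec <- function(feature_names) {
  pick <- function(candidates) {
    hit <- candidates[candidates %in% feature_names]
    if (length(hit) == 0) feature_names[1] else hit[1]
  }
  list(
    list(attribute = "fruity",
         coefficients = setNames(9, pick(c("Hanseniaspora_auc"))),
         noise_sd = 0.5),
    list(attribute = "acidity",
         coefficients = setNames(8, pick(c("Acetobacter_auc"))),
         noise_sd = 0.5),
    list(attribute = "cocoa",
         coefficients = setNames(7,
           pick(c("temperature_top_value_at_max_ke"))),
         noise_sd = 0.5)
  )
}

stage_record <- function(stage, status, n_rows = NA_integer_, note = "") {
  tibble::tibble(stage = stage, status = status,
                 n_rows = as.integer(n_rows), note = note)
}

#' Run the full flavour-association analysis
#'
#' Executes the complete chain on a synthetic study: simulate kinetic
#' series and taxon trajectories; invert the falling cotyledon pH; fit the
#' five-parameter model to every series and derive the 13 abiotic
#' features; select marker taxa by PERMANOVA-coefficient threshold and
#' derive their 7 growth features; assemble the per-replicate feature
#' matrix; min-max normalize; correlation-cluster the features and pick
#' one representative per cluster by highest CV; simulate sensory scores
#' from planted coefficients; and fit one permutation-importance random
#' forest per sensory attribute. All randomness flows from the
#' configuration seed through named sub-streams.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing); TSV tables and an
#'   md5 manifest are written there.
#' @param n_trees Trees per random forest (default 500).
#' @param k Cluster count passed to [cluster_features()] (`NULL` =
#'   silhouette default).
#' @return A `ferment_run` object: `report` (per-stage tibble), `manifest`
#'   (file md5 tibble), `config_hash`, and the in-memory `results`
#'   (features, clusters, sensory, importance, planted truth).
#' @export
run_flavour_analysis <- function(config, out_dir = tempfile("flavour_run_"),
                                 n_trees = 500, k = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  results <- list()
  finish <- function() {
    paths <- list.files(out_dir, full.names = TRUE)
    structure(list(
      report = dplyr::bind_rows(report),
      manifest = manifest_of(paths),
      config_hash = config_hash(config),
      out_dir = out_dir,
      results = results
    ), class = "ferment_run")
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report[[length(report) + 1]] <<-
        stage_record(stage, "failed", note = conditionMessage(res))
      NULL
    } else {
      n <- if (is.data.frame(res)) nrow(res) else NA_integer_
      report[[length(report) + 1]] <<- stage_record(stage, "ok", n)
      res
    }
  }

  series <- run_stage("simulate_kinetics", simulate_kinetics(config))
  if (is.null(series)) return(finish())
  taxa <- run_stage("simulate_taxa", simulate_taxa(config))
  if (is.null(taxa)) return(finish())

  abiotic <- run_stage("abiotic_features", {
    cot <- series$variable == "ph" & series$compartment == "cotyledon"
    inv <- invert_series(series[cot, ])
    prepped <- dplyr::bind_rows(
      series[!cot, ],
      inv[, names(series)]
    )
    fits <- fit_kinetics(prepped, seed = derive_seed(config$seed, "fit"))
    feats <- abiotic_features(fits)
    tidyr::pivot_wider(
      tidyr::pivot_longer(feats,
        dplyr::all_of(abiotic_feature_names),
        names_to = "feature", values_to = "value"),
      names_from = c("variable", "compartment", "feature"),
      values_from = "value", names_sep = "_"
    )
  })
  if (is.null(abiotic)) return(finish())

  growth <- run_stage("growth_features", {
    markers <- select_markers(attr(taxa, "coefficients"))
    traj <- dplyr::semi_join(taxa, markers, by = "taxon")
    gf <- growth_features(dplyr::select(traj, -"kingdom"))
    tidyr::pivot_wider(
      tidyr::pivot_longer(gf, dplyr::all_of(growth_feature_names),
                          names_to = "feature", values_to = "value"),
      names_from = c("taxon", "feature"), values_from = "value",
      names_sep = "_"
    )
  })
  if (is.null(growth)) return(finish())

  features <- run_stage("feature_matrix", {
    fm <- dplyr::full_join(abiotic, growth, by = "replicate")
    complete <- stats::complete.cases(fm)
    if (any(!complete)) {
      # default missing-value policy: drop the instance
      warning(sprintf("dropping %d instance(s) with missing features",
                      sum(!complete)), call. = FALSE)
      fm <- fm[complete, , drop = FALSE]
    }
    write_tsv_plain(fm, file.path(out_dir, "features.tsv"))
    fm
  })
  if (is.null(features)) return(finish())
  results$features <- features

  normalized <- run_stage("rescale01", {
    nm <- rescale01(features)
    write_tsv_plain(nm, file.path(out_dir, "features_normalized.tsv"))
    nm
  })
  if (is.null(normalized)) return(finish())

  clusters <- run_stage("cluster_features", {
    cluster_features(dplyr::select(features, -"replicate"), k = k)
  })
  if (is.null(clusters)) return(finish())
  results$clusters <- clusters
  write_tsv_plain(tidy(clusters), file.path(out_dir, "feature_clusters.tsv"))

  sensory <- run_stage("simulate_sensory", {
    spec <- config$sensory_spec %||%
      default_sensory_spec(setdiff(names(normalized), "replicate"))
    sn <- simulate_sensory(dplyr::select(normalized, -"replicate"), spec,
                           seed = config$seed)
    write_tsv_plain(sn, file.path(out_dir, "sensory.tsv"))
    sn
  })
  if (is.null(sensory)) return(finish())
  results$sensory <- sensory
  results$informative <- attr(sensory, "informative")

  importance <- run_stage("rf_importance", {
    reps <- select_representatives(clusters)
    imp <- flavour_importance(
      dplyr::select(normalized, dplyr::all_of(reps)), sensory,
      n_trees = n_trees, seed = derive_seed(config$seed, "forest")
    )
    write_tsv_plain(tidy(imp), file.path(out_dir, "importance.tsv"))
    imp
  })
  results$importance <- importance

  run <- finish()
  jsonlite::write_json(
    list(config_hash = run$config_hash,
         manifest = run$manifest,
         report = run$report),
    file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  run$manifest <- manifest_of(setdiff(list.files(out_dir, full.names = TRUE),
                                      file.path(out_dir, "run_report.json")))
  run
}

#' @export
print.ferment_run <- function(x, ...) {
  cat("fermentome pipeline run (config hash ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Run the community-design analysis
#'
#' Executes the network chain: simulate (or load) organism metabolic
#' networks, compute individual and community scopes, the added value of
#' cooperation, enumerate minimal communities for the chosen target mode,
#' and summarize the metabolite overlap between the full and the reduced
#' community.
#'
#' @param config A [sim_config()] (its `network_spec` defines the pool),
#'   or a list with elements `networks` (path to a network JSON) and
#'   `seeds` (path to a seed list) to analyse real inputs.
#' @param out_dir Output directory for JSON results and the manifest.
#' @param mode Target mode for [minimal_communities()].
#' @param seed Seed for the (approximate) search fallback; defaults to the
#'   configuration seed when simulating.
#' @return A `ferment_run` object with the scopes, added value, reduction
#'   and coverage in `results`.
#' @export
run_community_design <- function(config, out_dir = tempfile("community_run_"),
                                 mode = c("full", "added_value"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  results <- list()
  finish <- function(chash) {
    paths <- list.files(out_dir, full.names = TRUE)
    structure(list(
      report = dplyr::bind_rows(report),
      manifest = manifest_of(paths),
      config_hash = chash,
      out_dir = out_dir,
      results = results
    ), class = "ferment_run")
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report[[length(report) + 1]] <<-
        stage_record(stage, "failed", note = conditionMessage(res))
      NULL
    } else {
      n <- if (is.data.frame(res)) nrow(res) else NA_integer_
      report[[length(report) + 1]] <<- stage_record(stage, "ok", n)
      res
    }
  }

  if (inherits(config, "sim_config")) {
    seed <- seed %||% config$seed
    inst <- run_stage("simulate_networks", simulate_networks(config))
    if (is.null(inst)) return(finish(config_hash(config)))
    networks <- inst$networks
    seeds <- inst$seeds
    results$truth <- inst$truth
    chash <- config_hash(config)
  } else {
    seed <- seed %||% 1L
    inst <- run_stage("load_networks", {
      seeds <- read_seeds(config$seeds)
      list(networks = read_network_json(config$networks), seeds = seeds)
    })
    if (is.null(inst)) return(finish(NA_character_))
    networks <- inst$networks
    seeds <- inst$seeds
    chash <- config_hash(config)
  }

  scopes <- run_stage("individual_scopes", individual_scopes(networks, seeds))
  if (is.null(scopes)) return(finish(chash))
  results$individual <- scopes

  comm <- run_stage("community_scope", metabolic_scope(networks, seeds))
  if (is.null(comm)) return(finish(chash))
  results$community <- comm

  av <- run_stage("added_value", {
    sort(setdiff(comm$reachable, unique(unlist(scopes$reachable))))
  })
  results$added_value <- av

  red <- run_stage("minimal_communities", {
    minimal_communities(networks, seeds, mode = mode, seed = seed)
  })
  if (is.null(red)) return(finish(chash))
  results$reduction <- red

  cov <- run_stage("coverage_stats", {
    reduced <- metabolic_scope(networks, seeds,
                               organisms = red$communities[[1]])
    coverage_stats(comm, reduced)
  })
  results$coverage <- cov

  jsonlite::write_json(
    list(
      seeds = seeds,
      individual_scopes = setNames(scopes$reachable, scopes$organism),
      community_scope = comm$reachable,
      added_value = av,
      reduction = list(
        targets = red$targets, min_size = red$min_size,
        communities = red$communities,
        key_species = red$key_species,
        essential_species = red$essential_species,
        alternative_species = red$alternative_species,
        exhaustive = red$exhaustive
      ),
      coverage = as.list(cov)
    ),
    file.path(out_dir, "community_design.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  finish(chash)
}
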
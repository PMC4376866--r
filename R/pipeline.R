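#' Build the condensed bipartite network from universe tables
#'
#' The in-memory network construction used by the file-based `build`
#' stage and directly by tests: drug-likeness filter, ligand edge
#' thresholding, per-partition condensation, and interaction linking.
#'
#' @param universe list of tibbles as produced by [generate_universe()]
#'   (or read from the same TSV dialects): needs `compounds`,
#'   `ligand_sim`, `sites`, `site_comparisons`, `interactions`.
#' @param wqed_min drug-likeness threshold (inclusive, default 0.35).
#' @param ligand_threshold minimum pair-classifier probability that makes
#'   a ligand similarity edge (default 0.5).
#' @param site_zmin strict Z threshold for known-site edges (default 2).
#' @param cluster_mode,k passed to [find_clusters()].
#' @return a `ppnet` with interaction edges; cluster memberships attached
#'   as attributes `"ligand_clusters"` / `"site_clusters"`.
#' @export
build_core_network <- function(universe, wqed_min = 0.35,
                               ligand_threshold = 0.5, site_zmin = 2,
                               cluster_mode = c("clique", "kcore"), k = 2) {
  cluster_mode <- match.arg(cluster_mode)
  cmp <- filter_druglike(universe$compounds, threshold = wqed_min)
  lig_edges <- universe$ligand_sim |>
    filter(.data$value >= ligand_threshold,
           .data$a %in% cmp$id, .data$b %in% cmp$id)
  lig_cl <- find_clusters(lig_edges, node_ids = cmp$id, mode = cluster_mode,
                          k = k, prefix = "LC")
  lig_cl_edges <- condense_network(lig_edges, lig_cl)

  site_edges <- site_similarity_edges(universe$site_comparisons,
                                      zmin = site_zmin, kind = "site")
  site_cl <- find_clusters(site_edges, node_ids = universe$sites$id,
                           mode = cluster_mode, k = k, prefix = "SC")
  site_cl_edges <- condense_network(site_edges, site_cl)

  net <- assemble_network(lig_cl, lig_cl_edges, site_cl, site_cl_edges)
  net <- link_interactions(net, universe$interactions)
  attr(net, "ligand_clusters") <- lig_cl
  attr(net, "site_clusters") <- site_cl
  net
}

#' Run the whole pipeline in memory on a synthetic universe
#'
#' Convenience wrapper chaining [build_core_network()],
#' [integrate_target_sites()], [integrate_query_compounds()] and
#' [predict_all()] on a generated universe. Used heavily by the test
#' suite and the benchmark scripts.
#'
#' @param universe output of [generate_universe()].
#' @param d_max maximum path distance for the search.
#' @param ... passed to [build_core_network()].
#' @return list with elements `network` (integrated `ppnet`),
#'   `predictions` (scored tibble) and `truth` (planted labels).
#' @export
run_universe_pipeline <- function(universe, d_max = 10, ...) {
  net <- build_core_network(universe, ...)
  net <- integrate_target_sites(net, universe$model_sites,
                                universe$model_comparisons,
                                site_identity = universe$model_identity)
  net <- integrate_query_compounds(net, universe$queries,
                                   pair_probs = universe$query_sim)
  pred <- predict_all(net, d_max = d_max)
  list(network = net, predictions = pred, truth = universe$truth)
}

#' Default pipeline configuration
#'
#' The nested list consumed by [run_stage()]; any subset of it may be
#' supplied in a YAML/JSON config file, unknown keys are fatal.
#'
#' @param workdir artifact directory stages read from / write to.
#' @param seed master seed for the run.
#' @return nested configuration list.
#' @export
pp_default_config <- function(workdir = "pp_run", seed = 7) {
  list(
    workdir = workdir,
    seed = as.integer(seed),
    synth = unclass(synth_config(seed = seed)),
    build = list(wqed_min = 0.35, ligand_threshold = 0.5, site_zmin = 2,
                 cluster_mode = "clique", k = 2),
    integrate = list(quality_min = 1.1, id_min = 40, min_residues = 6,
                     redundancy_pct = 80, z_min = 1.0, query_threshold = 0.5),
    train = list(num_trees = 500),
    predict = list(d_max = 10, normalize = "minmax", local_by = "site"),
    benchmark = list(score_col = "score", higher_is_better = TRUE,
                     level = "protein", n_folds = 10, num_trees = 500,
                     threshold = 0.5)
  )
}

#' Load and validate a pipeline configuration file
#'
#' YAML or JSON; values override the defaults of [pp_default_config()].
#' Unknown keys abort with the offending names so typos never silently
#' fall back to defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`); `NULL` gives the
#'   defaults.
#' @param overrides named list applied after the file (e.g. from CLI
#'   flags), same validation.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- pp_default_config()
  apply_over <- function(base, over, where) {
    bad <- setdiff(names(over), names(base))
    if (length(bad) > 0) {
      abort(paste0("unknown config key(s) ", where, ": ",
                   paste(bad, collapse = ", "),
                   " (known: ", paste(names(base), collapse = ", "), ")"))
    }
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        apply_over(base[[nm]], over[[nm]], paste0(where, nm, "."))
      } else {
        over[[nm]]
      }
    }
    base
  }
  file_cfg <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    file_cfg <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      abort("config must be .yaml/.yml/.json")
    }
    cfg <- apply_over(cfg, file_cfg, "")
  }
  cfg <- apply_over(cfg, overrides, "")
  cfg$seed <- as.integer(cfg$seed)
  # the generator seed follows the master seed unless set explicitly
  explicit <- !is.null(file_cfg$synth$seed) || !is.null(overrides$synth$seed)
  if (!explicit) cfg$synth$seed <- cfg$seed
  cfg$synth$seed <- as.integer(cfg$synth$seed)
  cfg
}

stage_paths <- function(cfg) {
  w <- cfg$workdir
  list(
    universe = file.path(w, "universe"),
    network = file.path(w, "network.json"),
    network_integrated = file.path(w, "network_integrated.json"),
    pair_model = file.path(w, "models", "pair_classifier.rds"),
    predictions = file.path(w, "predictions.tsv"),
    metrics = file.path(w, "metrics")
  )
}

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(paste0("missing upstream artifact ", path,
                 "; run the `", producer, "` stage first"))
  }
  path
}

read_universe_dir <- function(dir) {
  need_artifact(file.path(dir, "compounds.tsv"), "simulate")
  nm <- c("compounds", "ligand_sim", "sites", "site_comparisons",
          "interactions", "queries", "query_sim", "model_sites",
          "model_comparisons", "model_identity", "truth")
  out <- lapply(nm, function(x) {
    readr::read_tsv(file.path(dir, paste0(x, ".tsv")), comment = "#",
                    show_col_types = FALSE, progress = FALSE)
  })
  names(out) <- nm
  out$compounds$fingerprint <- rep(list(NULL), nrow(out$compounds))
  out$queries$fingerprint <- rep(list(NULL), nrow(out$queries))
  out
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    tool = "pocketpath",
    version = as.character(utils::packageVersion("pocketpath")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "workdir")],
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) unname(tools::md5sum(p))),
    outputs = as.list(basename(outputs))
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$workdir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' File-based orchestration of the end-to-end flow; stages chain through
#' artifacts under `config$workdir` and each writes a provenance manifest
#' (inputs' checksums, configuration, seed, tool version).
#'
#' * `simulate` — generate the synthetic universe TSVs;
#' * `build` — drug-likeness filter, edge thresholds, condensation,
#'   interaction linking; writes `network.json`;
#' * `integrate` — modeled-site filters + query integration; writes
#'   `network_integrated.json`;
#' * `train` — fit the compound-pair classifier on the universe's
#'   compounds (SMILES-derived features, Tanimoto-rule labels); writes a
#'   model artifact;
#' * `predict` — bounded shortest-path search; writes `predictions.tsv`;
#' * `benchmark` — meta-classifier cross-validation (id-aware and
#'   anonymous) plus the evaluation battery; writes metrics files.
#'
#' @param stage one of `"simulate"`, `"build"`, `"integrate"`, `"train"`,
#'   `"predict"`, `"benchmark"`.
#' @param config configuration list from [load_config()].
#' @return invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage = c("simulate", "build", "integrate", "train",
                                "predict", "benchmark"),
                      config = load_config()) {
  stage <- match.arg(stage)
  p <- stage_paths(config)
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    simulate = stage_simulate(config, p),
    build = stage_build(config, p),
    integrate = stage_integrate(config, p),
    train = stage_train(config, p),
    predict = stage_predict(config, p),
    benchmark = stage_benchmark(config, p)
  )
  invisible(out)
}

stage_simulate <- function(cfg, p) {
  sc <- do.call(synth_config, cfg$synth)
  generate_universe(sc, dir = p$universe)
  write_manifest(cfg, "simulate", character(),
                 list.files(p$universe, full.names = TRUE))
  c(universe = p$universe)
}

stage_build <- function(cfg, p) {
  uni <- read_universe_dir(p$universe)
  net <- do.call(build_core_network, c(list(universe = uni), cfg$build))
  write_network(net, p$network)
  write_clusters(attr(net, "ligand_clusters"),
                 file.path(cfg$workdir, "ligand_clusters.tsv"))
  write_clusters(attr(net, "site_clusters"),
                 file.path(cfg$workdir, "site_clusters.tsv"))
  write_manifest(cfg, "build", list.files(p$universe, full.names = TRUE),
                 p$network)
  c(network = p$network)
}

stage_integrate <- function(cfg, p) {
  need_artifact(p$network, "build")
  uni <- read_universe_dir(p$universe)
  net <- read_network(p$network)
  ic <- cfg$integrate
  net <- integrate_target_sites(net, uni$model_sites, uni$model_comparisons,
                                site_identity = uni$model_identity,
                                quality_min = ic$quality_min,
                                id_min = ic$id_min,
                                min_residues = ic$min_residues,
                                redundancy_pct = ic$redundancy_pct,
                                z_min = ic$z_min)
  net <- integrate_query_compounds(net, uni$queries,
                                   pair_probs = uni$query_sim,
                                   threshold = ic$query_threshold)
  write_network(net, p$network_integrated)
  write_manifest(cfg, "integrate", c(p$network), p$network_integrated)
  c(network = p$network_integrated)
}

stage_train <- function(cfg, p) {
  uni <- read_universe_dir(p$universe)
  cmp <- featurize_compounds(uni$compounds)
  feats <- compound_pair_features(cmp)
  # positive pairs share a scaffold family (the planted notion of
  # "binds the same kind of pocket"); features are chemistry-derived
  fam <- uni$compounds$scaffold[match(feats$id_a, uni$compounds$id)]
  fam_b <- uni$compounds$scaffold[match(feats$id_b, uni$compounds$id)]
  feats$label <- fam == fam_b
  model <- train_pair_classifier(feats, num_trees = cfg$train$num_trees,
                                 seed = cfg$seed)
  dir.create(dirname(p$pair_model), showWarnings = FALSE, recursive = TRUE)
  save_model(model, p$pair_model)
  write_manifest(cfg, "train", file.path(p$universe, "compounds.tsv"),
                 p$pair_model)
  c(model = p$pair_model)
}

stage_predict <- function(cfg, p) {
  need_artifact(p$network_integrated, "integrate")
  net <- read_network(p$network_integrated)
  pred <- predict_all(net, d_max = cfg$predict$d_max,
                      normalize = cfg$predict$normalize,
                      local_by = cfg$predict$local_by)
  write_predictions(pred, p$predictions)
  write_manifest(cfg, "predict", p$network_integrated, p$predictions)
  c(predictions = p$predictions)
}

stage_benchmark <- function(cfg, p) {
  need_artifact(p$predictions, "predict")
  uni <- read_universe_dir(p$universe)
  pred <- readr::read_tsv(p$predictions, show_col_types = FALSE,
                          progress = FALSE)
  bc <- cfg$benchmark
  labeled <- pred |>
    inner_join(uni$truth, by = c("query_id", "protein_id"))
  dir.create(p$metrics, showWarnings = FALSE, recursive = TRUE)
  meta_anon <- train_meta_classifier(labeled, use_compound_id = FALSE,
                                     num_trees = bc$num_trees,
                                     n_folds = bc$n_folds, seed = cfg$seed)
  meta_id <- train_meta_classifier(labeled, use_compound_id = TRUE,
                                   num_trees = bc$num_trees,
                                   n_folds = bc$n_folds, seed = cfg$seed)
  classified <- classify_predictions(meta_anon, pred, threshold = bc$threshold)
  ev <- evaluate_predictions(classified, uni$truth, score_col = bc$score_col,
                             higher_is_better = bc$higher_is_better,
                             level = bc$level, threshold = bc$threshold)
  write_evaluation(ev, file.path(p$metrics, "evaluation"))
  cv <- bind_rows(
    glance(meta_anon) |> mutate(model = "anonymous", .before = 1),
    glance(meta_id) |> mutate(model = "id_aware", .before = 1)
  )
  readr::write_tsv(cv, file.path(p$metrics, "meta_cv.tsv"), progress = FALSE)
  write_manifest(cfg, "benchmark",
                 c(p$predictions, file.path(p$universe, "truth.tsv")),
                 list.files(p$metrics, full.names = TRUE))
  c(metrics = p$metrics)
}
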
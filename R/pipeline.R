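#' Pipeline configuration
#'
#' Normalizes a configuration (a list or a YAML file path) for
#' [run_pipeline()] and the stage functions. Required fields: `complexes`
#' (list of entries with `path`, `chains = list(P =, I =)` and optional
#' `id`) and `output`. Optional fields with defaults: `variance_threshold`
#' (0.95), `p_max` (0.90), `n_max` (30), `min_support` (0.5),
#' `support_grid` (0.1..1.0 step 0.1, set `sweep = TRUE` to run it),
#' `seed` (0), `criteria` (window overrides), `reference` (path to a YAML
#' reference set for the evaluation stage), `max_pattern_nodes`.
#'
#' @param config a list or path to a YAML file.
#' @return A validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$output)) stop("config needs an 'output' directory")
  if (is.null(config$complexes) || length(config$complexes) == 0) {
    stop("config needs a non-empty 'complexes' list")
  }
  for (cx in config$complexes) {
    if (is.null(cx$path)) stop("every complex needs a 'path'")
    if (is.null(cx$chains) || is.null(cx$chains$P) || is.null(cx$chains$I)) {
      stop("every complex needs 'chains' with P and I groups")
    }
  }
  config$variance_threshold <- config$variance_threshold %||% 0.95
  config$p_max <- config$p_max %||% 0.90
  config$n_max <- config$n_max %||% 30
  config$min_support <- config$min_support %||% 0.5
  config$support_grid <- config$support_grid %||% seq(0.1, 1.0, by = 0.1)
  config$sweep <- isTRUE(config$sweep)
  config$seed <- config$seed %||% 0
  config$max_pattern_nodes <- config$max_pattern_nodes %||% Inf
  config
}

.stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$output, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.need <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, "; run the '", producer, "' stage first")
  }
  path
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's persisted artifacts from the
#' configured output directory and writes its own, so single-stage runs
#' compose to exactly the result of [run_pipeline()].
#'
#' * `stage_graphs()`: parse complexes, build pruned bipartite contact
#'   multigraphs, extract components; writes JSON node-link + GraphML per
#'   complex and `manifest.json` under `graphs/`.
#' * `stage_features()`: counting matrix (`features/counting.csv`) and the
#'   default-threshold reduced matrix (`features/theta.csv`).
#' * `stage_cluster()`: joint (d, n, k) selection, spectral clustering;
#'   writes `clusters/assignments.csv`, `clusters/per_d_report.csv`,
#'   `clusters/params.json`.
#' * `stage_mine()`: per-cluster gSpan at `min_support` + maximal filter;
#'   writes `patterns/cluster_<c>.json` and optionally
#'   `patterns/support_sweep.csv`.
#' * `stage_map()`: maps every pattern onto its occurrence graphs; writes
#'   `mappings/mappings.json`.
#' * `stage_evaluate()`: precision/recall against the configured reference
#'   set; writes `report/evaluation.csv`.
#'
#' @param cfg a config accepted by [pipeline_config()].
#' @return Each stage invisibly returns its main in-memory result.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_graphs <- function(cfg) {
  cfg <- pipeline_config(cfg)
  typing <- if (!is.null(cfg$typing_table)) {
    tibble::as_tibble(utils::read.csv(cfg$typing_table, stringsAsFactors = FALSE))
  } else {
    default_typing_table()
  }
  criteria <- contact_criteria(cfg$criteria)
  atom_tables <- purrr::map(cfg$complexes, function(cx) {
    atoms <- read_interface_atoms(
      cx$path, list(P = cx$chains$P, I = cx$chains$I),
      complex_id = cx$id %||% NULL
    )
    assign_atom_labels(atoms, typing)
  })
  dataset <- build_graph_dataset(atom_tables, criteria, typing)
  write_graph_dataset(dataset, .stage_dir(cfg, "graphs"))
  invisible(dataset)
}

#' @rdname pipeline_stages
#' @export
stage_features <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dataset <- read_graph_dataset(.need(
    file.path(cfg$output, "graphs", "manifest.json"), "graphs"
  ) |> dirname())
  cm <- build_counting_matrix(dataset)
  fdir <- .stage_dir(cfg, "features")
  utils::write.csv(cm, file.path(fdir, "counting.csv"), row.names = FALSE)
  red <- reduce_counting_matrix(cm, threshold = cfg$variance_threshold)
  theta <- as.data.frame(red$theta)
  names(theta) <- paste0("component_", seq_len(ncol(theta)))
  utils::write.csv(
    cbind(graph_id = cm$graph_id, theta),
    file.path(fdir, "theta.csv"),
    row.names = FALSE
  )
  invisible(cm)
}

.read_counting <- function(cfg) {
  path <- .need(file.path(cfg$output, "features", "counting.csv"), "features")
  cm <- tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  cm$graph_id <- as.character(cm$graph_id)
  cm
}

#' @rdname pipeline_stages
#' @export
stage_cluster <- function(cfg) {
  cfg <- pipeline_config(cfg)
  cm <- .read_counting(cfg)
  p_grid <- seq(0.01, cfg$p_max, by = 0.01)
  sel <- select_parameters(
    cm, threshold = cfg$variance_threshold, p_grid = p_grid, n_max = cfg$n_max
  )
  red <- reduce_counting_matrix(cm, d = sel$d)
  cl <- spectral_cluster(red, n = sel$n, k = sel$k, seed = cfg$seed)
  cdir <- .stage_dir(cfg, "clusters")
  manifest <- read_graph_dataset(file.path(cfg$output, "graphs"))
  assignments <- dplyr::left_join(
    dplyr::mutate(cl$assignments, graph_id = as.integer(.data$graph_id)),
    manifest[, c("graph_id", "complex_id", "component")],
    by = "graph_id"
  )
  utils::write.csv(
    assignments[, c("graph_id", "complex_id", "component", "cluster")],
    file.path(cdir, "assignments.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    sel$report, file.path(cdir, "per_d_report.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(d = sel$d, n = sel$n, k = sel$k, seed = cfg$seed),
    file.path(cdir, "params.json"),
    auto_unbox = TRUE
  )
  invisible(cl)
}

#' @rdname pipeline_stages
#' @export
stage_mine <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dataset <- read_graph_dataset(file.path(cfg$output, "graphs"))
  assignments <- utils::read.csv(
    .need(file.path(cfg$output, "clusters", "assignments.csv"), "cluster")
  )
  pdir <- .stage_dir(cfg, "patterns")
  graphs <- stats::setNames(
    lapply(dataset$graph, to_simple_graph), as.character(dataset$graph_id)
  )
  out <- list()
  for (cl in sort(unique(assignments$cluster))) {
    gids <- as.character(assignments$graph_id[assignments$cluster == cl])
    cluster_graphs <- graphs[gids]
    pats <- gspan(
      cluster_graphs, cfg$min_support,
      max_pattern_nodes = cfg$max_pattern_nodes
    )
    pats <- filter_maximal(pats)
    write_patterns(pats, file.path(pdir, sprintf("cluster_%d.json", cl)))
    if (cfg$sweep) {
      sw <- support_sweep(
        cluster_graphs, cfg$support_grid,
        max_pattern_nodes = cfg$max_pattern_nodes
      )
      sw$cluster <- cl
      out$sweep <- dplyr::bind_rows(out$sweep, sw)
    }
    pats$cluster <- cl
    out$patterns <- dplyr::bind_rows(out$patterns, pats)
  }
  if (cfg$sweep) {
    utils::write.csv(
      out$sweep, file.path(pdir, "support_sweep.csv"),
      row.names = FALSE
    )
  }
  invisible(out$patterns)
}

.read_cluster_patterns <- function(cfg) {
  pdir <- file.path(cfg$output, "patterns")
  files <- list.files(pdir, pattern = "^cluster_[0-9]+\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no pattern files under ", pdir, "; run the 'mine' stage first")
  rows <- purrr::map(files, function(f) {
    cl <- as.integer(sub("^cluster_([0-9]+)\\.json$", "\\1", basename(f)))
    pats <- read_patterns(f)
    if (nrow(pats) > 0) pats$cluster <- cl
    pats
  })
  dplyr::bind_rows(rows)
}

#' @rdname pipeline_stages
#' @export
stage_map <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dataset <- read_graph_dataset(file.path(cfg$output, "graphs"))
  patterns <- .read_cluster_patterns(cfg)
  mdir <- .stage_dir(cfg, "mappings")
  mappings <- list()
  for (cl in unique(patterns$cluster)) {
    sub <- patterns[patterns$cluster == cl, , drop = FALSE]
    # pattern ids are unique within a cluster only
    sub$pattern_id <- paste0(cl, ":", sub$pattern_id)
    m <- map_all(sub, dataset)
    if (nrow(m) > 0) m$cluster <- cl
    mappings[[length(mappings) + 1]] <- m
  }
  mappings <- dplyr::bind_rows(mappings)
  write_mappings(mappings, file.path(mdir, "mappings.json"))
  invisible(mappings)
}

#' @rdname pipeline_stages
#' @export
stage_evaluate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  if (is.null(cfg$reference)) stop("config needs a 'reference' YAML for evaluation")
  ref <- read_reference_set(cfg$reference)
  patterns <- .read_cluster_patterns(cfg)
  mappings <- read_mappings(.need(
    file.path(cfg$output, "mappings", "mappings.json"), "map"
  ))
  rel <- list()
  for (cl in unique(patterns$cluster)) {
    sub <- patterns[patterns$cluster == cl, , drop = FALSE]
    sub$pattern_id <- paste0(cl, ":", sub$pattern_id)
    msub <- mappings[mappings$cluster == cl, , drop = FALSE]
    r <- pattern_relevance(sub, msub, ref)
    r$group <- as.character(cl)
    rel[[length(rel) + 1]] <- r
  }
  report <- precision_recall(dplyr::bind_rows(rel), ref)
  rdir <- .stage_dir(cfg, "report")
  utils::write.csv(report, file.path(rdir, "evaluation.csv"), row.names = FALSE)
  invisible(report)
}

#' Run the full interface-mining pipeline
#'
#' Executes the stages in order — graphs, features, cluster, mine, map and
#' (when a reference set is configured) evaluate — persisting every
#' intermediate artifact under the configured output directory, so any
#' stage can be re-run individually from the previous stage's files. All
#' randomness flows from the single configured seed.
#'
#' @param config a config list or YAML path ([pipeline_config()]).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  stages <- list(
    graphs = stage_graphs, features = stage_features,
    cluster = stage_cluster, mine = stage_mine, map = stage_map
  )
  if (!is.null(cfg$reference)) stages$evaluate <- stage_evaluate
  for (nm in names(stages)) {
    tryCatch(
      stages[[nm]](cfg),
      error = function(e) {
        stop("pipeline stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  invisible(cfg$output)
}
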
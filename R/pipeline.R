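#' @name pipeline
#' @title End-to-end similarity pipeline
NULL

#' Run configuration for the full pipeline
#'
#' Thresholds default to the study's screening choices: cosine 0.77 (the
#' P95 of the cosine distribution) and Jaccard 0.50 (chosen above the
#' uninformative Jaccard P95 of 0.32).
#'
#' @param nodes_path,edges_path input TSV paths.
#' @param annotations_path optional annotation TSV for exclusion rules.
#' @param out_dir artifact directory.
#' @param train a [make_train_config()] block.
#' @param metrics similarity metrics to compute.
#' @param cosine_threshold,jaccard_threshold screening thresholds.
#' @param feature_scheme node feature scheme, see [init_features()].
#' @param seed master seed; stage streams derive from it (see
#'   [derive_seed()]). Overrides `train$seed`.
#' @return a `run_config` list.
#' @export
make_run_config <- function(nodes_path, edges_path, annotations_path = NULL,
                            out_dir = "prescsim-out",
                            train = make_train_config(),
                            metrics = c("cosine", "jaccard"),
                            cosine_threshold = 0.77,
                            jaccard_threshold = 0.50,
                            feature_scheme = "identity",
                            seed = 1L) {
  metrics <- match.arg(metrics, c("cosine", "jaccard"), several.ok = TRUE)
  if (cosine_threshold < -1 || cosine_threshold > 1)
    stopf("cosine threshold outside [-1, 1]", class = "prescsim_config_error")
  if (jaccard_threshold < 0 || jaccard_threshold > 1)
    stopf("jaccard threshold outside [0, 1]", class = "prescsim_config_error")
  train$seed <- as.integer(seed)
  structure(list(nodes_path = nodes_path, edges_path = edges_path,
                 annotations_path = annotations_path, out_dir = out_dir,
                 train = train, metrics = metrics,
                 cosine_threshold = cosine_threshold,
                 jaccard_threshold = jaccard_threshold,
                 feature_scheme = feature_scheme, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
          class = "prescsim_pipeline_error")
  })
}

#' Run the full similarity pipeline
#'
#' build -> train -> similarity (per metric) -> summarize -> screen ->
#' exclusions, writing every artifact plus a JSON manifest (package
#' version, seed, config, input MD5 hashes) sufficient to reproduce the
#' run. Training is skipped when only the Jaccard metric is requested —
#' set similarity needs no embeddings. Idempotent for a fixed seed.
#'
#' @param config a [make_run_config()] list.
#' @return invisibly, a list with the graph, embeddings, per-metric
#'   similarity tables, stats, screen results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  nodes <- pipeline_stage("read", read_node_table(config$nodes_path))
  edges <- pipeline_stage("read", read_edge_table(config$edges_path, nodes))
  graph <- pipeline_stage("build",
    build_graph(nodes, edges, feature_scheme = config$feature_scheme))
  jsonlite::write_json(graph_summary(graph), file.path(out, "graph_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  embeddings <- NULL
  if ("cosine" %in% config$metrics) {
    embeddings <- pipeline_stage("train", train_dgi(graph, config$train))
    write_embeddings(embeddings, file.path(out, "embeddings.tsv"))
  }

  annotations <- NULL
  if (!is.null(config$annotations_path))
    annotations <- pipeline_stage("read",
      read_annotation_table(config$annotations_path))

  tables <- list(); stats <- list(); screens <- list()
  for (metric in config$metrics) {
    tab <- pipeline_stage("similarity",
      pairwise_similarity(graph, embeddings, metric = metric))
    tables[[metric]] <- tab
    stats[[metric]] <- pipeline_stage("summarize", summary_stats(tab$value))
    thr <- if (metric == "cosine") config$cosine_threshold else
      config$jaccard_threshold
    sc <- pipeline_stage("screen", screen_pairs(tab, thr))
    if (!is.null(annotations))
      sc <- pipeline_stage("exclusions", apply_exclusions(sc, annotations))
    screens[[metric]] <- sc
    write_screen_report(sc, file.path(out, sprintf("screen_%s.tsv", metric)))
  }
  write_similarity_table(do.call(rbind, unname(tables)),
                         file.path(out, "similarities.tsv"))
  write_stats_json(lapply(stats, unclass), file.path(out, "stats.json"))

  manifest <- list(
    package = "prescsim",
    version = as.character(utils::packageVersion("prescsim")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "train")],
    train = unclass(config$train),
    input_md5 = as.list(tools::md5sum(c(config$nodes_path, config$edges_path))),
    final_objective = if (!is.null(embeddings)) embeddings$objective else NULL
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(graph = graph, embeddings = embeddings, tables = tables,
                 stats = stats, screens = screens, out_dir = out))
}
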
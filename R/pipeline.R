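#' Pipeline run configuration
#'
#' Bundles the parameters of both pipelines. Defaults are the reference
#' analysis settings for a large metropolitan registry: affinity threshold
#' `k = 100`, 3-core, 10 clustering runs, a 64 x 64 grid with at least 50
#' persons per cell, Euclidean chord distance, 250 MMST iterations with the
#' first 20 trees aggregated. Smaller synthetic datasets need `k`, the grid
#' resolution, and `min_count` rescaled to their density (see the package
#' vignette).
#'
#' @param input path to a person-record file, or a [city_config()] to
#'   generate records on the fly
#' @param k affinity security multiplier
#' @param k_core_min minimum core degree
#' @param runs clustering runs for the consensus
#' @param nx,ny grid resolution
#' @param min_count minimum persons per retained cell
#' @param metric isonymic distance metric for the spatial network
#' @param n_iter MMST iterations
#' @param aggregate fixed aggregation depth (`NULL` to use [choose_depth()])
#' @param seed master seed; stages derive sub-seeds via [sub_seed()]
#' @param out_dir optional output directory; when non-`NULL` all
#'   intermediate artifacts are written there
#' @return a `run_config` list
#' @export
run_config <- function(input, k = 100, k_core_min = 3L, runs = 10L,
                       nx = 64L, ny = 64L, min_count = 50L,
                       metric = "euclid", n_iter = 250L, aggregate = 20L,
                       seed = 1L, out_dir = NULL) {
  structure(list(input = input, k = k, k_core_min = k_core_min,
                 runs = as.integer(runs), nx = as.integer(nx),
                 ny = as.integer(ny), min_count = as.integer(min_count),
                 metric = metric, n_iter = as.integer(n_iter),
                 aggregate = if (is.null(aggregate)) NULL else as.integer(aggregate),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_records <- function(config) {
  if (inherits(config$input, "city_config")) {
    generate_city(config$input)
  } else if (is.data.frame(config$input)) {
    config$input
  } else {
    read_person_records(config$input)
  }
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

prepare_records <- function(records) {
  if (is.null(records$ses)) {
    ses <- with_stage("normalize_ses", block_ses_index(records))
    records <- with_stage("assign_person_ses", assign_person_ses(records, ses))
  }
  records
}

#' Run the paternal-maternal affinity pipeline
#'
#' records -> [count_pairs()] -> [affinity_filter()] -> [k_core()] ->
#' [detect_consensus()] -> [cluster_ses()] + [top_degree_surnames()]
#' (+ [cohort_representation()] when a cohort table is supplied).
#'
#' @param config a [run_config()]
#' @param cohort optional data.frame (`period`, `surname`, optionally
#'   `member_id`) for historical representation
#' @return a report list with stage-by-stage node/edge counts, the
#'   consensus partition, per-cluster SES, and top-degree surnames
#' @export
run_affinity_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  records <- with_stage("load_records", load_records(config))
  records <- prepare_records(records)

  g0 <- with_stage("count_pairs", count_pairs(records))
  g1 <- with_stage("affinity_filter", affinity_filter(g0, k = config$k))
  g2 <- with_stage("k_core", k_core(g1, k_core_min = config$k_core_min))
  if (igraph::vcount(g2) == 0L) stop("pipeline stage 'k_core' failed: empty core")
  part <- with_stage("detect_consensus",
                     detect_consensus(g2, n_runs = config$runs,
                                      seed = sub_seed(config$seed, "affinity_louvain")))
  sses <- with_stage("surname_ses", surname_ses(records))
  report <- list(
    stages = list(
      persons = nrow(records),
      pair_graph = c(nodes = igraph::vcount(g0), edges = igraph::ecount(g0)),
      affinity = c(nodes = igraph::vcount(g1), edges = igraph::ecount(g1)),
      core = c(nodes = igraph::vcount(g2), edges = igraph::ecount(g2))
    ),
    graph = g2,
    partition = part,
    modularity_range = part$modularity_range,
    cluster_ses = with_stage("cluster_ses", cluster_ses(part, sses)),
    top_surnames = with_stage("top_degree_surnames", top_degree_surnames(part, g2)),
    surname_ses = sses
  )
  if (!is.null(cohort)) {
    report$cohort_representation <-
      with_stage("cohort_representation", cohort_representation(cohort, part))
  }
  if (!is.null(config$out_dir)) write_affinity_artifacts(report, config)
  report
}

#' Run the spatial isonymy pipeline
#'
#' records -> [grid_bin()] -> [distance_matrix()] (all three metrics, with
#' a [separability_report()] each) -> [mmst()] -> [choose_depth()] or the
#' fixed depth -> [aggregate_skeleton()] -> [network_stats()] ->
#' [detect_consensus()] -> per-community alpha, [salient_surnames()], and
#' [alpha_ses_correlation()].
#'
#' Community detection runs on the unweighted skeleton: membership in an
#' early minimum spanning tree is the signal; the residual edge distances
#' are not re-used as modularity weights.
#'
#' @param config a [run_config()]
#' @return a report list with the cell table, separability summaries, the
#'   skeleton run and its statistics, the consensus partition over cells,
#'   per-community mean alpha, salient surnames, and the alpha-SES
#'   correlation
#' @export
run_isonymy_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- with_stage("load_records", load_records(config))
  records <- prepare_records(records)
  ext <- if (inherits(config$input, "city_config")) config$input$grid_extent
         else c(min(records$x), max(records$x), min(records$y), max(records$y))

  cells <- with_stage("grid_bin",
                      grid_bin(records, ext, nx = config$nx, ny = config$ny,
                               min_count = config$min_count))
  if (nrow(cells$cells) < 2L) stop("pipeline stage 'grid_bin' failed: fewer than 2 retained cells")

  metrics <- c("lasker", "nei", "euclid")
  dms <- lapply(metrics, function(m) with_stage(paste0("distance_", m),
                                                distance_matrix(cells, metric = m)))
  names(dms) <- metrics
  sep <- lapply(dms, function(d) with_stage("separability_report", separability_report(d)))

  dm <- if (config$metric %in% metrics) dms[[config$metric]]
        else with_stage("distance_matrix", distance_matrix(cells, metric = config$metric))
  run <- with_stage("mmst", mmst(dm, n_iter = config$n_iter))
  depth <- if (!is.null(config$aggregate)) {
    min(config$aggregate, length(run$trees))
  } else {
    with_stage("choose_depth", choose_depth(run))
  }
  skel <- with_stage("aggregate_skeleton", aggregate_skeleton(run, depth))
  stats <- with_stage("network_stats", network_stats(skel))
  part <- with_stage("detect_consensus",
                     detect_consensus(skel, n_runs = config$runs,
                                      seed = sub_seed(config$seed, "isonymy_louvain"),
                                      weighted = FALSE))

  alpha_by_cell <- stats::setNames(cells$cells$alpha, cells$cells$cell_id)
  comm_alpha <- tapply(alpha_by_cell[names(part$membership)], part$membership, mean)
  report <- list(
    cells = cells,
    n_candidate_cells = cells$grid$n_candidate_cells,
    separability = sep,
    distance = dm,
    skeleton_run = run,
    depth = depth,
    skeleton = skel,
    network_stats = stats,
    partition = part,
    community_alpha = stats::setNames(as.numeric(comm_alpha), names(comm_alpha)),
    salient_surnames = with_stage("salient_surnames", salient_surnames(cells, part)),
    alpha_ses_correlation = with_stage("alpha_ses_correlation", alpha_ses_correlation(cells))
  )
  if (!is.null(config$out_dir)) write_isonymy_artifacts(report, config)
  report
}

write_affinity_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_surname_graph(report$graph, file.path(config$out_dir, "affinity_graph.tsv"))
  write_surname_graph(report$graph, file.path(config$out_dir, "affinity_graph.graphml"),
                      format = "graphml")
  write_partition(report$partition, file.path(config$out_dir, "affinity_partition.csv"),
                  cluster_ses = report$cluster_ses)
  invisible(NULL)
}

write_isonymy_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(report$cells,
                   file.path(config$out_dir, "cell_frequencies.csv"),
                   file.path(config$out_dir, "cell_summary.csv"))
  write_distance_matrix(report$distance, file.path(config$out_dir, "distances.csv"))
  write_d_values(report$skeleton_run, file.path(config$out_dir, "d_values.tsv"))
  write_surname_graph(report$skeleton, file.path(config$out_dir, "skeleton.tsv"))
  write_surname_graph(report$skeleton, file.path(config$out_dir, "skeleton.graphml"),
                      format = "graphml")
  write_partition(report$partition, file.path(config$out_dir, "isonymy_partition.csv"))
  invisible(NULL)
}

#' Re-analyse deposited affinity and isonymy networks
#'
#' Loads the two networks deposited alongside the original analysis
#' (weighted edge lists named `affinity_edges.*` and `isonymy_edges.*`,
#' tab- or comma-separated, two node columns and an optional weight) from a
#' local directory and recomputes consensus communities, modularity, and
#' the isonymy network's diameter. The deposit must be downloaded
#' separately (figshare collection); this function performs no network
#' access.
#'
#' @param dir directory containing the downloaded edge lists
#' @param runs,seed consensus parameters
#' @return list with per-network consensus partitions and
#'   [network_stats()]
#' @export
deposited_network_checks <- function(dir, runs = 10L, seed = 1L) {
  find_one <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem), full.names = TRUE)
    if (length(hits) == 0L) {
      stop("deposited_network_checks: no file matching '", stem, "*' in ", dir,
           " (download the deposited networks first)")
    }
    hits[1]
  }
  read_edges <- function(path) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
    if (ncol(df) >= 3) igraph::E(g)$weight <- as.numeric(df[[3]])
    igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
  }
  aff <- read_edges(find_one("affinity_edges"))
  iso <- read_edges(find_one("isonymy_edges"))
  list(
    affinity = list(
      partition = detect_consensus(aff, n_runs = runs, seed = sub_seed(seed, "dep_aff")),
      stats = network_stats(aff)
    ),
    isonymy = list(
      partition = detect_consensus(iso, n_runs = runs, seed = sub_seed(seed, "dep_iso"),
                                   weighted = FALSE),
      stats = network_stats(iso)
    )
  )
}
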
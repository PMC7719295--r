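#' @title Pipeline orchestration and reports
#' @name pipeline
#' @description
#' Thin orchestration wrappers, one per analysis stage, that read the
#' standard TSV inputs, call the corresponding module function, and
#' write TSV/JSON reports plus a machine-readable provenance block
#' (package version, configuration echo, seed, input checksums) into
#' an output directory. `run_all()` chains every stage. These
#' functions are the scripted interface of the package; each is a thin
#' shell over one module so results are identical to calling the
#' module functions directly.
NULL

.provenance <- function(out_dir, stage, config, inputs = character(0)) {
  prov <- list(
    stage = stage,
    package = "endonet",
    version = as.character(utils::packageVersion("endonet")),
    r_version = as.character(getRversion()),
    config = config,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(prov)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Classify a hit table and write assignments
#'
#' @param hits_path TSV hit table (see [read_hit_table()]).
#' @param out_dir output directory.
#' @param rules a `rank_rules` object or path to a YAML rules file.
#' @return Path of the written assignments TSV, invisibly.
#' @export
run_classify <- function(hits_path, out_dir, rules = default_rank_rules()) {
  .ensure_dir(out_dir)
  if (is.character(rules)) rules <- read_rank_rules(rules)
  assignments <- classify_hits(read_hit_table(hits_path), rules)
  out <- file.path(out_dir, "assignments.tsv")
  write_assignments(assignments, out)
  .provenance(out_dir, "classify",
              list(min_coverage = attr(rules, "min_coverage")),
              hits_path)
  invisible(out)
}

#' Build the interaction matrix and write matrix + edge list
#'
#' @param assignments_path assignments TSV from [run_classify()].
#' @param hits_path the hit table carrying read counts.
#' @param out_dir output directory.
#' @return Path of the written matrix TSV, invisibly.
#' @export
run_matrix <- function(assignments_path, hits_path, out_dir) {
  .ensure_dir(out_dir)
  assignments <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  hits <- read_hit_table(hits_path)
  m <- build_interaction_matrix(assignments, hits)
  out <- file.path(out_dir, "matrix.tsv")
  write_matrix_tsv(m, out)
  utils::write.table(to_edge_list(m), file.path(out_dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .provenance(out_dir, "matrix", list(), c(assignments_path, hits_path))
  invisible(out)
}

#' Compute and write the network-level report
#'
#' @param matrix_path matrix TSV.
#' @param out_dir output directory.
#' @return The `network_report`, invisibly.
#' @export
run_network <- function(matrix_path, out_dir) {
  .ensure_dir(out_dir)
  report <- network_report(read_matrix_tsv(matrix_path))
  write_network_report(report,
                       path_tsv = file.path(out_dir, "network_report.tsv"),
                       path_json = file.path(out_dir, "network_report.json"))
  .provenance(out_dir, "network", list(), matrix_path)
  invisible(report)
}

#' Compute and write node-level reports for both levels
#'
#' @inheritParams run_network
#' @return The combined node report, invisibly.
#' @export
run_nodes <- function(matrix_path, out_dir) {
  .ensure_dir(out_dir)
  m <- read_matrix_tsv(matrix_path)
  report <- node_report(m, "both")
  write_node_report(report[report$level == "HL", ],
                    file.path(out_dir, "nodes_HL.tsv"))
  write_node_report(report[report$level == "LL", ],
                    file.path(out_dir, "nodes_LL.tsv"))
  .provenance(out_dir, "nodes", list(), matrix_path)
  invisible(report)
}

#' Maximize modularity and write the partition
#'
#' @inheritParams run_network
#' @param config an [sa_config()].
#' @return The `sa_partition`, invisibly.
#' @export
run_modules <- function(matrix_path, out_dir, config = sa_config()) {
  .ensure_dir(out_dir)
  fit <- optimize_modularity(read_matrix_tsv(matrix_path), config)
  write_partition(fit, path_tsv = file.path(out_dir, "partition.tsv"),
                  path_json = file.path(out_dir, "modules.json"))
  .provenance(out_dir, "modules",
              unclass(config)[c("t0", "cooling", "t_min", "seed", "weighted")],
              matrix_path)
  invisible(fit)
}

#' Annotate guilds and write the trophic partition
#'
#' @param assignments_path assignments TSV from [run_classify()].
#' @param out_dir output directory.
#' @param db_path guild database TSV (default: the bundled snapshot).
#' @return The `trophic_partition`, invisibly.
#' @export
run_guilds <- function(assignments_path, out_dir,
                       db_path = system.file("extdata", "myrtle_guilds.tsv",
                                             package = "endonet")) {
  .ensure_dir(out_dir)
  assignments <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  db <- load_guild_db(db_path)
  annotated <- annotate_guilds(assignments, db)
  flat <- annotated
  flat$modes <- vapply(annotated$modes, paste, character(1), collapse = "-")
  utils::write.table(flat, file.path(out_dir, "guilds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  partition <- trophic_partition(annotated)
  write_trophic_partition(partition,
                          file.path(out_dir, "trophic_partition.json"))
  .provenance(out_dir, "guilds", list(), c(assignments_path, db_path))
  invisible(partition)
}

#' Simulate a fixture bundle
#'
#' Writes a synthetic hit table and interaction matrix (with planted
#' ground truth) in the same TSV dialects the pipeline consumes.
#'
#' @param out_dir output directory.
#' @param spec a [community_spec()].
#' @param hits_spec optional [hit_table_spec()]; when `NULL` a small
#'   default panel spanning every rank rule interval is used.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, spec = community_spec(11, 45, "random", p = 0.19),
                         hits_spec = NULL) {
  .ensure_dir(out_dir)
  sim <- gen_matrix(spec)
  write_matrix_tsv(sim$matrix, file.path(out_dir, "sim_matrix.tsv"))
  if (!is.null(sim$truth)) {
    jsonlite::write_json(sim$truth, file.path(out_dir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (is.null(hits_spec)) {
    panel <- data.frame(
      taxon = paste0("tax", 1:6),
      lineage = paste0("k__Fungi;p__Basidiomycota;c__Agaricomycetes;",
                       "o__Polyporales;f__Polyporaceae;g__Genus", 1:6),
      identity_mean = c(99, 96, 92, 87, 82, 75),
      identity_sd = 0,
      stringsAsFactors = FALSE)
    hits_spec <- hit_table_spec(panel, n_samples = 3, seed = spec$seed)
  }
  hits <- gen_hits(hits_spec)
  utils::write.table(hits, file.path(out_dir, "sim_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .provenance(out_dir, "simulate", list(seed = spec$seed,
                                        structure = spec$structure))
  invisible(list(matrix = file.path(out_dir, "sim_matrix.tsv"),
                 hits = file.path(out_dir, "sim_hits.tsv")))
}

#' Run the full pipeline
#'
#' Chains classify, matrix, network, nodes, modules and guilds over a
#' configuration list, writing every report into `out_dir`.
#'
#' @param config list with elements `hits_path`, `out_dir`, optional
#'   `rules` (object or YAML path), `sa` (an [sa_config()]), `db_path`
#'   (guild database TSV) and `seed`.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config) {
  stopifnot(is.list(config), !is.null(config$hits_path), !is.null(config$out_dir))
  out_dir <- .ensure_dir(config$out_dir)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  rules <- if (is.null(config$rules)) default_rank_rules() else config$rules
  sa <- if (is.null(config$sa)) sa_config(seed = seed) else config$sa
  db_path <- if (is.null(config$db_path))
    system.file("extdata", "myrtle_guilds.tsv", package = "endonet") else
      config$db_path

  assignments_path <- run_classify(config$hits_path, out_dir, rules)
  matrix_path <- run_matrix(assignments_path, config$hits_path, out_dir)
  network <- run_network(matrix_path, out_dir)
  nodes <- run_nodes(matrix_path, out_dir)
  modules <- run_modules(matrix_path, out_dir, sa)
  guilds <- run_guilds(assignments_path, out_dir, db_path)
  invisible(list(network = network, nodes = nodes, modules = modules,
                 guilds = guilds))
}
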
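#' @title Host-by-taxon interaction matrices
#' @name interaction-matrix
#' @description
#' The quantitative bipartite network is stored as a plain numeric
#' matrix: rows are host individuals (the lower level), columns are
#' fungal taxa (the higher level), and each cell holds the number of
#' reads of that taxon in that host. Helper functions build the matrix
#' from taxonomic assignments plus per-sample read counts, validate and
#' prune it, binarize it, z-score its positive cells, and serialize it
#' losslessly to TSV, edge-list and GraphML interchange formats.
NULL

#' Build the host-by-taxon interaction matrix
#'
#' Joins per-MOTU taxonomic assignments with per-(sample, MOTU) read
#' counts, sums reads per (sample, taxon) cell, and prunes hosts and
#' taxa with no reads at all. Taxon labels come from
#' [putative_species()] so distinct MOTUs sharing a genus stay separate
#' columns ("Genus sp. 1", "Genus sp. 2"). MOTUs left `"unassigned"`
#' by the coverage gate are dropped with a message.
#'
#' @param assignments output of [classify_hits()].
#' @param hits hit table carrying `query_id`, `sample_id`,
#'   `read_count`.
#' @return Numeric matrix with host row names and taxon column names.
#' @export
build_interaction_matrix <- function(assignments, hits) {
  stopifnot(is.data.frame(assignments), is.data.frame(hits))
  if (any(hits$read_count < 0, na.rm = TRUE)) {
    stop("negative read counts", call. = FALSE)
  }
  keep <- assignments$assigned_rank != "unassigned"
  if (any(!keep)) {
    message(sum(!keep), " unassigned MOTU(s) excluded from the matrix")
  }
  assignments <- assignments[keep, , drop = FALSE]
  labels <- stats::setNames(putative_species(assignments), assignments$motu_id)
  hits <- hits[as.character(hits$query_id) %in% names(labels), , drop = FALSE]
  if (nrow(hits) == 0) stop("no reads left after dropping unassigned MOTUs",
                            call. = FALSE)
  taxon <- unname(labels[as.character(hits$query_id)])
  cell <- paste(hits$sample_id, taxon, sep = "\r")
  if (anyDuplicated(paste(hits$sample_id, hits$query_id, sep = "\r"))) {
    warning("duplicate (sample, MOTU) rows summed", call. = FALSE)
  }
  agg <- tapply(hits$read_count, cell, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  samples <- vapply(parts, `[`, character(1), 1)
  taxa <- vapply(parts, `[`, character(1), 2)
  m <- matrix(0, nrow = length(unique(samples)), ncol = length(unique(taxa)),
              dimnames = list(sort(unique(samples)), sort(unique(taxa))))
  m[cbind(samples, taxa)] <- as.numeric(agg)
  prune_empty(m)
}

#' Drop all-zero rows and columns
#'
#' @param m interaction matrix.
#' @return The pruned matrix; pruning is reported via `message()`.
#' @export
prune_empty <- function(m) {
  m <- .as_count_matrix(m)
  dr <- rowSums(m) == 0
  dc <- colSums(m) == 0
  if (any(dr)) message("pruned ", sum(dr), " empty host row(s)")
  if (any(dc)) message("pruned ", sum(dc), " empty taxon column(s)")
  m[!dr, !dc, drop = FALSE]
}

#' Binarize an interaction matrix
#'
#' @param m interaction matrix.
#' @return 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(m) {
  m <- .as_count_matrix(m)
  (m > 0) * 1
}

#' Z-score the positive cells of a matrix
#'
#' Standardizes the number of interactions per link: over the multiset
#' of positive cells only, `z = (a - mean) / sd` with the population
#' standard deviation. Zero cells are non-links and are returned as
#' `NA` so downstream shading can leave them blank.
#'
#' @param m interaction matrix with at least 2 links.
#' @return Real-valued matrix; non-links are `NA`.
#' @export
zscore_cells <- function(m) {
  m <- .as_count_matrix(m)
  pos <- m[m > 0]
  if (length(pos) < 2) stop("need at least 2 links to z-score", call. = FALSE)
  mu <- mean(pos)
  sd_pop <- sqrt(mean((pos - mu)^2))
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (sd_pop == 0) {
    warning("all links carry the same weight; z-scores set to 0", call. = FALSE)
    z[m > 0] <- 0
  } else {
    z[m > 0] <- (m[m > 0] - mu) / sd_pop
  }
  z
}

#' Read / write an interaction matrix as TSV
#'
#' The format is a header row of taxon labels and a first column of
#' host labels; cells are counts. The round trip is lossless for
#' integer matrices. Ragged rows or non-numeric cells raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @return `read_matrix_tsv()` returns the matrix; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file needs a header and at least one row",
                              call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  taxa <- header[-1]
  width <- length(header)
  body <- fields[-1]
  hosts <- character(length(body))
  m <- matrix(0, length(body), length(taxa))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != width) {
      stop("line ", i + 1, ": expected ", width, " fields, found ", length(row),
           call. = FALSE)
    }
    hosts[i] <- row[1]
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) stop("line ", i + 1, ": non-numeric cell", call. = FALSE)
    m[i, ] <- vals
  }
  dimnames(m) <- list(hosts, taxa)
  .as_count_matrix(m)
}

#' @rdname read_matrix_tsv
#' @param m interaction matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- .as_count_matrix(m)
  header <- paste(c("", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Convert a matrix to a (host, taxon, weight) edge list
#'
#' Zeros are omitted; the edge list has one row per link.
#'
#' @param m interaction matrix.
#' @return Data frame with columns `host`, `taxon`, `weight`.
#' @export
to_edge_list <- function(m) {
  m <- .as_count_matrix(m)
  idx <- which(m > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(host = rownames(m)[idx[, 1]],
             taxon = colnames(m)[idx[, 2]],
             weight = m[idx],
             stringsAsFactors = FALSE)
}

#' Convert a matrix to a bipartite igraph graph
#'
#' Nodes carry a logical `type` attribute (`FALSE` = host/lower level,
#' `TRUE` = taxon/higher level) and a `level` attribute (`"LL"`/`"HL"`);
#' edges carry the interaction count as `weight`.
#'
#' @param m interaction matrix.
#' @return An undirected weighted `igraph` object with `I + J` nodes
#'   and `L` edges.
#' @export
as_bipartite_igraph <- function(m) {
  m <- .as_count_matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("H", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  el <- to_edge_list(m)
  g <- igraph::graph_from_data_frame(
    el[, c("host", "taxon")], directed = FALSE,
    vertices = data.frame(name = c(rownames(m), colnames(m)),
                          type = rep(c(FALSE, TRUE), c(nrow(m), ncol(m))),
                          level = rep(c("LL", "HL"), c(nrow(m), ncol(m)))))
  igraph::E(g)$weight <- el$weight
  g
}

#' Export a matrix as GraphML
#'
#' @param m interaction matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(m, path) {
  igraph::write_graph(as_bipartite_igraph(m), path, format = "graphml")
  invisible(path)
}
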
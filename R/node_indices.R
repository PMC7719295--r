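#' @title Node-level indices of bipartite networks
#' @name node-indices
#' @description
#' Per-node descriptors for both levels of the bipartite network:
#' degree, normalized degree, species strength (summed partner
#' dependence), weighted betweenness (exact shortest-path betweenness
#' on the bipartite graph with inverse-weight edge lengths, normalized
#' to each level's total), effective partners (exp of the Shannon
#' entropy of the node's interaction distribution) and proportional
#' generality (effective partners scaled by the effective number of
#' available partners on the other level).
NULL

.level_vectors <- function(m, level) {
  # node interaction vectors as columns of the returned matrix
  if (level == "HL") m else t(m)
}

#' Node degrees and normalized degrees
#'
#' Degree is the number of partners; normalized degree divides by the
#' node count of the opposite level.
#'
#' @param m interaction matrix (hosts x taxa).
#' @param level `"HL"` (taxa) or `"LL"` (hosts).
#' @return Named numeric vector.
#' @export
node_degree <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  x <- .level_vectors(.as_count_matrix(m), level)
  colSums(x > 0)
}

#' @rdname node_degree
#' @export
normalized_degree <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  x <- .level_vectors(.as_count_matrix(m), level)
  colSums(x > 0) / nrow(x)
}

#' Species strength
#'
#' Sum over a node's partners of the partner's proportional dependence
#' on it: for taxon `j`, `sum_i a_ij / r_i`; for host `i`,
#' `sum_j a_ij / c_j`. Within a level, strengths sum exactly to the
#' size of the opposite level.
#'
#' @inheritParams node_degree
#' @return Named numeric vector.
#' @export
species_strength <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  m <- .as_count_matrix(m)
  .require_links(m)
  x <- .level_vectors(m, level)
  partner_tot <- rowSums(x)
  if (any(partner_tot == 0)) stop("prune empty nodes before species strength",
                                  call. = FALSE)
  colSums(x / partner_tot)
}

#' Effective partners
#'
#' Exponential of the Shannon entropy (natural log) of the node's
#' interaction proportions: 1 for a degree-1 node, equal to the degree
#' under uniform weights.
#'
#' @inheritParams node_degree
#' @return Named numeric vector, `1 <= value <= degree`.
#' @export
effective_partners <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  x <- .level_vectors(.as_count_matrix(m), level)
  apply(x, 2, .effective_number)
}

#' Proportional generality
#'
#' Effective partners divided by the effective number of available
#' partners on the opposite level, i.e. `exp` of the entropy of the
#' opposite level's weighted marginal distribution. All degree-1 nodes
#' of a level share the same value, `1 / exp(H(marginals))`.
#'
#' @inheritParams node_degree
#' @return Named numeric vector, positive.
#' @export
proportional_generality <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  m <- .as_count_matrix(m)
  .require_links(m)
  x <- .level_vectors(m, level)
  available <- .effective_number(rowSums(x))   # opposite level's marginals
  effective_partners(m, level) / available
}

#' Weighted betweenness
#'
#' Exact shortest-path betweenness on the bipartite graph with edge
#' length `1 / a_ij` (stronger links are shorter), fractional credit
#' over equal-length paths, endpoints excluded. Within each level the
#' scores are divided by the level's total, so they sum to 1 whenever
#' any node of the level lies on a shortest path (and are all 0
#' otherwise). Invariant under uniform rescaling of all weights.
#'
#' @inheritParams node_degree
#' @return Named numeric vector summing to 0 or 1.
#' @export
weighted_betweenness <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  m <- .as_count_matrix(m)
  .require_links(m)
  g <- as_bipartite_igraph(m)
  bw <- igraph::betweenness(g, directed = FALSE,
                            weights = 1 / igraph::E(g)$weight)
  keep <- igraph::V(g)$level == level
  scores <- bw[keep]
  names(scores) <- igraph::V(g)$name[keep]
  tot <- sum(scores)
  if (tot > 0) scores / tot else scores * 0
}

#' Node-level report
#'
#' One row per node with the standard column battery: `Degree`,
#' `Normalizeddegree`, `Speciesstrength`, `Weightedbetweenness`,
#' `Effectivepartners`, `Proportionalgenerality`.
#'
#' @inheritParams node_degree
#' @param level `"HL"`, `"LL"` or `"both"` (adds a `level` column).
#' @return Data frame with one row per node.
#' @export
node_report <- function(m, level = c("both", "HL", "LL")) {
  level <- match.arg(level)
  if (level == "both") {
    out <- rbind(node_report(m, "LL"), node_report(m, "HL"))
    rownames(out) <- NULL
    return(out)
  }
  m <- .as_count_matrix(m)
  x <- .level_vectors(m, level)
  nodes <- colnames(x)
  if (is.null(nodes)) nodes <- paste0(if (level == "HL") "T" else "H",
                                      seq_len(ncol(x)))
  data.frame(
    node = nodes,
    level = level,
    Degree = unname(node_degree(m, level)),
    Normalizeddegree = unname(normalized_degree(m, level)),
    Speciesstrength = unname(species_strength(m, level)),
    Weightedbetweenness = unname(weighted_betweenness(m, level)),
    Effectivepartners = unname(effective_partners(m, level)),
    Proportionalgenerality = unname(proportional_generality(m, level)),
    stringsAsFactors = FALSE
  )
}

#' Write node reports to TSV
#'
#' @param report output of [node_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
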
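#' @title Network-level indices of bipartite networks
#' @name network-indices
#' @description
#' First-principles implementations of the standard network-level
#' descriptors of quantitative bipartite ecological networks:
#' connectance, web asymmetry, links per taxon, NODF and weighted NODF
#' nestedness, Bersier's quantitative linkage density and weighted
#' connectance, the H2' specialization index, the checkerboard C-score,
#' Horn's niche overlap, and the mean number of shared partners. All
#' entropies use natural logarithms; effective numbers
#' (`exp(H)`) are base-invariant. Rows are hosts (lower level, LL),
#' columns are taxa (higher level, HL).
NULL

#' Connectance
#'
#' Realized links over possible links, `L / (I * J)`.
#'
#' @param m interaction matrix (hosts x taxa).
#' @return Scalar in (0, 1\].
#' @export
connectance <- function(m) {
  m <- .as_count_matrix(m)
  if (nrow(m) < 1 || ncol(m) < 1) stop("empty matrix", call. = FALSE)
  sum(m > 0) / (nrow(m) * ncol(m))
}

#' Web asymmetry
#'
#' Balance of the two levels, `(J - I) / (J + I)`: positive when taxa
#' (columns) outnumber hosts (rows).
#'
#' @inheritParams connectance
#' @return Scalar in (-1, 1).
#' @export
web_asymmetry <- function(m) {
  m <- .as_count_matrix(m)
  (ncol(m) - nrow(m)) / (ncol(m) + nrow(m))
}

#' Links per taxon
#'
#' `L / (I + J)`, the mean number of links per node.
#'
#' @inheritParams connectance
#' @return Non-negative scalar.
#' @export
links_per_taxa <- function(m) {
  m <- .as_count_matrix(m)
  sum(m > 0) / (nrow(m) + ncol(m))
}

#' Quantitative linkage density and weighted connectance
#'
#' Bersier's quantitative linkage density: with `n_x` the effective
#' number of partners of node `x` (exp of the Shannon entropy of its
#' interaction proportions) and marginal weights `r_i`, `c_j` out of
#' the grand total `m`,
#' `LD = 1/2 * (sum_j (c_j/m) n_j + sum_i (r_i/m) n_i)`.
#' Weighted connectance is `LD / (I + J)`, so
#' `weighted_connectance(m) * (I + J) == linkage_density(m)` always.
#'
#' @inheritParams connectance
#' @return Scalar; `linkage_density` >= 1 for any non-empty network.
#' @export
linkage_density <- function(m) {
  m <- .as_count_matrix(m)
  .require_links(m)
  tot <- sum(m)
  n_col <- apply(m, 2, .effective_number)
  n_row <- apply(m, 1, .effective_number)
  0.5 * (sum(colSums(m) / tot * n_col) + sum(rowSums(m) / tot * n_row))
}

#' @rdname linkage_density
#' @export
weighted_connectance <- function(m) {
  linkage_density(m) / (nrow(m) + ncol(m))
}

#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill. For every
#' ordered pair of columns `(u, v)` with fills `f_u > f_v` the pair
#' contributes `100 * |shared rows| / f_v`; pairs of equal fill
#' contribute 0; row pairs are scored symmetrically. NODF is the sum of
#' contributions over `I(I-1)/2 + J(J-1)/2` pairs.
#'
#' @param m matrix; any positive entry counts as a link.
#' @return Scalar in \[0, 100\].
#' @export
nodf <- function(m) {
  b <- binarize(m)
  pairs_axis <- function(x) {
    # x: links in columns of the slice under consideration
    f <- colSums(x)
    n <- ncol(x)
    if (n < 2) return(c(0, 0))
    shared <- crossprod(x)                     # shared rows per column pair
    fu <- matrix(f, n, n)                      # column fills, recycled
    fv <- t(fu)
    contrib <- 100 * shared / fv
    contrib[fu <= fv] <- 0                     # needs strictly decreasing fill
    contrib[fv == 0] <- 0                      # empty partner: no overlap
    c(sum(contrib) , n * (n - 1) / 2)          # diagonal already zeroed
  }
  col_part <- pairs_axis(b)
  row_part <- pairs_axis(t(b))
  denom <- col_part[2] + row_part[2]
  if (denom == 0) {
    warning("NODF undefined for a single node per level", call. = FALSE)
    return(NA_real_)
  }
  (col_part[1] + row_part[1]) / denom
}

#' Weighted NODF nestedness
#'
#' Quantitative analogue of NODF. For an ordered column pair `(u, v)`
#' with marginal totals `F_u > F_v`, the contribution is
#' `100 * |{rows r: 0 < a[r, v] < a[r, u]}| / |{rows r: a[r, v] > 0}|`;
#' equal totals contribute 0; row pairs symmetrically; averaged over
#' the same pair count as NODF.
#'
#' @inheritParams connectance
#' @return Scalar in \[0, 100\].
#' @export
wnodf <- function(m) {
  m <- .as_count_matrix(m)
  pairs_axis <- function(x) {
    f <- colSums(x)
    n <- ncol(x)
    if (n < 2) return(c(0, 0))
    total <- 0
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        hi <- if (f[u] > f[v]) u else if (f[v] > f[u]) v else next
        lo <- if (hi == u) v else u
        filled <- sum(x[, lo] > 0)
        if (filled == 0) next
        total <- total + 100 * sum(x[, lo] > 0 & x[, lo] < x[, hi]) / filled
      }
    }
    c(total, n * (n - 1) / 2)
  }
  col_part <- pairs_axis(m)
  row_part <- pairs_axis(t(m))
  denom <- col_part[2] + row_part[2]
  if (denom == 0) {
    warning("weighted NODF undefined for a single node per level", call. = FALSE)
    return(NA_real_)
  }
  (col_part[1] + row_part[1]) / denom
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction
#' matrix. With cell proportions `p_ij = a_ij / m`,
#' `H2 = -sum p_ij log p_ij`; `H2max` is the entropy of the
#' independence surface `q_ij = r_i c_j / m^2`; `H2min` is the entropy
#' of a maximally packed allocation that preserves both marginals,
#' found by repeatedly placing `min(remaining r_i, remaining c_j)` into
#' the cell with the largest remaining row-by-column product (first
#' index wins ties). `H2' = (H2max - H2) / (H2max - H2min)`, clipped to
#' \[0, 1\]: 0 means interactions follow the marginal expectation, 1
#' means maximal specialization.
#'
#' @inheritParams connectance
#' @return Scalar in \[0, 1\].
#' @export
h2prime <- function(m) {
  m <- .as_count_matrix(m)
  .require_links(m)
  if (nrow(m) == 1 && ncol(m) == 1) {
    warning("H2' undefined for a 1x1 matrix; returning 0", call. = FALSE)
    return(0)
  }
  tot <- sum(m)
  h2 <- .entropy(m)
  r <- rowSums(m)
  cc <- colSums(m)
  h2max <- .entropy(outer(r, cc))
  h2min <- .entropy(pack_marginals(r, cc))
  if (h2max - h2min < sqrt(.Machine$double.eps)) {
    warning("degenerate marginals: H2max == H2min; returning 0", call. = FALSE)
    return(0)
  }
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

#' Greedy marginal-packing allocation
#'
#' Deterministic allocation of the grand total into cells so that both
#' marginals are preserved and the entropy is (heuristically) minimal:
#' repeatedly place `min(remaining row total, remaining column total)`
#' into the cell whose remaining row-by-column product is largest,
#' breaking ties by the smallest cell index. Used for the `H2min`
#' reference point of [h2prime()].
#'
#' @param r,cc row and column marginal totals (equal sums).
#' @return Matrix of allocations with `rowSums == r`, `colSums == cc`.
#' @export
pack_marginals <- function(r, cc) {
  stopifnot(abs(sum(r) - sum(cc)) < 1e-9)
  out <- matrix(0, length(r), length(cc))
  r_rem <- r
  c_rem <- cc
  while (sum(r_rem) > 1e-12) {
    prod <- outer(r_rem, c_rem)
    k <- which.max(prod)               # column-major: first index wins ties
    i <- (k - 1) %% length(r) + 1
    j <- (k - 1) %/% length(r) + 1
    v <- min(r_rem[i], c_rem[j])
    out[i, j] <- out[i, j] + v
    r_rem[i] <- r_rem[i] - v
    c_rem[j] <- c_rem[j] - v
  }
  out
}

#' Checkerboard C-score
#'
#' Mean checkerboard unit over all unordered pairs of same-level nodes:
#' for nodes with degrees `r_u`, `r_v` sharing `S` partners,
#' `CU = (r_u - S)(r_v - S) / (r_u r_v)`, bounded in \[0, 1\]. High
#' values mean mutual exclusion across partners.
#'
#' @inheritParams connectance
#' @param level `"HL"` (taxa, columns) or `"LL"` (hosts, rows).
#' @return Scalar in \[0, 1\].
#' @export
c_score <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  b <- binarize(m)
  x <- if (level == "HL") b else t(b)
  n <- ncol(x)
  if (n < 2) stop("C-score needs at least two nodes in the level", call. = FALSE)
  deg <- colSums(x)
  if (any(deg == 0)) stop("prune zero-degree nodes before computing C-score",
                          call. = FALSE)
  shared <- crossprod(x)
  cu <- (matrix(deg, n, n) - shared) * (t(matrix(deg, n, n)) - shared) /
    outer(deg, deg)
  mean(cu[upper.tri(cu)])
}

#' Horn's niche overlap
#'
#' Mean of Horn's information-theoretic overlap index over all
#' unordered pairs of same-level nodes. For weight vectors `x`, `y`
#' with totals `X`, `Y`:
#' `R_o = (sum (x+y) log(x+y) - sum x log x - sum y log y) /
#'        ((X+Y) log(X+Y) - X log X - Y log Y)`, with `0 log 0 == 0`.
#' Proportional vectors give 1; disjoint supports give 0.
#'
#' @inheritParams c_score
#' @return Scalar in \[0, 1\].
#' @export
niche_overlap <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  m <- .as_count_matrix(m)
  x <- if (level == "HL") m else t(m)
  n <- ncol(x)
  if (n < 2) stop("niche overlap needs at least two nodes in the level",
                  call. = FALSE)
  xlogx <- function(v) sum(v[v > 0] * log(v[v > 0]))
  vals <- numeric(0)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      a <- x[, u]; b <- x[, v]
      A <- sum(a); B <- sum(b)
      denom <- xlogx(A + B) - xlogx(A) - xlogx(B)
      if (denom <= 0) next                    # degenerate pair (a zero vector)
      vals <- c(vals, (xlogx(a + b) - xlogx(a) - xlogx(b)) / denom)
    }
  }
  mean(vals)
}

#' Mean number of shared partners
#'
#' Mean over unordered same-level pairs of the number of partners the
#' two nodes share.
#'
#' @inheritParams c_score
#' @return Non-negative scalar.
#' @export
mean_shared_partners <- function(m, level = c("HL", "LL")) {
  level <- match.arg(level)
  b <- binarize(m)
  x <- if (level == "HL") b else t(b)
  if (ncol(x) < 2) stop("needs at least two nodes in the level", call. = FALSE)
  shared <- crossprod(x)
  mean(shared[upper.tri(shared)])
}

#' Network-level report
#'
#' Computes the full battery of network-level indices and returns them
#' under their conventional report names, in report order:
#' `Connectance`, `Web asymmetry`, `Links per taxa`, `NODF`,
#' `Weighted NODF`, `Linkage density`, `Weighted connectance`, `H2`,
#' `Number.of.taxa.HL`, `Number.of.taxa.LL`,
#' `Mean.number.of.shared.partners.HL/.LL`, `Niche.overlap.HL/.LL`,
#' `C.score.HL/.LL`.
#'
#' @inheritParams connectance
#' @return A `network_report` object: named list of index values with
#'   a `meta` attribute recording `I`, `J`, `L` and `m`.
#' @export
network_report <- function(m) {
  m <- .as_count_matrix(m)
  .require_links(m)
  values <- list(
    "Connectance" = connectance(m),
    "Web asymmetry" = web_asymmetry(m),
    "Links per taxa" = links_per_taxa(m),
    "NODF" = nodf(m),
    "Weighted NODF" = wnodf(m),
    "Linkage density" = linkage_density(m),
    "Weighted connectance" = weighted_connectance(m),
    "H2" = h2prime(m),
    "Number.of.taxa.HL" = ncol(m),
    "Number.of.taxa.LL" = nrow(m),
    "Mean.number.of.shared.partners.HL" = mean_shared_partners(m, "HL"),
    "Mean.number.of.shared.partners.LL" = mean_shared_partners(m, "LL"),
    "Niche.overlap.HL" = niche_overlap(m, "HL"),
    "Niche.overlap.LL" = niche_overlap(m, "LL"),
    "C.score.HL" = c_score(m, "HL"),
    "C.score.LL" = c_score(m, "LL")
  )
  structure(values,
            meta = list(I = nrow(m), J = ncol(m), L = sum(m > 0), m = sum(m)),
            class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  df <- data.frame(Index = names(x),
                   Value = vapply(x, function(v) format(v, digits = 8),
                                  character(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a network report as TSV and JSON
#'
#' @param report a `network_report`.
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_network_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    df <- data.frame(Index = names(report), Value = unlist(report))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(c(unclass(report), list(meta = attr(report, "meta"))),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
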
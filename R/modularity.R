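#' @title Barber bipartite modularity and simulated annealing
#' @name modularity
#' @description
#' Barber's bipartite modularity compares the interaction weight inside
#' modules with its degree-based expectation:
#' `Q = (1/m) * sum_ij (B_ij - k_i d_j / m) * delta(g_i, g_j)`, where
#' `B` is the (binary by default, optionally weighted) interaction
#' matrix, `k_i`/`d_j` its row/column marginals, `m` its total, and
#' `g` the module assignment of every node of both levels. `Q` is
#' maximized by simulated annealing over partitions, with single-node
#' reassignment, module-merge and module-split moves, geometric
#' cooling, and seeded pseudo-randomness so runs are reproducible.
NULL

#' Simulated-annealing configuration
#'
#' @param t0 initial temperature (default 1).
#' @param cooling geometric cooling factor in (0, 1) (default 0.95).
#' @param steps_per_temp proposals per temperature; default
#'   `100 * (I + J)`, set at run time when `NULL`.
#' @param t_min stop once the temperature falls below this (default
#'   1e-4).
#' @param seed integer seed driving every random choice.
#' @param move_weights probabilities of the three move kinds
#'   (single-node reassignment, module merge, module split).
#' @param weighted use the weighted matrix for `Q` instead of the
#'   binary default.
#' @return An `sa_config` list.
#' @export
sa_config <- function(t0 = 1, cooling = 0.95, steps_per_temp = NULL,
                      t_min = 1e-4, seed = 1,
                      move_weights = c(single = 0.8, merge = 0.1, split = 0.1),
                      weighted = FALSE) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, t_min > 0,
            length(move_weights) == 3, all(move_weights >= 0),
            sum(move_weights) > 0)
  structure(list(t0 = t0, cooling = cooling, steps_per_temp = steps_per_temp,
                 t_min = t_min, seed = as.integer(seed),
                 move_weights = move_weights / sum(move_weights),
                 weighted = weighted),
            class = "sa_config")
}

#' Barber bipartite modularity Q
#'
#' @param m interaction matrix (hosts x taxa).
#' @param partition a list with integer vectors `rows` and `cols`
#'   assigning every host and taxon to a module.
#' @param weighted score the weighted matrix (default binary
#'   presence/absence).
#' @return Scalar `Q <= 1`; 0 for the one-module partition.
#' @export
barber_q <- function(m, partition, weighted = FALSE) {
  m <- .as_count_matrix(m)
  b <- if (weighted) m else binarize(m)
  .require_links(b)
  g_rows <- as.integer(partition$rows)
  g_cols <- as.integer(partition$cols)
  stopifnot(length(g_rows) == nrow(b), length(g_cols) == ncol(b),
            !anyNA(g_rows), !anyNA(g_cols))
  tot <- sum(b)
  s <- b - outer(rowSums(b), colSums(b)) / tot
  sum(s[outer(g_rows, g_cols, "==")]) / tot
}

# internal SA state: s = B - k d'/m, row_mod/col_mod assignments,
# rm[i, mod] = sum of s[i, j] over cols j in mod,
# cm[j, mod] = sum of s[i, j] over rows i in mod
.sa_state <- function(s, row_mod, col_mod, n_mod_max) {
  rm_ <- matrix(0, nrow(s), n_mod_max)
  cm_ <- matrix(0, ncol(s), n_mod_max)
  for (mod in unique(col_mod)) rm_[, mod] <- rowSums(s[, col_mod == mod, drop = FALSE])
  for (mod in unique(row_mod)) cm_[, mod] <- colSums(s[row_mod == mod, , drop = FALSE])
  list(rm = rm_, cm = cm_, row_mod = row_mod, col_mod = col_mod)
}

.sa_q <- function(st, s, tot) {
  q <- 0
  for (i in seq_along(st$row_mod)) q <- q + st$rm[i, st$row_mod[i]]
  q / tot
}

#' Maximize Barber modularity by simulated annealing
#'
#' Starts from the all-singletons partition, proposes single-node
#' reassignments (including to an empty module), module merges and
#' module splits, accepts improvements always and deteriorations with
#' probability `exp(dQ / T)`, cools geometrically (`T <- cooling * T`)
#' and returns the best partition seen. Deterministic for a given
#' seed.
#'
#' @param m interaction matrix.
#' @param config an [sa_config()].
#' @return An `sa_partition` list: `partition` (module ids, contiguous
#'   from 1, for `rows` and `cols`), `q`, `n_modules`, `trajectory`
#'   (best Q after each temperature) and the `config` echo.
#' @export
optimize_modularity <- function(m, config = sa_config()) {
  m <- .as_count_matrix(m)
  b <- if (config$weighted) m else binarize(m)
  .require_links(b)
  I <- nrow(b); J <- ncol(b); n <- I + J
  steps <- if (is.null(config$steps_per_temp)) 100L * n else config$steps_per_temp
  tot <- sum(b)
  s <- b - outer(rowSums(b), colSums(b)) / tot

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  # singleton start: every node its own module
  row_mod <- seq_len(I)
  col_mod <- I + seq_len(J)
  st <- .sa_state(s, row_mod, col_mod, n)
  q <- .sa_q(st, s, tot)
  best <- list(row_mod = row_mod, col_mod = col_mod, q = q)
  trajectory <- numeric(0)
  temp <- config$t0
  kinds <- c("single", "merge", "split")

  move_single <- function() {
    k <- sample.int(n, 1)
    is_row <- k <= I
    idx <- if (is_row) k else k - I
    cur <- if (is_row) st$row_mod[idx] else st$col_mod[idx]
    occupied <- unique(c(st$row_mod, st$col_mod))
    empty <- setdiff(seq_len(n), occupied)
    targets <- setdiff(occupied, cur)
    if (length(empty)) targets <- c(targets, empty[1])
    if (!length(targets)) return(0)
    new <- targets[sample.int(length(targets), 1)]
    gain <- if (is_row) (st$rm[idx, new] - st$rm[idx, cur]) / tot
            else (st$cm[idx, new] - st$cm[idx, cur]) / tot
    if (gain >= 0 || stats::runif(1) < exp(gain / temp)) {
      if (is_row) {
        st$row_mod[idx] <<- new
        st$cm[, cur] <<- st$cm[, cur] - s[idx, ]
        st$cm[, new] <<- st$cm[, new] + s[idx, ]
      } else {
        st$col_mod[idx] <<- new
        st$rm[, cur] <<- st$rm[, cur] - s[, idx]
        st$rm[, new] <<- st$rm[, new] + s[, idx]
      }
      return(gain)
    }
    0
  }

  move_merge <- function() {
    mods <- unique(c(st$row_mod, st$col_mod))
    if (length(mods) < 2) return(0)
    ab <- sample(mods, 2)
    a <- ab[1]; b2 <- ab[2]
    ra <- which(st$row_mod == a); rb <- which(st$row_mod == b2)
    gain <- (sum(st$rm[ra, b2]) + sum(st$rm[rb, a])) / tot
    if (gain >= 0 || stats::runif(1) < exp(gain / temp)) {
      st$row_mod[rb] <<- a
      ca <- which(st$col_mod == a); cb <- which(st$col_mod == b2)
      st$col_mod[cb] <<- a
      st$rm[, a] <<- st$rm[, a] + st$rm[, b2]; st$rm[, b2] <<- 0
      st$cm[, a] <<- st$cm[, a] + st$cm[, b2]; st$cm[, b2] <<- 0
      return(gain)
    }
    0
  }

  move_split <- function() {
    mods <- unique(c(st$row_mod, st$col_mod))
    sizes <- vapply(mods, function(mod)
      sum(st$row_mod == mod) + sum(st$col_mod == mod), integer(1))
    cand <- mods[sizes >= 2]
    if (!length(cand)) return(0)
    a <- cand[sample.int(length(cand), 1)]
    empty <- setdiff(seq_len(n), mods)
    if (!length(empty)) return(0)
    b2 <- empty[1]
    ra <- which(st$row_mod == a); ca <- which(st$col_mod == a)
    members <- c(ra, I + ca)
    go <- stats::runif(length(members)) < 0.5
    mv <- members[go]
    if (!length(mv) || length(mv) == length(members)) return(0)
    mv_rows <- mv[mv <= I]
    mv_cols <- mv[mv > I] - I
    keep_rows <- setdiff(ra, mv_rows)
    keep_cols <- setdiff(ca, mv_cols)
    # losing the cross terms between the two halves
    gain <- -(sum(s[keep_rows, mv_cols]) + sum(s[mv_rows, keep_cols])) / tot
    if (gain >= 0 || stats::runif(1) < exp(gain / temp)) {
      st$row_mod[mv_rows] <<- b2
      st$col_mod[mv_cols] <<- b2
      if (length(mv_cols)) {
        delta <- rowSums(s[, mv_cols, drop = FALSE])
        st$rm[, a] <<- st$rm[, a] - delta
        st$rm[, b2] <<- st$rm[, b2] + delta
      }
      if (length(mv_rows)) {
        delta <- colSums(s[mv_rows, , drop = FALSE])
        st$cm[, a] <<- st$cm[, a] - delta
        st$cm[, b2] <<- st$cm[, b2] + delta
      }
      return(gain)
    }
    0
  }

  while (temp >= config$t_min) {
    for (step in seq_len(steps)) {
      kind <- sample(kinds, 1, prob = config$move_weights)
      q <- q + switch(kind,
                      single = move_single(),
                      merge = move_merge(),
                      split = move_split())
      if (q > best$q + 1e-12) {
        best <- list(row_mod = st$row_mod, col_mod = st$col_mod, q = q)
      }
    }
    trajectory <- c(trajectory, best$q)
    temp <- temp * config$cooling
  }

  # contiguous module ids from 1, in order of first appearance
  ids <- unique(c(best$row_mod, best$col_mod))
  relabel <- match(c(best$row_mod, best$col_mod), ids)
  rows <- relabel[seq_len(I)]
  cols <- relabel[I + seq_len(J)]
  names(rows) <- rownames(b)
  names(cols) <- colnames(b)
  structure(list(partition = list(rows = rows, cols = cols),
                 q = barber_q(m, list(rows = rows, cols = cols),
                              weighted = config$weighted),
                 n_modules = length(ids),
                 trajectory = trajectory,
                 config = config),
            class = "sa_partition")
}

#' @export
print.sa_partition <- function(x, ...) {
  cat("Barber modularity partition: Q =", format(x$q, digits = 7),
      "with", x$n_modules, "modules\n")
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Convenience wrapper around `igraph::compare(..., method = "nmi")`
#' for checking recovery of planted module structure.
#'
#' @param a,b integer membership vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  igraph::compare(as.integer(a), as.integer(b), method = "nmi")
}

#' Write a module partition as TSV + JSON report
#'
#' @param fit an `sa_partition`.
#' @param path_tsv partition table (node, level, module).
#' @param path_json JSON report with `q`, module count, and the config
#'   echo (including the seed).
#' @return Invisibly, `fit`.
#' @export
write_partition <- function(fit, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    df <- data.frame(
      node = c(names(fit$partition$rows), names(fit$partition$cols)),
      level = rep(c("LL", "HL"),
                  c(length(fit$partition$rows), length(fit$partition$cols))),
      module = c(unname(fit$partition$rows), unname(fit$partition$cols)))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(q = fit$q, n_modules = fit$n_modules,
                              config = unclass(fit$config)),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
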
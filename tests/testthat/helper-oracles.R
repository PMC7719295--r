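# Independent brute-force oracles: literal nested-loop transcriptions of the
# index definitions, kept free of the vectorized implementation code paths.

oracle_nodf <- function(b) {
  b <- (b > 0) * 1
  I <- nrow(b); J <- ncol(b)
  tot <- 0
  for (u in seq_len(J)) for (v in seq_len(J)) {
    if (u == v) next
    fu <- sum(b[, u]); fv <- sum(b[, v])
    if (fu > fv && fv > 0) tot <- tot + 100 * sum(b[, u] > 0 & b[, v] > 0) / fv
  }
  for (u in seq_len(I)) for (v in seq_len(I)) {
    if (u == v) next
    fu <- sum(b[u, ]); fv <- sum(b[v, ])
    if (fu > fv && fv > 0) tot <- tot + 100 * sum(b[u, ] > 0 & b[v, ] > 0) / fv
  }
  tot / (I * (I - 1) / 2 + J * (J - 1) / 2)
}

oracle_wnodf <- function(m) {
  I <- nrow(m); J <- ncol(m)
  tot <- 0
  for (u in seq_len(J)) for (v in seq_len(J)) {
    if (u == v) next
    if (sum(m[, u]) > sum(m[, v]) && sum(m[, v] > 0) > 0) {
      tot <- tot + 100 * sum(m[, v] > 0 & m[, v] < m[, u]) / sum(m[, v] > 0)
    }
  }
  for (u in seq_len(I)) for (v in seq_len(I)) {
    if (u == v) next
    if (sum(m[u, ]) > sum(m[v, ]) && sum(m[v, ] > 0) > 0) {
      tot <- tot + 100 * sum(m[v, ] > 0 & m[v, ] < m[u, ]) / sum(m[v, ] > 0)
    }
  }
  tot / (I * (I - 1) / 2 + J * (J - 1) / 2)
}

# level = "HL": pairs of columns; "LL": pairs of rows
oracle_cscore <- function(m, level) {
  b <- (m > 0) * 1
  x <- if (level == "HL") b else t(b)
  n <- ncol(x)
  vals <- c()
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    ru <- sum(x[, u]); rv <- sum(x[, v])
    s <- sum(x[, u] > 0 & x[, v] > 0)
    vals <- c(vals, (ru - s) * (rv - s) / (ru * rv))
  }
  mean(vals)
}

oracle_shared <- function(m, level) {
  b <- (m > 0) * 1
  x <- if (level == "HL") b else t(b)
  n <- ncol(x)
  vals <- c()
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    vals <- c(vals, sum(x[, u] > 0 & x[, v] > 0))
  }
  mean(vals)
}

oracle_barber_q <- function(m, g_rows, g_cols, weighted = FALSE) {
  b <- if (weighted) m else (m > 0) * 1
  tot <- sum(b)
  k <- rowSums(b); d <- colSums(b)
  q <- 0
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b))) {
    if (g_rows[i] == g_cols[j]) q <- q + b[i, j] - k[i] * d[j] / tot
  }
  q / tot
}

oracle_horn <- function(x, y) {
  f <- function(v) sum(ifelse(v > 0, v * log(v), 0))
  X <- sum(x); Y <- sum(y)
  (f(x + y) - f(x) - f(y)) / (f(X + Y) - f(X) - f(Y))
}

# exhaustive minimum Shannon entropy over all non-negative integer matrices
# with the given marginals (tiny totals only)
oracle_h2min <- function(r, cc) {
  best <- Inf
  fill <- function(cells, r_rem, c_rem) {
    if (length(r_rem) == 1) {
      if (all(c_rem >= 0)) {
        final <- c(cells, c_rem)
        p <- final[final > 0] / sum(final)
        best <<- min(best, -sum(p * log(p)))
      }
      return(invisible())
    }
    ncols <- length(c_rem)
    row_fills <- function(row, j, left) {
      if (j == ncols) {
        if (left <= c_rem[ncols]) {
          row[ncols] <- left
          fill(c(cells, row), r_rem[-1], c_rem - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, c_rem[j])) {
        row[j] <- v
        row_fills(row, j + 1, left - v)
      }
    }
    row_fills(numeric(ncols), 1, r_rem[1])
  }
  fill(numeric(0), r, cc)
  best
}

# enumerate all partitions of n items as restricted growth strings
all_partitions <- function(n, max_blocks = n) {
  out <- list()
  rec <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (g in seq_len(min(m + 1, max_blocks))) rec(c(prefix, g), max(m, g))
  }
  rec(integer(0), 0L)
  out
}

# all I x J binary matrices as a list, from bit patterns
enum_binary <- function(I, J) {
  lapply(0:(2^(I * J) - 1), function(code) {
    matrix(as.integer(intToBits(code)[seq_len(I * J)]), I, J)
  })
}

random_count_matrix <- function(I, J, max_count = 9, p_zero = 0.4) {
  m <- matrix(sample(0:max_count, I * J, replace = TRUE,
                     prob = c(p_zero, rep((1 - p_zero) / max_count, max_count))),
              I, J)
  m
}
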
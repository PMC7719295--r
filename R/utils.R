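# internal helpers shared across modules

# Shannon entropy of a non-negative weight vector (normalized internally),
# natural log, 0*log(0) == 0
.entropy <- function(x) {
  s <- sum(x)
  if (s <= 0) return(0)
  p <- x[x > 0] / s
  -sum(p * log(p))
}

# effective number of categories (exp of Shannon entropy); base-invariant
.effective_number <- function(x) exp(.entropy(x))

.as_count_matrix <- function(m, arg = "m") {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`", arg, "` must be a numeric matrix (hosts in rows, taxa in columns)",
         call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("interaction matrix contains missing or non-finite cells", call. = FALSE)
  }
  if (any(m < 0)) stop("interaction counts must be non-negative", call. = FALSE)
  m
}

.require_links <- function(m) {
  if (sum(m) <= 0) stop("interaction matrix has no interactions (m = 0)", call. = FALSE)
  invisible(m)
}
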
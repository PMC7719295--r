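#' @title Synthetic host-endophyte communities
#' @name synthetic-data
#' @description
#' Generators that emulate the outputs of an ITS metabarcoding
#' pipeline after clustering: host-by-taxon read-count matrices with
#' planted modular, nested or random link structure and log-normal
#' link weights, and per-MOTU hit tables with controlled identity
#' distributions. Everything is reproducible from a seed, so every
#' analysis stage can be exercised without sequencing data.
NULL

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic community
#'
#' @param I,J host and taxon counts (each >= 2).
#' @param structure `"modular"` (planted modules), `"nested"`
#'   (exponentially decaying fill) or `"random"` (uniform link
#'   probability).
#' @param n_modules,p_in,p_out modular structure: number of planted
#'   modules and within/between-module link probabilities (defaults 3,
#'   0.9, 0.05).
#' @param decay nested structure: rate of the exponential fill decay
#'   (default 3).
#' @param p random structure: link probability (default 0.3).
#' @param meanlog,sdlog log-normal read-count model on realized links
#'   (defaults 3 and 1.5, giving the right-skewed per-link read
#'   distributions typical of metabarcoding abundance tables); weights
#'   are rounded up so every link keeps at least one read.
#' @param seed integer seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(I, J, structure = c("modular", "nested", "random"),
                           n_modules = 3, p_in = 0.9, p_out = 0.05,
                           decay = 3, p = 0.3,
                           meanlog = 3, sdlog = 1.5, seed = 1) {
  structure <- match.arg(structure)
  stopifnot(I >= 2, J >= 2, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            p >= 0, p <= 1, sdlog > 0, n_modules >= 1)
  base::structure(list(I = I, J = J, structure = structure,
                       n_modules = n_modules, p_in = p_in, p_out = p_out,
                       decay = decay, p = p, meanlog = meanlog, sdlog = sdlog,
                       seed = as.integer(seed)),
                  class = "community_spec")
}

#' Generate an interaction matrix with planted structure
#'
#' Draws link presence according to the spec's structure, weights the
#' realized links with rounded-up log-normal read counts, prunes empty
#' hosts and taxa, and returns the planted ground truth (module
#' memberships or nested node orders) restricted to the surviving
#' nodes.
#'
#' @param spec a [community_spec()].
#' @return List with elements `matrix` (hosts x taxa counts), `truth`
#'   (for modular structure: integer vectors `rows` and `cols` of
#'   planted module ids; for nested: the planted row/column orders),
#'   and the `spec` echo.
#' @export
gen_matrix <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(spec$seed, {
    I <- spec$I; J <- spec$J
    truth <- NULL
    prob <- switch(spec$structure,
      modular = {
        row_mod <- rep(seq_len(spec$n_modules), length.out = I)[order(
          rep(seq_len(spec$n_modules), length.out = I))]
        col_mod <- rep(seq_len(spec$n_modules), length.out = J)[order(
          rep(seq_len(spec$n_modules), length.out = J))]
        truth <- list(rows = row_mod, cols = col_mod)
        ifelse(outer(row_mod, col_mod, "=="), spec$p_in, spec$p_out)
      },
      nested = {
        truth <- list(row_order = seq_len(I), col_order = seq_len(J))
        outer((seq_len(I) - 1) / (I - 1), (seq_len(J) - 1) / (J - 1),
              function(a, b) exp(-spec$decay * (a + b)))
      },
      random = matrix(spec$p, I, J)
    )
    links <- matrix(stats::runif(I * J) < prob, I, J)
    w <- matrix(0, I, J)
    w[links] <- ceiling(stats::rlnorm(sum(links), spec$meanlog, spec$sdlog))
    dimnames(w) <- list(paste0("T", seq_len(I)), paste0("F", seq_len(J)))
    keep_r <- rowSums(w) > 0
    keep_c <- colSums(w) > 0
    if (!any(keep_r) || !any(keep_c)) {
      stop("spec produced an empty matrix; raise the link probability",
           call. = FALSE)
    }
    m <- w[keep_r, keep_c, drop = FALSE]
    if (!is.null(truth$rows)) {
      truth$rows <- truth$rows[keep_r]
      truth$cols <- truth$cols[keep_c]
    }
    list(matrix = m, truth = truth, spec = spec)
  })
}

#' Specify a synthetic hit table
#'
#' @param taxa data frame with columns `taxon`, `lineage` (semicolon
#'   `k__...;...;g__...` string), `identity_mean`, `identity_sd`.
#' @param n_samples number of host samples.
#' @param coverage percent coverage stamped on every hit (default 95).
#' @param reads_meanlog,reads_sdlog log-normal read-count model per
#'   (sample, taxon).
#' @param seed integer seed.
#' @return A `hit_table_spec` list.
#' @export
hit_table_spec <- function(taxa, n_samples = 3, coverage = 95,
                           reads_meanlog = 3, reads_sdlog = 1, seed = 1) {
  stopifnot(is.data.frame(taxa),
            all(c("taxon", "lineage", "identity_mean", "identity_sd") %in%
                  names(taxa)))
  structure(list(taxa = taxa, n_samples = n_samples, coverage = coverage,
                 reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
                 seed = as.integer(seed)),
            class = "hit_table_spec")
}

#' Generate a synthetic hit table
#'
#' Emits one best-hit row per (sample, taxon) with identity drawn from
#' the taxon's normal model (clipped to \[0, 100\]), the spec'd
#' coverage, a score proportional to identity, and log-normal read
#' counts. With `identity_sd = 0` the expected rank of every taxon
#' under [default_rank_rules()] is deterministic.
#'
#' @param spec a [hit_table_spec()].
#' @return Hit table data frame in the layout [classify_hits()]
#'   expects.
#' @export
gen_hits <- function(spec) {
  stopifnot(inherits(spec, "hit_table_spec"))
  .with_seed(spec$seed, {
    tx <- spec$taxa
    grid <- expand.grid(sample = seq_len(spec$n_samples),
                        taxon = seq_len(nrow(tx)))
    identity <- pmin(100, pmax(0, stats::rnorm(
      nrow(grid), tx$identity_mean[grid$taxon], tx$identity_sd[grid$taxon])))
    data.frame(
      query_id = sprintf("MOTU_%03d", grid$taxon),
      sample_id = sprintf("S%02d", grid$sample),
      subject_lineage = tx$lineage[grid$taxon],
      pct_identity = identity,
      pct_coverage = spec$coverage,
      score = round(2 * identity),
      read_count = ceiling(stats::rlnorm(nrow(grid), spec$reads_meanlog,
                                         spec$reads_sdlog)),
      stringsAsFactors = FALSE
    )
  })
}

# Degree sequences of the 11-tree x 45-taxon Mediterranean myrtle
# foliar-endophyte reference network (94 links).
.reference_hl_degrees <- function() {
  c("Ascomycota sp." = 1, "Aurantiporus sp.1" = 10, "Aurantiporus sp.2" = 1,
    "Auriculariales sp." = 1, "Botryobasidium sp." = 2, "Calocera sp." = 1,
    "Candida sp." = 1, "Ceratastomella sp." = 1, "Ceratobasidium sp." = 1,
    "Chaetothyriales sp." = 1, "Dacrymyces sp." = 1, "Filobasidium sp." = 1,
    "Flagelloscypha sp." = 1, "Ganoderma sp." = 4, "Gloeoporus sp." = 1,
    "Gymnopilus sp.1" = 1, "Gymnopilus sp.2" = 1, "Gymnopilus sp.3" = 2,
    "Hymenochaetaceae sp.1" = 4, "Hymenochaetales sp.1" = 1,
    "Hymenochaetales sp.2" = 1, "Hymenochaetales sp.3" = 2,
    "Hymenochaete sp." = 3, "Hyphoderma sp." = 4, "Hyphodontia sp." = 2,
    "Malassezia sp." = 1, "Naganishia sp." = 1, "Neopestalotiopsis sp." = 5,
    "Phragmidium sp." = 1, "Physisporinus sp." = 2, "Polyporaceae sp.1" = 7,
    "Polyporaceae sp.2" = 9, "Pterulaceae sp." = 2, "Pycnoporus sp." = 1,
    "Rhodotorula sp." = 2, "Spegazzinia sp." = 1, "Sporobolomyces sp." = 1,
    "Sympodiomycopsis sp." = 1, "Thelephorales sp." = 3, "Trametes sp.1" = 1,
    "Trametes sp.2" = 1, "Trametes sp.3" = 1, "Tricholomataceae sp." = 1,
    "Trichomerium sp." = 1, "Tyromyces sp." = 3)
}

.reference_ll_degrees <- function() {
  stats::setNames(c(14, 3, 6, 16, 4, 9, 9, 8, 16, 3, 6),
                  paste0("T", 1:11))
}

#' Realize a bipartite binary matrix from degree sequences
#'
#' Deterministic greedy (Havel-Hakimi-style) construction: taxa are
#' processed in decreasing degree order (ties by input order) and each
#' is connected to the hosts with the largest remaining capacity (ties
#' by input order). Errors if the degree pair is not bigraphical.
#'
#' @param row_degrees,col_degrees named integer degree sequences with
#'   equal sums.
#' @return Binary matrix whose row and column sums equal the inputs.
#' @export
realize_degrees <- function(row_degrees, col_degrees) {
  stopifnot(sum(row_degrees) == sum(col_degrees),
            all(row_degrees >= 0), all(col_degrees >= 0),
            all(col_degrees <= length(row_degrees)),
            all(row_degrees <= length(col_degrees)))
  I <- length(row_degrees); J <- length(col_degrees)
  m <- matrix(0, I, J, dimnames = list(names(row_degrees), names(col_degrees)))
  capacity <- as.numeric(row_degrees)
  for (j in order(-as.numeric(col_degrees))) {
    d <- col_degrees[j]
    if (d == 0) next
    hosts <- order(-capacity)[seq_len(d)]
    if (capacity[hosts[d]] <= 0) {
      stop("degree sequences are not bigraphical", call. = FALSE)
    }
    m[hosts, j] <- 1
    capacity[hosts] <- capacity[hosts] - 1
  }
  if (!all(rowSums(m) == row_degrees)) {
    stop("degree sequences are not bigraphical", call. = FALSE)
  }
  m
}

#' Reference study fixture: 11 trees x 45 fungal taxa, 94 links
#'
#' Builds a deterministic bipartite realization of the degree
#' sequences of the Mediterranean myrtle foliar-endophyte reference
#' network (11 host trees, 45 fungal taxa, 94 links) and weights the
#' links with rounded-up log-normal read counts. The realization
#' matches the published degree sequences exactly — and therefore all
#' purely degree-determined indices — but it is a synthetic stand-in,
#' not the study's unpublished count matrix: weighted indices computed
#' from it do not reproduce the study's weighted values.
#'
#' @param seed integer seed for the link weights.
#' @param meanlog,sdlog log-normal read-count model (defaults 3, 1.5).
#' @return List with `matrix` (11 x 45 counts), `hl_degrees`,
#'   `ll_degrees`.
#' @export
gen_study_fixture <- function(seed = 1, meanlog = 3, sdlog = 1.5) {
  hl <- .reference_hl_degrees()
  ll <- .reference_ll_degrees()
  b <- realize_degrees(ll, hl)
  m <- .with_seed(seed, {
    w <- b
    w[b > 0] <- ceiling(stats::rlnorm(sum(b > 0), meanlog, sdlog))
    w
  })
  list(matrix = m, hl_degrees = hl, ll_degrees = ll)
}
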
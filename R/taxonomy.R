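#' @title Identity-threshold taxonomic rank assignment
#' @name taxonomy
#' @description
#' ITS metabarcoding pipelines commonly cap the taxonomic resolution of a
#' MOTU by the percent identity of its best reference hit: a 99% hit is
#' trusted to genus, a 92% hit only to order, and so on. These functions
#' implement that rule engine: a configurable set of identity intervals
#' mapping to ranks, best-hit selection with deterministic tie-breaks, a
#' minimum-coverage gate, and lineage truncation so that every rank deeper
#' than the assigned one is reported as `"Undefined"`.
NULL

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Default identity-to-rank rule set
#'
#' Returns the six half-open identity intervals used to cap taxonomic
#' resolution: identity >= 97 resolves to genus, \[95, 97) to family,
#' \[90, 95) to order, \[85, 90) to class, (80, 85) to phylum, and
#' identity <= 80 to kingdom. Intervals are closed at the lower bound
#' except the phylum interval, whose lower end is open so that exactly
#' 80 falls to kingdom. The default minimum hit coverage is 90%: a best
#' hit covering less of the query is left unassigned.
#'
#' @param min_coverage minimum percent query coverage for an assignment
#'   (default 90).
#' @return A `rank_rules` object: a data frame of intervals (columns
#'   `rank`, `lower`, `upper`, `lower_closed`) with attribute
#'   `min_coverage`.
#' @examples
#' rules <- default_rank_rules()
#' assign_rank(99.38, rules)  # "genus"
#' assign_rank(92.86, rules)  # "order"
#' @export
default_rank_rules <- function(min_coverage = 90) {
  rules <- data.frame(
    rank         = c("genus", "family", "order", "class", "phylum", "kingdom"),
    lower        = c(97, 95, 90, 85, 80, 0),
    upper        = c(100, 97, 95, 90, 85, 80),
    lower_closed = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  rank_rules(rules, min_coverage = min_coverage)
}

#' Construct and validate a rank rule set
#'
#' @param rules data frame with columns `rank`, `lower`, `upper` and
#'   optionally `lower_closed` (default: closed at the lower bound).
#' @param min_coverage minimum percent coverage gate.
#' @return A validated `rank_rules` object.
#' @export
rank_rules <- function(rules, min_coverage = 90) {
  stopifnot(is.data.frame(rules),
            all(c("rank", "lower", "upper") %in% names(rules)))
  if (is.null(rules$lower_closed)) rules$lower_closed <- TRUE
  if (!all(rules$rank %in% RANKS)) {
    stop("unknown rank name(s): ",
         paste(setdiff(rules$rank, RANKS), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rules$rank)) stop("duplicate rank in rule set", call. = FALSE)
  rules <- rules[order(rules$lower, decreasing = TRUE), , drop = FALSE]
  # intervals must tile [0, 100]: each upper bound meets the previous lower
  if (rules$upper[1] < 100 || rules$lower[nrow(rules)] > 0) {
    stop("rule intervals must cover [0, 100]", call. = FALSE)
  }
  if (nrow(rules) > 1 &&
      any(abs(rules$upper[-1] - rules$lower[-nrow(rules)]) > 1e-9)) {
    stop("rule intervals must be contiguous (no gaps or overlaps)", call. = FALSE)
  }
  # deeper ranks must sit at higher identity (monotonicity)
  depth <- match(rules$rank, RANKS)
  if (is.unsorted(rev(depth), strictly = TRUE)) {
    stop("higher identity must never map to a shallower rank", call. = FALSE)
  }
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 100) {
    stop("`min_coverage` must be a percentage in [0, 100]", call. = FALSE)
  }
  structure(rules, min_coverage = min_coverage, class = c("rank_rules", "data.frame"))
}

#' Read a rank rule set from a YAML config file
#'
#' The file holds a `min_coverage` scalar and a `rules` list of
#' `{rank, lower, upper, lower_closed}` entries.
#'
#' @param path path to a YAML file.
#' @return A `rank_rules` object.
#' @export
read_rank_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(cfg$rules, function(r) {
    data.frame(rank = r$rank, lower = r$lower, upper = r$upper,
               lower_closed = if (is.null(r$lower_closed)) TRUE else r$lower_closed,
               stringsAsFactors = FALSE)
  }))
  rank_rules(rules, min_coverage = if (is.null(cfg$min_coverage)) 90 else cfg$min_coverage)
}

#' Write a rank rule set to a YAML config file
#'
#' @param rules a `rank_rules` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rank_rules <- function(rules, path) {
  yaml::write_yaml(list(
    min_coverage = attr(rules, "min_coverage"),
    rules = lapply(seq_len(nrow(rules)), function(i) {
      list(rank = rules$rank[i], lower = rules$lower[i],
           upper = rules$upper[i], lower_closed = rules$lower_closed[i])
    })
  ), path)
  invisible(path)
}

#' Map a percent identity to a taxonomic rank
#'
#' @param identity percent identity (scalar or vector) in \[0, 100\].
#' @param rules a `rank_rules` object, default [default_rank_rules()].
#' @return Character vector of rank names.
#' @examples
#' assign_rank(c(99.38, 92.86, 90.49, 80))
#' @export
assign_rank <- function(identity, rules = default_rank_rules()) {
  if (!is.numeric(identity) || anyNA(identity) ||
      any(identity < 0 | identity > 100)) {
    stop("`identity` must lie in [0, 100]", call. = FALSE)
  }
  vapply(identity, function(x) {
    for (i in seq_len(nrow(rules))) {
      lo_ok <- if (rules$lower_closed[i]) x >= rules$lower[i] else x > rules$lower[i]
      hi_ok <- if (i == 1) x <= rules$upper[i] else x < rules$upper[i]
      if (lo_ok && hi_ok) return(rules$rank[i])
    }
    # only reachable when a lower bound is open: value falls to the next rule
    rules$rank[nrow(rules)]
  }, character(1))
}

#' Truncate a lineage at a rank
#'
#' Replaces every rank deeper than `rank` by `"Undefined"`. Ranks the
#' lineage never resolved stay `"Undefined"`; truncation cannot invent
#' deeper ranks and is idempotent.
#'
#' @param lineage named character vector or single-row data frame with
#'   elements `kingdom`, `phylum`, `class`, `order`, `family`, `genus`.
#' @param rank rank name at which to cap resolution, or `"unassigned"`
#'   (everything becomes `"Undefined"`).
#' @return Named character vector over the six ranks.
#' @export
truncate_lineage <- function(lineage, rank) {
  if (is.data.frame(lineage)) lineage <- unlist(lineage[1, , drop = TRUE])
  out <- stats::setNames(rep("Undefined", length(RANKS)), RANKS)
  keep <- intersect(names(lineage), RANKS)
  out[keep] <- as.character(lineage[keep])
  out[is.na(out) | out == ""] <- "Undefined"
  if (identical(rank, "unassigned")) {
    out[] <- "Undefined"
    return(out)
  }
  depth <- match(rank, RANKS)
  if (is.na(depth)) stop("unknown rank: ", rank, call. = FALSE)
  if (depth < length(RANKS)) out[(depth + 1):length(RANKS)] <- "Undefined"
  # once a rank is Undefined all deeper ranks are Undefined
  undef <- which(out == "Undefined")
  if (length(undef)) out[seq_along(out) >= min(undef)] <- "Undefined"
  out
}

#' Select the best hit among a MOTU's reference hits
#'
#' Maximal alignment score wins; ties break by higher percent identity,
#' then higher percent coverage, then the lexicographically smallest
#' lineage string, so the choice is deterministic under any row order.
#'
#' @param hits data frame of hits for one MOTU (columns `score`,
#'   `pct_identity`, `pct_coverage` and the six rank columns or a
#'   `subject_lineage` string).
#' @return The selected row of `hits`.
#' @export
best_hit <- function(hits) {
  if (!is.data.frame(hits) || nrow(hits) == 0) {
    stop("`hits` must be a non-empty data frame", call. = FALSE)
  }
  key <- .lineage_key(hits)
  ord <- order(-hits$score, -hits$pct_identity, -hits$pct_coverage, key,
               method = "radix")
  hits[ord[1], , drop = FALSE]
}

.lineage_key <- function(hits) {
  if (!is.null(hits$subject_lineage)) return(as.character(hits$subject_lineage))
  cols <- intersect(RANKS, names(hits))
  if (!length(cols)) return(rep("", nrow(hits)))
  do.call(paste, c(hits[cols], sep = ";"))
}

#' Classify MOTUs from a table of reference hits
#'
#' Per MOTU: select the best hit, gate on minimum coverage (below the
#' gate the MOTU is `"unassigned"` with an all-`"Undefined"` lineage),
#' map percent identity to a rank, and truncate the lineage at that
#' rank. Malformed rows (missing identity, identity or coverage outside
#' \[0, 100\], negative score) are skipped with a warning.
#'
#' @param hits hit table as returned by [read_hit_table()]: one row per
#'   hit with columns `query_id`, `sample_id`, the six rank columns (or
#'   `subject_lineage`), `pct_identity`, `pct_coverage`, `score`,
#'   `read_count`.
#' @param rules a `rank_rules` object.
#' @return Data frame sorted by `motu_id` with columns `motu_id`, the
#'   six ranks, `assigned_rank`, `pct_identity`, `pct_coverage`.
#' @export
classify_hits <- function(hits, rules = default_rank_rules()) {
  stopifnot(is.data.frame(hits))
  hits <- .expand_lineage(hits)
  bad <- !is.finite(hits$pct_identity) | hits$pct_identity < 0 | hits$pct_identity > 100 |
    !is.finite(hits$pct_coverage) | hits$pct_coverage < 0 | hits$pct_coverage > 100 |
    !is.finite(hits$score) | hits$score < 0
  if (any(bad)) {
    warning(sum(bad), " malformed hit row(s) skipped", call. = FALSE)
    hits <- hits[!bad, , drop = FALSE]
  }
  if (nrow(hits) == 0) stop("no valid hit rows to classify", call. = FALSE)
  min_cov <- attr(rules, "min_coverage")
  motus <- sort(unique(as.character(hits$query_id)))
  rows <- lapply(motus, function(id) {
    bh <- best_hit(hits[hits$query_id == id, , drop = FALSE])
    rank <- if (bh$pct_coverage < min_cov) "unassigned" else
      assign_rank(bh$pct_identity, rules)
    lin <- truncate_lineage(bh[1, RANKS], rank)
    cbind(data.frame(motu_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(lin), stringsAsFactors = FALSE),
          data.frame(assigned_rank = rank,
                     pct_identity = bh$pct_identity,
                     pct_coverage = bh$pct_coverage,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# accept either six rank columns or a semicolon "k__...;p__...;..." string;
# normalize placeholder taxon names to the "Undefined" sentinel
.expand_lineage <- function(hits) {
  if (all(RANKS %in% names(hits))) {
    for (r in RANKS) {
      v <- as.character(hits[[r]])
      v[is.na(v) | v == "" |
          tolower(v) %in% c("undefined", "unidentified", "incertae sedis", "na")] <-
        "Undefined"
      hits[[r]] <- v
    }
    return(hits)
  }
  if (is.null(hits$subject_lineage)) {
    stop("hit table needs either the six rank columns or `subject_lineage`",
         call. = FALSE)
  }
  lin <- parse_lineage_strings(hits$subject_lineage)
  cbind(hits, lin)
}

#' Parse semicolon-delimited lineage strings
#'
#' Accepts the UNITE-style `"k__Fungi;p__...;c__...;o__...;f__...;g__..."`
#' dialect (prefixes optional). Missing, empty, `"unidentified"` or
#' `"Incertae sedis"` fields become `"Undefined"`.
#'
#' @param x character vector of lineage strings.
#' @return Data frame with the six rank columns.
#' @export
parse_lineage_strings <- function(x) {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    vals <- stats::setNames(rep("Undefined", length(RANKS)), RANKS)
    for (i in seq_along(prefixes)) {
      hit <- p[startsWith(p, prefixes[i])]
      if (length(hit)) {
        vals[i] <- sub(prefixes[i], "", hit[1], fixed = TRUE)
      } else if (!any(grepl("__", p, fixed = TRUE)) && length(p) >= i) {
        vals[i] <- p[i]
      }
    }
    vals[vals == "" | is.na(vals) |
           tolower(vals) %in% c("undefined", "unidentified", "incertae sedis",
                                "na")] <- "Undefined"
    vals
  })
  as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
}

#' Label putative species within genera
#'
#' Mirrors the usual "Genus sp. N" morphotype labelling: genus-level
#' MOTUs sharing a genus get integer suffixes in `motu_id` order
#' ("Aurantiporus sp. 1", "Aurantiporus sp. 2"); a genus with a single
#' MOTU gets plain "Genus sp.". MOTUs resolved above genus are labelled
#' by their deepest resolved taxon ("Hymenochaetales sp. 1", ...).
#'
#' @param assignments output of [classify_hits()].
#' @return Character vector of labels, parallel to `assignments` rows.
#' @export
putative_species <- function(assignments) {
  base <- vapply(seq_len(nrow(assignments)), function(i) {
    lin <- unlist(assignments[i, RANKS])
    resolved <- lin[lin != "Undefined"]
    if (length(resolved) == 0) "Unassigned" else resolved[[length(resolved)]]
  }, character(1))
  labels <- character(length(base))
  for (b in unique(base)) {
    idx <- which(base == b)
    if (length(idx) == 1) {
      labels[idx] <- paste(b, "sp.")
    } else {
      labels[idx] <- paste0(b, " sp. ", seq_along(idx))
    }
  }
  labels
}

#' Read a tab-separated hit table
#'
#' Expected columns: `query_id`, `sample_id`, `subject_lineage` (or the
#' six rank columns), `pct_identity`, `pct_coverage`, `score`,
#' `read_count`.
#'
#' @param path path to a TSV file with a header row.
#' @return Data frame of hits.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("query_id", "sample_id", "pct_identity", "pct_coverage",
            "score", "read_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read 12-column BLAST tabular output with a sidecar lineage map
#'
#' Reads the classic 12-column tabular format (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and joins subject ids to lineages via a two-column TSV map
#' (`subject_id`, `lineage`). Percent coverage is taken as
#' `100 * length / query_length` when a `query_lengths` map is given,
#' otherwise left as `NA` for the caller to gate manually.
#'
#' @param path BLAST outfmt-6-like file (no header).
#' @param lineage_map path to a TSV with columns `subject_id`,
#'   `lineage`.
#' @param sample_id sample identifier to stamp on every row.
#' @param query_lengths optional named vector of query lengths.
#' @param read_counts optional named vector of per-query read counts
#'   (default 1).
#' @return Hit table in the layout [classify_hits()] expects.
#' @export
read_blast6 <- function(path, lineage_map, sample_id = "S1",
                        query_lengths = NULL, read_counts = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 tab-separated BLAST columns", call. = FALSE)
  names(df)[1:12] <- cols
  lm <- utils::read.delim(lineage_map, stringsAsFactors = FALSE)
  lineage <- lm$lineage[match(df$sseqid, lm$subject_id)]
  if (anyNA(lineage)) {
    warning(sum(is.na(lineage)), " hit(s) without a lineage-map entry dropped",
            call. = FALSE)
  }
  cov <- if (is.null(query_lengths)) NA_real_ else
    100 * df$length / unname(query_lengths[df$qseqid])
  rc <- if (is.null(read_counts)) 1L else unname(read_counts[df$qseqid])
  out <- data.frame(query_id = df$qseqid, sample_id = sample_id,
                    subject_lineage = lineage, pct_identity = df$pident,
                    pct_coverage = cov, score = df$bitscore,
                    read_count = rc, stringsAsFactors = FALSE)
  out[!is.na(out$subject_lineage), , drop = FALSE]
}

#' Write taxonomic assignments to TSV
#'
#' @param assignments output of [classify_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
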
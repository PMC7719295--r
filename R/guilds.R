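#' @title Trophic modes and ecological guilds
#' @name guilds
#' @description
#' Fungal taxa are classified into three canonical trophic modes —
#' Saprotroph, Pathotroph, Symbiotroph, or any combination — and into
#' finer guilds (e.g. "Wood Saprotroph") by lookup in a local guild
#' database snapshot (a FunGuild-style TSV, optionally extended with
#' manual literature-derived entries). Matching is rank-descending:
#' a genus entry beats a family entry beats an order entry, and the
#' first match wins. The trophic partition tallies taxa over the seven
#' non-empty mode subsets (the Venn-diagram cells) plus an unassigned
#' bucket.
NULL

TROPHIC_MODES <- c("Pathotroph", "Saprotroph", "Symbiotroph")

# tolerant spelling/dash normalization for mode tokens
.mode_alias <- c(
  "pathotroph" = "Pathotroph", "pathothroph" = "Pathotroph",
  "saprotroph" = "Saprotroph", "saprothroph" = "Saprotroph",
  "symbiotroph" = "Symbiotroph", "symbiothroph" = "Symbiotroph"
)

#' Parse a trophic-mode string into the canonical mode set
#'
#' Splits on hyphen, en-dash or em-dash, normalizes spelling variants
#' ("Pathothroph", "Saprothroph") with a message, and returns the
#' sorted canonical subset. Unknown tokens yield `NULL` with a
#' warning.
#'
#' @param x a single mode string, e.g.
#'   `"Pathotroph-Saprotroph-Symbiotroph"`.
#' @return Character vector of canonical modes, or `NULL` if any token
#'   is unknown.
#' @export
parse_trophic_modes <- function(x) {
  tokens <- trimws(strsplit(x, "[-–—−]")[[1]])
  tokens <- tokens[tokens != ""]
  canon <- unname(.mode_alias[tolower(tokens)])
  if (anyNA(canon)) {
    warning("unknown trophic mode token(s) in \"", x, "\"", call. = FALSE)
    return(NULL)
  }
  if (any(canon != tokens)) {
    message("normalized trophic mode spelling in \"", x, "\"")
  }
  sort(unique(canon))
}

#' Load a guild database snapshot
#'
#' Reads a TSV with columns `key` (taxon name), `rank` (genus, family,
#' order, class or phylum), `trophic_modes` (hyphen-joined) and
#' `guild`; an optional `label` column is preserved. Rows whose mode
#' string contains an unknown token are rejected with a warning.
#'
#' @param path TSV path; defaults to the bundled guild snapshot for
#'   the Mediterranean myrtle foliar-endophyte community.
#' @return A `guild_db` data frame with a `modes` list column of
#'   canonical mode sets.
#' @export
load_guild_db <- function(path = system.file("extdata", "myrtle_guilds.tsv",
                                             package = "endonet")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("key", "rank", "trophic_modes", "guild")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("guild database is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok_rank <- df$rank %in% RANKS
  if (any(!ok_rank)) {
    warning(sum(!ok_rank), " guild row(s) with invalid rank rejected",
            call. = FALSE)
    df <- df[ok_rank, , drop = FALSE]
  }
  modes <- lapply(df$trophic_modes, parse_trophic_modes)
  bad <- vapply(modes, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " guild row(s) with unknown trophic mode rejected",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    modes <- modes[!bad]
  }
  df$modes <- modes
  structure(df, class = c("guild_db", "data.frame"))
}

#' Annotate taxa with trophic modes and guilds
#'
#' Matches each assignment against the database at the deepest
#' available rank first (genus, then family, order, class, phylum);
#' the first matching database row wins. Unmatched taxa are returned
#' as unassigned and counted in a message.
#'
#' @param assignments output of [classify_hits()], or any data frame
#'   with the six rank columns (rows = taxa).
#' @param db a `guild_db` from [load_guild_db()].
#' @param taxon_labels optional display labels (default
#'   [putative_species()] of the assignments).
#' @return Data frame with columns `taxon`, `matched`, `modes` (list
#'   column), `guild`.
#' @export
annotate_guilds <- function(assignments, db, taxon_labels = NULL) {
  stopifnot(inherits(db, "guild_db"))
  if (is.null(taxon_labels)) taxon_labels <- putative_species(assignments)
  search_ranks <- rev(RANKS[-1])               # genus ... phylum
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    for (r in search_ranks) {
      name <- assignments[[r]][i]
      if (is.na(name) || name == "Undefined") next
      hit <- which(db$rank == r & db$key == name)
      if (length(hit)) {
        return(data.frame(taxon = taxon_labels[i], matched = TRUE,
                          modes = I(db$modes[hit[1]]),
                          guild = db$guild[hit[1]],
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(taxon = taxon_labels[i], matched = FALSE,
               modes = I(list(character(0))), guild = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$matched)) {
    message(sum(!out$matched), " taxa without a guild database entry")
  }
  out
}

#' Trophic-mode partition (Venn-diagram cells)
#'
#' Tallies taxa over the seven non-empty subsets of
#' \{Pathotroph, Saprotroph, Symbiotroph\} plus an `unassigned`
#' bucket, with percentages over assigned taxa, and the per-mode
#' containing and exclusive fractions.
#'
#' @param annotated output of [annotate_guilds()] or a `guild_db`
#'   (each row one taxon).
#' @return A `trophic_partition` list: `counts` (named by
#'   hyphen-joined subset), `unassigned`, `n_assigned`, `percent`,
#'   `containing` and `exclusive` per-mode fractions.
#' @export
trophic_partition <- function(annotated) {
  modes <- annotated$modes
  if (is.null(modes)) stop("input has no `modes` column", call. = FALSE)
  subset_names <- unlist(lapply(seq_along(TROPHIC_MODES), function(k) {
    combn(TROPHIC_MODES, k, paste, collapse = "-")
  }))
  counts <- stats::setNames(integer(length(subset_names)), subset_names)
  unassigned <- 0L
  for (ms in modes) {
    ms <- sort(unique(unlist(ms)))
    if (length(ms) == 0) {
      unassigned <- unassigned + 1L
    } else {
      key <- paste(ms, collapse = "-")
      counts[key] <- counts[key] + 1L
    }
  }
  n_assigned <- sum(counts)
  containing <- vapply(TROPHIC_MODES, function(mode) {
    sum(counts[grepl(mode, names(counts), fixed = TRUE)])
  }, numeric(1)) / max(n_assigned, 1)
  exclusive <- vapply(TROPHIC_MODES, function(mode) {
    counts[[mode]]
  }, numeric(1)) / max(n_assigned, 1)
  structure(list(counts = counts, unassigned = unassigned,
                 n_assigned = n_assigned,
                 percent = 100 * counts / max(n_assigned, 1),
                 containing = containing, exclusive = exclusive),
            class = "trophic_partition")
}

#' @export
print.trophic_partition <- function(x, ...) {
  cat("Trophic partition over", x$n_assigned, "assigned taxa",
      sprintf("(+%d unassigned)\n", x$unassigned))
  for (k in names(x$counts)) {
    if (x$counts[[k]] > 0)
      cat(sprintf("  %-35s %3d (%.1f%%)\n", k, x$counts[[k]], x$percent[[k]]))
  }
  invisible(x)
}

#' Write a trophic partition as JSON
#'
#' @param partition a `trophic_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trophic_partition <- function(partition, path) {
  jsonlite::write_json(lapply(unclass(partition), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
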
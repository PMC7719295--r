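# Shared fixtures built in code.

# Reference survey rows whose printed taxonomic resolution is internally
# consistent with the identity-interval rules (38 of 44; the 6 exceptions,
# e.g. a 96.90% hit printed at genus, are documented in the vignette and
# deliberately excluded).
consistent_reference_rows <- function() {
  g <- c(99.38, 98.70, 97.15, 98.71, 98.17, 99.12, 99.66, 99.73, 99.19,
         97.78, 99.29, 97.66, 98.24, 98.25, 99.37, 99.68, 99.02, 99.72,
         98.58, 97.08, 98.51, 99.09, 99.43, 97.56, 99.12, 99.71, 98.77,
         99.04, 97.84, 97.89)
  f <- c(95.38, 95.04, 95.29, 96.17)
  o <- c(92.86, 90.49, 91.10, 93.41)
  data.frame(identity = c(g, f, o),
             expected_rank = rep(c("genus", "family", "order"),
                                 c(length(g), length(f), length(o))),
             stringsAsFactors = FALSE)
}

# minimal well-formed hit table rows
make_hit <- function(query_id = "M1", sample_id = "S1",
                     kingdom = "Fungi", phylum = "Basidiomycota",
                     class = "Agaricomycetes", order = "Polyporales",
                     family = "Meruliaceae", genus = "Aurantiporus",
                     pct_identity = 99, pct_coverage = 100,
                     score = 2 * pct_identity, read_count = 10) {
  data.frame(query_id = query_id, sample_id = sample_id, kingdom = kingdom,
             phylum = phylum, class = class, order = order, family = family,
             genus = genus, pct_identity = pct_identity,
             pct_coverage = pct_coverage, score = score,
             read_count = read_count, stringsAsFactors = FALSE)
}

# path bipartite network T1 - F1 - T2 - F2 - T3 (rows hosts, cols taxa)
path_matrix <- function(w = 1) {
  m <- matrix(0, 3, 2, dimnames = list(paste0("T", 1:3), paste0("F", 1:2)))
  m["T1", "F1"] <- w; m["T2", "F1"] <- w
  m["T2", "F2"] <- w; m["T3", "F2"] <- w
  m
}
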
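test_that("default rule intervals tile [0, 100] and honor the boundary convention", {
  rules <- default_rank_rules()
  grid <- seq(0, 100, by = 0.125)
  ranks <- assign_rank(grid, rules)
  expect_true(all(ranks %in% c("kingdom", "phylum", "class", "order",
                               "family", "genus")))
  # boundary cases: lower-closed except phylum, whose lower end falls to kingdom
  expect_identical(assign_rank(c(97, 96.999, 95, 94.999, 90, 89.999,
                                 85, 84.999, 80.001, 80, 50)),
                   c("genus", "family", "family", "order", "order", "class",
                     "class", "phylum", "phylum", "kingdom", "kingdom"))
  expect_error(assign_rank(101), "identity")
  expect_error(assign_rank(-1), "identity")
})

test_that("higher identity never maps to a shallower rank", {
  depth <- function(r) match(r, c("kingdom", "phylum", "class", "order",
                                  "family", "genus"))
  set.seed(42)
  x <- runif(500, 0, 100)
  y <- runif(500, 0, 100)
  hi <- pmax(x, y); lo <- pmin(x, y)
  expect_true(all(depth(assign_rank(hi)) >= depth(assign_rank(lo))))
})

test_that("rule sets reject gaps, overlaps and non-monotone rank maps", {
  expect_error(rank_rules(data.frame(rank = c("genus", "kingdom"),
                                     lower = c(97, 0), upper = c(100, 90))),
               "contiguous")
  expect_error(rank_rules(data.frame(rank = c("kingdom", "genus"),
                                     lower = c(50, 0), upper = c(100, 50))),
               "shallower")
  expect_error(rank_rules(data.frame(rank = "genus", lower = 50, upper = 100)),
               "cover")
})

test_that("rule sets round-trip through YAML", {
  rules <- default_rank_rules(min_coverage = 85)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rank_rules(rules, path)
  back <- read_rank_rules(path)
  expect_equal(as.data.frame(back), as.data.frame(rules))
  expect_equal(attr(back, "min_coverage"), 85)
})

test_that("lineage truncation is idempotent and cannot invent ranks", {
  full <- c(kingdom = "Fungi", phylum = "Basidiomycota",
            class = "Agaricomycetes", order = "Polyporales",
            family = "Meruliaceae", genus = "Aurantiporus")
  expect_identical(truncate_lineage(full, "genus"), full)
  t_order <- truncate_lineage(full, "order")
  expect_identical(unname(t_order[c("family", "genus")]),
                   c("Undefined", "Undefined"))
  expect_identical(unname(t_order[1:4]), unname(full[1:4]))
  expect_identical(truncate_lineage(t_order, "order"), t_order)
  # a lineage already capped at class stays capped when asked for genus
  at_class <- truncate_lineage(full, "class")
  expect_identical(truncate_lineage(at_class, "genus"), at_class)
  # unassigned wipes everything
  expect_true(all(truncate_lineage(full, "unassigned") == "Undefined"))
})

test_that("best hit follows score, identity, coverage, lineage tie-breaks", {
  hits <- rbind(
    make_hit(score = 240, pct_identity = 99, genus = "Zzz"),
    make_hit(score = 250, pct_identity = 96, genus = "Bbb"),
    make_hit(score = 250, pct_identity = 98, genus = "Aaa"))
  expect_equal(best_hit(hits)$genus, "Aaa")
  # exhaustive-sort oracle over all row orders of a 3-hit fixture
  key <- do.call(paste, c(hits[c("kingdom", "phylum", "class", "order",
                                 "family", "genus")], sep = ";"))
  oracle <- hits[order(-hits$score, -hits$pct_identity, -hits$pct_coverage,
                       key), ][1, ]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    expect_equal(best_hit(hits[p, ])$genus, oracle$genus)
  }
  # coverage breaks a score+identity tie
  tied <- rbind(make_hit(score = 250, pct_identity = 98, pct_coverage = 92,
                         genus = "LowCov"),
                make_hit(score = 250, pct_identity = 98, pct_coverage = 99,
                         genus = "HighCov"))
  expect_equal(best_hit(tied)$genus, "HighCov")
  expect_error(best_hit(data.frame()), "non-empty")
})

test_that("classify gates on coverage, truncates, sorts and warns on bad rows", {
  hits <- rbind(
    make_hit("M2", pct_identity = 98.58, pct_coverage = 90, genus = "Neopestalotiopsis"),
    make_hit("M1", pct_identity = 99.5, pct_coverage = 50, genus = "Covgated"),
    make_hit("M3", pct_identity = 92.86, pct_coverage = 93, genus = "Deep"))
  out <- classify_hits(hits)
  expect_identical(out$motu_id, c("M1", "M2", "M3"))
  expect_identical(out$assigned_rank, c("unassigned", "genus", "order"))
  expect_true(all(unlist(out[1, c("kingdom", "phylum", "class", "order",
                                  "family", "genus")]) == "Undefined"))
  expect_identical(out$genus[3], "Undefined")
  expect_identical(out$family[3], "Undefined")
  expect_identical(out$order[3], "Polyporales")
  # malformed rows are skipped with a warning, not fatal
  bad <- rbind(hits, make_hit("M4", pct_identity = 250))
  expect_warning(out2 <- classify_hits(bad), "malformed")
  expect_false("M4" %in% out2$motu_id)
})

test_that("classify is deterministic under row reordering", {
  set.seed(7)
  panel <- data.frame(
    taxon = paste0("t", 1:10),
    lineage = paste0("k__Fungi;p__P", 1:10, ";c__C", 1:10, ";o__O", 1:10,
                     ";f__F", 1:10, ";g__G", 1:10),
    identity_mean = seq(78, 99.5, length.out = 10),
    identity_sd = 0.5, stringsAsFactors = FALSE)
  hits <- gen_hits(hit_table_spec(panel, n_samples = 4, seed = 3))
  ref <- classify_hits(hits)
  for (i in 1:3) {
    shuffled <- hits[sample(nrow(hits)), ]
    expect_identical(classify_hits(shuffled), ref)
  }
})

test_that("lineage strings in the k__ dialect parse with sentinel handling", {
  lin <- parse_lineage_strings(c(
    "k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Hymenochaetales;f__;g__",
    "k__Fungi;p__Ascomycota;c__unidentified;o__Incertae sedis;f__X;g__Y"))
  expect_identical(lin$family[1], "Undefined")
  expect_identical(lin$order[1], "Hymenochaetales")
  expect_identical(lin$class[2], "Undefined")
  expect_identical(lin$order[2], "Undefined")
  expect_identical(lin$genus[2], "Y")
})

test_that("putative species labels number morphotypes within a taxon", {
  hits <- rbind(make_hit("M1", genus = "Aurantiporus"),
                make_hit("M2", genus = "Aurantiporus"),
                make_hit("M3", genus = "Trametes"),
                make_hit("M4", genus = "undefined", pct_identity = 92))
  out <- classify_hits(hits)
  labels <- putative_species(out)
  expect_identical(labels[1:3], c("Aurantiporus sp. 1", "Aurantiporus sp. 2",
                                  "Trametes sp."))
  expect_identical(labels[4], "Polyporales sp.")  # order-level morphotype
})
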
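test_that("trophic mode strings normalize dashes and spelling variants", {
  expect_identical(parse_trophic_modes("Saprotroph"), "Saprotroph")
  expect_identical(parse_trophic_modes("Pathotroph–Saprotroph–Symbiotroph"),
                   c("Pathotroph", "Saprotroph", "Symbiotroph"))
  expect_message(modes <- parse_trophic_modes("Symbiotroph-Saprothroph"),
                 "normalized")
  expect_identical(modes, c("Saprotroph", "Symbiotroph"))
  expect_warning(expect_null(parse_trophic_modes("Lichenized")), "unknown")
})

test_that("the bundled guild snapshot loads with all rows mode-resolved", {
  db <- suppressMessages(load_guild_db())
  expect_s3_class(db, "guild_db")
  expect_equal(nrow(db), 44)
  expect_true(all(lengths(db$modes) >= 1))
  expect_true(all(unlist(db$modes) %in%
                    c("Pathotroph", "Saprotroph", "Symbiotroph")))
})

test_that("rows with unknown modes or ranks are rejected, not fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\trank\ttrophic_modes\tguild",
               "Trametes\tgenus\tSaprotroph\tWood Saprotroph",
               "Xylaria\tgenus\tLichenized\tweird",
               "Foo\tvariety\tSaprotroph\tx"), path)
  w <- capture_warnings(db <- load_guild_db(path))
  expect_match(w, "invalid rank", all = FALSE)
  expect_match(w, "unknown", all = FALSE)
  expect_equal(nrow(db), 1)
})

test_that("annotation matches the deepest available rank first", {
  db <- suppressMessages(load_guild_db())
  hits <- rbind(
    make_hit("M1", genus = "Aurantiporus", pct_identity = 99.38),
    # resolved only to order Hymenochaetales (family/genus in db at order level)
    make_hit("M2", order = "Hymenochaetales", family = "undefined",
             genus = "undefined", pct_identity = 95.67),
    make_hit("M3", phylum = "Glomeromycota", class = "Glomeromycetes",
             order = "Glomerales", family = "Glomeraceae", genus = "Glomus",
             pct_identity = 99))
  ann <- suppressMessages(annotate_guilds(classify_hits(hits), db))
  expect_true(ann$matched[1])
  expect_equal(ann$guild[1], "Wood Saprotroph")
  expect_true(ann$matched[2])
  expect_equal(ann$guild[2], "Ectomycorrhizal-Wood Saprotroph")
  expect_false(ann$matched[3])
  expect_length(ann$modes[[3]], 0)
})

test_that("a genus entry shadows a shallower entry for the same taxon", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\trank\ttrophic_modes\tguild",
               "Polyporales\torder\tSaprotroph\tWood Saprotroph",
               "Ganoderma\tgenus\tPathotroph\tPlant Pathogen"), path)
  db <- load_guild_db(path)
  hits <- make_hit("M1", genus = "Ganoderma", pct_identity = 99)
  ann <- annotate_guilds(classify_hits(hits), db)
  expect_equal(ann$guild, "Plant Pathogen")
  # same hit resolved only to order falls back to the order entry
  hits2 <- make_hit("M1", genus = "Ganoderma", pct_identity = 93)
  ann2 <- annotate_guilds(classify_hits(hits2), db)
  expect_equal(ann2$guild, "Wood Saprotroph")
})

test_that("the trophic partition is complete and internally consistent", {
  db <- suppressMessages(load_guild_db())
  tp <- trophic_partition(db)
  expect_equal(sum(tp$counts) + tp$unassigned, 44)
  expect_equal(sum(tp$percent), 100)
  # containing fraction can never fall below the exclusive fraction
  for (mode in c("Pathotroph", "Saprotroph", "Symbiotroph")) {
    expect_gte(tp$containing[[mode]], tp$exclusive[[mode]])
  }
  # empty input
  empty <- trophic_partition(data.frame(modes = I(list())))
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$unassigned, 0)
})

test_that("the partition is invariant to database row order for unique keys", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\trank\ttrophic_modes\tguild",
               "Trametes\tgenus\tSaprotroph\tWood Saprotroph",
               "Ganoderma\tgenus\tPathotroph-Saprotroph\tPlant Pathogen",
               "Candida\tgenus\tSymbiotroph\tEndophyte"), path)
  db <- load_guild_db(path)
  hits <- rbind(make_hit("M1", genus = "Trametes"),
                make_hit("M2", genus = "Ganoderma"),
                make_hit("M3", genus = "Candida"))
  assignments <- classify_hits(hits)
  ref <- annotate_guilds(assignments, db)
  for (ord in list(c(3, 1, 2), c(2, 3, 1))) {
    db2 <- db[ord, ]
    class(db2) <- class(db)
    shuffled <- annotate_guilds(assignments, db2)
    expect_equal(shuffled, ref)
  }
})
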
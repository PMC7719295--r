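test_that("connectance, web asymmetry and links per taxa follow their closed forms", {
  m <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(connectance(m), 0.5)
  expect_equal(connectance(matrix(1, 3, 3)), 1)
  expect_equal(web_asymmetry(m), 0)
  expect_equal(web_asymmetry(matrix(1, 1, 3)), 0.5)
  expect_equal(links_per_taxa(diag(3)), 0.5)
  set.seed(5)
  b <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(links_per_taxa(b), sum(b) / 7)
})

test_that("linkage density and weighted connectance satisfy the Bersier contract", {
  expect_equal(linkage_density(matrix(7, 1, 1)), 1)
  expect_equal(weighted_connectance(matrix(7, 1, 1)), 0.5)
  expect_equal(linkage_density(diag(3) * 5), 1)
  set.seed(6)
  for (i in 1:25) {
    r <- random_count_matrix(sample(2:6, 1), sample(2:6, 1))
    if (sum(r) == 0) next
    expect_equal(weighted_connectance(r) * (nrow(r) + ncol(r)),
                 linkage_density(r))
  }
})

test_that("NODF spans its extremes and agrees with vegan on random matrices", {
  packed <- matrix(0, 4, 4)
  packed[lower.tri(packed, diag = TRUE)] <- 1   # perfectly nested triangle
  expect_equal(nodf(packed), 100)
  expect_equal(nodf(diag(2)), 0)                # checkerboard
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:30) {
    b <- matrix(rbinom(30, 1, 0.5), 5, 6)
    if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
    v <- vegan::nestednodf(b, order = TRUE, weighted = FALSE)
    expect_equal(nodf(b), unname(v$statistic["NODF"]), tolerance = 1e-10)
  }
})

test_that("weighted NODF rewards strictly decreasing nested weights", {
  nested <- matrix(0, 3, 3)
  nested[1, ] <- c(9, 5, 2); nested[2, 1:2] <- c(6, 3); nested[3, 1] <- 4
  expect_equal(wnodf(nested), 100)
  # equal marginal totals contribute nothing
  expect_equal(wnodf(matrix(c(2, 1, 1, 2), 2, 2)), 0)
  set.seed(9)
  for (i in 1:40) {
    r <- random_count_matrix(4, 4)
    expect_equal(wnodf(r), oracle_wnodf(r))
  }
})

test_that("H2' hits 1 on diagonal and 0 on independence matrices", {
  expect_equal(h2prime(diag(4) * 6), 1)
  r <- c(2, 4); cc <- c(3, 3)
  indep <- outer(r, cc) / 6      # cell = r_i c_j / m exactly
  expect_equal(h2prime(indep), 0)
  expect_warning(h2prime(matrix(5, 1, 1)), "1x1")
})

test_that("greedy H2min packing matches exhaustive enumeration on tiny marginals", {
  cases <- list(list(r = c(4, 2, 1), cc = c(3, 3, 1)),
                list(r = c(3, 3), cc = c(2, 2, 2)),
                list(r = c(5, 1), cc = c(2, 4)))
  for (cs in cases) {
    packed <- pack_marginals(cs$r, cs$cc)
    expect_equal(rowSums(packed), cs$r)
    expect_equal(colSums(packed), cs$cc)
    p <- packed[packed > 0] / sum(packed)
    expect_equal(-sum(p * log(p)), oracle_h2min(cs$r, cs$cc), tolerance = 1e-10)
  }
})

test_that("C-score spans exclusion extremes and matches pair enumeration", {
  m <- cbind(a = c(1, 1, 0), b = c(1, 1, 0))
  expect_equal(c_score(m, "HL"), 0)               # identical columns
  expect_equal(c_score(diag(2), "HL"), 1)         # perfect checkerboard
  set.seed(10)
  kept <- 0
  while (kept < 25) {
    b <- matrix(rbinom(20, 1, 0.6), 4, 5)
    if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
    kept <- kept + 1
    expect_equal(c_score(b, "HL"), oracle_cscore(b, "HL"))
    expect_equal(c_score(b, "LL"), oracle_cscore(b, "LL"))
  }
})

test_that("Horn niche overlap is 1 for proportional and 0 for disjoint vectors", {
  prop <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(niche_overlap(prop, "HL"), 1)
  disj <- cbind(c(5, 0, 3), c(0, 2, 0))
  expect_equal(niche_overlap(disj, "HL"), 0)
  # two-pair fixture against the direct formula
  m <- cbind(c(3, 1, 0), c(1, 1, 2), c(0, 4, 4))
  expected <- mean(c(oracle_horn(m[, 1], m[, 2]),
                     oracle_horn(m[, 1], m[, 3]),
                     oracle_horn(m[, 2], m[, 3])))
  expect_equal(niche_overlap(m, "HL"), expected)
})

test_that("mean shared partners counts overlap per pair", {
  expect_equal(mean_shared_partners(diag(3), "HL"), 0)
  ident <- cbind(c(1, 1, 1, 0), c(1, 1, 1, 0))
  expect_equal(mean_shared_partners(ident, "HL"), 3)
  set.seed(12)
  for (i in 1:25) {
    b <- matrix(rbinom(20, 1, 0.5), 4, 5)
    expect_equal(mean_shared_partners(b, "HL"), oracle_shared(b, "HL"))
    expect_equal(mean_shared_partners(b, "LL"), oracle_shared(b, "LL"))
  }
})

test_that("the network report carries the full index battery under report names", {
  set.seed(13)
  sim <- gen_matrix(community_spec(6, 9, "random", p = 0.5, seed = 13))
  rep1 <- network_report(sim$matrix)
  expect_named(rep1, c("Connectance", "Web asymmetry", "Links per taxa",
                       "NODF", "Weighted NODF", "Linkage density",
                       "Weighted connectance", "H2", "Number.of.taxa.HL",
                       "Number.of.taxa.LL",
                       "Mean.number.of.shared.partners.HL",
                       "Mean.number.of.shared.partners.LL",
                       "Niche.overlap.HL", "Niche.overlap.LL",
                       "C.score.HL", "C.score.LL"))
  expect_equal(rep1$Number.of.taxa.LL, nrow(sim$matrix))
  expect_true(all(is.finite(unlist(rep1))))
})

test_that("network indices are invariant to node relabeling and count rescaling", {
  set.seed(14)
  sim <- gen_matrix(community_spec(6, 8, "random", p = 0.5, seed = 14))
  m <- sim$matrix
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  rep_m <- unlist(network_report(m))
  rep_p <- unlist(network_report(perm))
  expect_equal(rep_p, rep_m)
  # scale invariance of the proportion-based indices
  for (f in list(h2prime, function(x) niche_overlap(x, "HL"),
                 function(x) niche_overlap(x, "LL"), wnodf)) {
    expect_equal(f(m * 7), f(m))
  }
})

test_that("index ranges hold across random communities", {
  set.seed(15)
  for (i in 1:20) {
    sim <- gen_matrix(community_spec(sample(3:7, 1), sample(3:7, 1),
                                     "random", p = 0.6, seed = i))
    m <- sim$matrix
    if (nrow(m) < 2 || ncol(m) < 2) next
    expect_gt(connectance(m), 0)
    expect_lte(connectance(m), 1)
    expect_true(abs(web_asymmetry(m)) < 1)
    expect_true(nodf(m) >= 0 && nodf(m) <= 100)
    expect_true(wnodf(m) >= 0 && wnodf(m) <= 100)
    expect_true(h2prime(m) >= 0 && h2prime(m) <= 1)
    expect_true(c_score(m, "HL") >= 0 && c_score(m, "HL") <= 1)
    no <- niche_overlap(m, "HL")
    expect_true(no >= -1e-12 && no <= 1 + 1e-12)
  }
})
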
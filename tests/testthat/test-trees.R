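test_that("Ward merges match an exhaustive Lance-Williams oracle", {
  set.seed(31)
  for (rep in 1:4) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- runif(6, 0.1, 1)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:4], letters[1:4])
    d <- dist_matrix(m, "gower")
    hc <- ward_tree(d)
    oracle <- oracle_ward_d2(unclass(d))
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    got <- lapply(seq_len(nrow(hc$merge)), function(i) sort(hc$merge[i, ]))
    expect_equal(got, oracle$merges)
  }
})

test_that("a 3-leaf matrix merges its closest pair first", {
  m <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- ward_tree(dist_matrix(m, "gower"))
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  expect_error(ward_tree(dist_matrix(m[1:2, 1:2], "gower")), "at least 3")
})

test_that("Ward trees are invariant to label order", {
  set.seed(32)
  d <- random_dist_matrix(8)
  perm <- sample(rownames(d))
  h1 <- ward_tree(d)
  h2 <- ward_tree(dist_subset(d, perm))
  c1 <- palaeotax:::.clade_sets(h1)
  c2 <- palaeotax:::.clade_sets(h2)
  expect_setequal(vapply(c1, paste, "", collapse = "|"),
                  vapply(c2, paste, "", collapse = "|"))
})

test_that("two-block data earns full support; weak branches collapse", {
  set.seed(33)
  block <- function(base, n) {
    t(replicate(n, base))
  }
  vals <- rbind(block(c(rep(1L, 10), rep(0L, 10)), 3),
                block(c(rep(0L, 10), rep(1L, 10)), 3))
  rownames(vals) <- c("A", "B", "C", "D", "E", "F")
  colnames(vals) <- paste0("t", 1:20)
  tm <- tiny_traits(vals)
  ct <- bootstrap_consensus(tm, n_boot = 100L, threshold = 50, seed = 1)
  n_tip <- length(ct$full_tree$tip.label)
  blocks <- palaeotax:::.clade_sets(ct$full_tree)
  keys <- vapply(blocks, paste, "", collapse = "|")
  sup <- ct$supports
  # the two perfectly separated blocks have 100% support
  for (b in c("A|B|C", "D|E|F")) {
    nd <- which(vapply(seq_along(sup), function(i) {
      tips <- sort(ct$full_tree$tip.label[
        palaeotax:::.tips_under(ct$full_tree, i + n_tip)])
      paste(tips, collapse = "|") == b
    }, logical(1)))
    expect_length(nd, 1L)
    expect_equal(sup[nd], 100)
  }
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("consensus edge sets are monotone in the collapse threshold", {
  ds <- simulate_dataset(small_generator(seed = 12, noise_flip_rate = 0.25))
  c50 <- bootstrap_consensus(ds$tools, n_boot = 60L, threshold = 50,
                             seed = 2)
  c90 <- bootstrap_consensus(ds$tools, n_boot = 60L, threshold = 90,
                             seed = 2)
  # identical replicates (same seed), different collapse thresholds
  expect_identical(c50$supports, c90$supports)
  e50 <- vapply(palaeotax:::.clade_sets(c50$tree), paste, "",
                collapse = "|")
  e90 <- vapply(palaeotax:::.clade_sets(c90$tree), paste, "",
                collapse = "|")
  expect_true(all(e90 %in% e50))
})

test_that("pure-noise columns leave few supported branches", {
  retained <- vapply(1:5, function(s) {
    set.seed(400 + s)
    vals <- matrix(rbinom(20 * 30, 1L, 0.5), 20,
                   dimnames = list(sprintf("n%02d", 1:20), NULL))
    colnames(vals) <- paste0("t", 1:30)
    ct <- bootstrap_consensus(tiny_traits(vals), n_boot = 80L,
                              threshold = 50, seed = s)
    # internal edges excluding the root, after collapsing
    length(palaeotax:::.clade_sets(ct$tree)) / (20 - 2)
  }, numeric(1))
  expect_lt(mean(retained), 0.25)
})

test_that("stratified subsampling keeps at most per_nac outlines per NAC", {
  nacs <- c(rep("A", 30), rep("B", 2), "C")
  idx <- stratified_subsample(nacs, per_nac = 2L, seed = 1)
  expect_identical(as.integer(table(nacs[idx])), c(2L, 2L, 1L))
  ds <- simulate_dataset(small_generator(seed = 13))
  sub <- stratified_subsample(ds$outlines, per_nac = 2L, seed = 2)
  tab <- table(outline_meta(sub)$nac_id)
  expect_true(all(tab <= 2))
  full_tab <- table(outline_meta(ds$outlines)$nac_id)
  expect_equal(sum(pmin(full_tab, 2)), sum(tab))
  expect_error(stratified_subsample(character(0)), "empty")
  expect_error(stratified_subsample(ds$outlines, per_nac = 0L), "per_nac")
})

test_that("tanglegrams of identical trees share everything and never tangle", {
  set.seed(34)
  d <- random_dist_matrix(10)
  hc <- ward_tree(d)
  cmp <- tanglegram_compare(hc, hc)
  expect_equal(cmp$entanglement, 0)
  expect_identical(length(cmp$shared_clades),
                   length(palaeotax:::.clade_sets(hc)))
  hc2 <- ward_tree(random_dist_matrix(10, sprintf("x%02d", 1:10)))
  expect_error(tanglegram_compare(hc, hc2), "leaf sets differ")
})

test_that("random trees share almost no clades; planted trees share them all", {
  set.seed(35)
  shared <- vapply(1:20, function(i) {
    a <- ward_tree(random_dist_matrix(20))
    b <- ward_tree(random_dist_matrix(20))
    length(tanglegram_compare(a, b)$shared_clades)
  }, numeric(1))
  expect_lte(stats::median(shared), 2)
  # same planted macro-units, no trait noise: all unit clades recovered in
  # both domains
  ds <- simulate_dataset(generator_config(seed = 14, noise_flip_rate = 0,
                                          missing_rate = 0))
  cmp <- tanglegram_compare(ward_tree(gower_distance(ds$tools)),
                            ward_tree(gower_distance(ds$technology)))
  keys <- vapply(cmp$shared_clades, paste, "", collapse = "\r")
  for (u in setdiff(macro_unit_levels(), "unassigned")) {
    planted <- sort(ds$nacs$nac_id[ds$nacs$macro_unit == u])
    expect_true(paste(planted, collapse = "\r") %in% keys)
  }
  expect_identical(
    length(tanglegram_compare(ward_tree(gower_distance(ds$tools)),
                              ward_tree(gower_distance(ds$technology)))$shared_clades),
    length(cmp$shared_clades))
})
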
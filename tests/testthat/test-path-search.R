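# The backtracking engine: heuristic test, k-path enumeration, exact
# distance, minimal paths, topology contrast and cut detection.

toy_a <- function() parse_genome("1 -2 -3 -5 -4")
toy_b <- function() parse_genome("1 2 3 4 5")

test_that("the heuristic test answers YES / NO / INDETERMINATE correctly", {
  a <- toy_a(); b <- toy_b()
  expect_identical(heuristic_test(b, b, 2, 2), "YES")
  expect_identical(heuristic_test(b, b, 1, 3), "NO")    # early arrival
  expect_identical(heuristic_test(a, b, 2, 2), "NO")    # budget spent
  # nb_breakpoints = 4 > 3 * 1
  expect_identical(heuristic_test(a, b, 0, 1), "NO")
  expect_identical(heuristic_test(a, b, 0, 2), "INDETERMINATE")
  expect_identical(heuristic_test(a, b, 0, 1, ht2 = FALSE), "INDETERMINATE")
})

test_that("k-path enumeration is complete on the toy pair", {
  a <- toy_a(); b <- toy_b()
  # trivial 0-path
  p0 <- enumerate_k_paths(b, b, 0)
  expect_length(p0, 1L)
  expect_length(p0[[1]], 1L)
  # no single rearrangement links the pair
  expect_length(enumerate_k_paths(a, b, 1), 0L)
  expect_false(canonical_key(b) %in%
                 vapply(enumerate_neighbors(a), canonical_key, character(1)))
  # the printed 2-path plus seven others
  p2 <- enumerate_k_paths(a, b, 2, ht1 = FALSE)
  expect_length(p2, 8L)
  mids <- vapply(p2, function(p) canonical_key(p[[2]]), character(1))
  expect_true(canonical_key(parse_genome("1 -2 -3 4 5")) %in% mids)
  # each consecutive pair really is one rearrangement apart
  for (p in p2[1:3]) expect_true(path_is_valid(p))
  # reversal of a path is a path
  expect_true(path_is_valid(rev(p2[[1]])))
})

test_that("distance is exact and reports failure beyond k_max", {
  a <- toy_a(); b <- toy_b()
  expect_equal(genome_distance(b, b), 0L)
  expect_equal(genome_distance(a, b), 2L)
  expect_equal(genome_distance(a, b, k_max = 4L), 2L)
  expect_true(is.na(genome_distance(a, b, k_max = 1L)))
  expect_equal(attr(genome_distance(a, b, k_max = 1L), "k_max"), 1L)
})

test_that("the linear reading of the toy pair behaves differently", {
  al <- parse_genome("1 -2 -3 -5 -4", "linear")
  bl <- parse_genome("1 2 3 4 5", "linear")
  expect_equal(genome_distance(al, bl), 3L)
  # the printed 3-step scenario is a valid linear path ...
  printed <- list(al,
                  parse_genome("1 -2 5 3 -4", "linear"),
                  parse_genome("1 4 -3 -2 5", "linear"),
                  bl)
  expect_true(path_is_valid(printed))
  # ... and it cuts the block [-5 -4] shared by its endpoints
  expect_true(1L %in% path_cuts(printed))
  # while circular minimal paths exist without cuts
  circ <- enumerate_minimal_paths(toy_a(), toy_b())
  cutfree <- vapply(circ, function(p) length(path_cuts(p)) == 0L, logical(1))
  expect_true(any(cutfree))
})

test_that("a one-step pair has exactly one minimal path", {
  set.seed(3)
  g <- rand_genome_int(5)
  h <- enumerate_neighbors(g)[[4]]
  expect_equal(genome_distance(g, h), 1L)
  expect_length(enumerate_minimal_paths(g, h), 1L)
})

test_that("distance agrees with the breadth-first oracle", {
  # one full BFS sweep from the identity reaches every class; by relabeling
  # symmetry this covers all pairs -- exhaustive at n = 4, sampled at n = 5
  id4 <- parse_genome("1 2 3 4")
  omap4 <- oracle_bfs_all(id4)
  expect_setequal(names(omap4), all_signed_classes(4))
  for (key in names(omap4)) {
    expect_identical(genome_distance(id4, parse_genome(key)),
                     unname(omap4[key]))
  }
  id5 <- parse_genome("1 2 3 4 5")
  omap5 <- oracle_bfs_all(id5)
  set.seed(41)
  for (key in sample(names(omap5), 25)) {
    expect_identical(genome_distance(id5, parse_genome(key)),
                     unname(omap5[key]))
  }
})

test_that("the pruning tests change the work, never the distance", {
  # by relabeling symmetry, pairs (identity, G) cover all pairs: exhaustive
  # over all classes for n = 3 and 4, sampled for n = 5
  flag_sets <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                    c(FALSE, FALSE))
  for (n in 3:4) {
    id <- parse_genome(paste(seq_len(n), collapse = " "))
    for (key in all_signed_classes(n)) {
      g <- parse_genome(key)
      ds <- vapply(flag_sets, function(f)
        genome_distance(id, g, k_max = 6L, ht1 = f[1], ht2 = f[2]),
        integer(1))
      expect_length(unique(ds), 1L)
    }
  }
  set.seed(53)
  id5 <- parse_genome("1 2 3 4 5")
  for (i in 1:8) {
    g <- rand_genome_int(5)
    ds <- vapply(flag_sets, function(f)
      genome_distance(id5, g, k_max = 6L, ht1 = f[1], ht2 = f[2]),
      integer(1))
    expect_length(unique(ds), 1L)
  }
})

test_that("distance is a metric and obeys the breakpoint lower bound", {
  set.seed(59)
  for (i in 1:15) {
    n <- sample(5:6, 1)
    x <- rand_genome_int(n); y <- rand_genome_int(n); z <- rand_genome_int(n)
    dxy <- genome_distance(x, y); dyx <- genome_distance(y, x)
    dxz <- genome_distance(x, z); dyz <- genome_distance(y, z)
    expect_identical(dxy, dyx)
    expect_identical(dxy == 0L, genomes_equal(x, y))
    expect_lte(dxz, dxy + dyz)
    expect_gte(3L * dxy, nb_breakpoints(x, y))
  }
})

test_that("neighbors are exactly the genomes at distance one", {
  set.seed(61)
  g <- rand_genome_int(5)
  nb_keys <- vapply(enumerate_neighbors(g), canonical_key, character(1))
  for (key in nb_keys[seq(1, length(nb_keys), by = 11)]) {
    expect_equal(genome_distance(g, parse_genome(key)), 1L)
  }
  # and a genome at distance 2 is not a neighbor
  p <- enumerate_k_paths(g, parse_genome(nb_keys[1]), 1)[[1]]
  two_away <- enumerate_neighbors(p[[2]])[[1]]
  if (!canonical_key(two_away) %in% c(nb_keys, canonical_key(g))) {
    expect_gte(genome_distance(g, two_away), 2L)
  }
})
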
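# The three elementary rearrangements, equivalence-class deduplication,
# breakpoints and shared blocks.

test_that("circularity makes distinct operation parameters equivalent", {
  g <- parse_genome("A B C")
  # three transpositions, one resulting gene order (circular [B A C])
  t1 <- apply_rearrangement(g, "transposition", 2, 1, insert_after = 3)  # B after C
  t2 <- apply_rearrangement(g, "transposition", 1, 1, insert_after = 2)  # A after B
  t3 <- apply_rearrangement(g, "transposition", 3, 1, insert_after = 1)  # C after A
  expect_true(genomes_equal(t1, parse_genome("B A C")))
  expect_true(genomes_equal(t1, t2))
  expect_true(genomes_equal(t2, t3))

  # two inversions of [A B], one resulting gene order ([-A B] = [A -B])
  ab <- parse_genome("A B")
  i1 <- apply_rearrangement(ab, "inversion", 1, 1)
  i2 <- apply_rearrangement(ab, "inversion", 2, 1)
  expect_true(genomes_equal(i1, parse_genome("-A B")))
  expect_true(genomes_equal(i1, i2))

  # the same with multi-gene blocks
  g4 <- parse_genome("a1 a2 b1")
  j1 <- apply_rearrangement(g4, "inversion", 1, 2)   # invert [a1 a2]
  j2 <- apply_rearrangement(g4, "inversion", 3, 1)   # invert [b1]
  expect_true(genomes_equal(j1, j2))
})

test_that("inversion is an involution and bad parameters error", {
  g <- parse_genome("1 -2 3 4 5")
  h <- apply_rearrangement(g, "inversion", 2, 3)
  expect_false(genomes_equal(g, h))
  expect_true(genomes_equal(apply_rearrangement(h, "inversion", 2, 3), g))

  expect_error(apply_rearrangement(g, "inversion", 1, 5), "block_length")
  expect_error(apply_rearrangement(g, "transposition", 1, 2,
                                   insert_after = 2), "inside")
  expect_error(apply_rearrangement(g, "transposition", 2, 2,
                                   insert_after = 1), "original position")
  expect_error(apply_rearrangement(g, "reverse_transposition", 2, 2,
                                   insert_after = 1), "original position")
})

test_that("neighbor enumeration equals the brute-force oracle", {
  # exhaustive over all classes for n = 3 and n = 4
  for (n in 3:4) {
    for (key in all_signed_classes(n)) {
      g <- parse_genome(key)
      mine <- vapply(enumerate_neighbors(g), canonical_key, character(1))
      expect_false(anyDuplicated(mine) > 0)
      expect_setequal(mine, brute_force_neighbors(g))
    }
  }
  # random spot checks at n = 5
  set.seed(31)
  for (i in 1:5) {
    g <- rand_genome_int(5)
    mine <- vapply(enumerate_neighbors(g), canonical_key, character(1))
    expect_false(anyDuplicated(mine) > 0)
    expect_setequal(mine, brute_force_neighbors(g))
  }
})

test_that("neighborhood is symmetric and excludes the genome itself", {
  set.seed(13)
  for (n in 3:5) {
    g <- rand_genome_int(n)
    gkey <- canonical_key(g)
    nbs <- enumerate_neighbors(g)
    expect_false(gkey %in% vapply(nbs, canonical_key, character(1)))
    for (h in nbs[seq_len(min(4, length(nbs)))]) {
      back <- vapply(enumerate_neighbors(h), canonical_key, character(1))
      expect_true(gkey %in% back)
    }
  }
})

test_that("breakpoint counts match the adjacency definition", {
  a <- parse_genome("1 2 3 4 5")
  b <- parse_genome("1 -2 -3 -5 -4")
  expect_equal(nb_breakpoints(a, a), 0L)
  expect_equal(nb_breakpoints(a, b), 4L)
  expect_equal(nb_breakpoints(b, a), 4L)
  set.seed(17)
  for (i in 1:20) {
    x <- rand_genome_int(6); y <- rand_genome_int(6)
    expect_identical(nb_breakpoints(x, y), nb_breakpoints(y, x))
  }
  expect_error(nb_breakpoints(parse_genome("1 2 3"), parse_genome("1 2 4")),
               "same genes")
})

test_that("one rearrangement creates at most three breakpoints", {
  set.seed(23)
  for (n in c(4L, 6L)) {
    g <- rand_genome_int(n)
    for (h in enumerate_neighbors(g)) {
      expect_lte(nb_breakpoints(g, h), 3L)
      expect_gte(nb_breakpoints(g, h), 1L)
    }
  }
})

test_that("shared blocks are found up to inversion", {
  a <- parse_genome("1 2 3 4 5")
  b <- parse_genome("1 -2 -3 -5 -4")
  blocks <- shared_blocks(a, b)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]], c("4", "5"))  # present in b as [-5 -4]

  expect_error(shared_blocks(a, parse_genome("3 4 5 1 2")), "equal")

  # a single transposition leaves the moved block shared
  g <- parse_genome("1 2 3 4 5 6")
  h <- apply_rearrangement(g, "transposition", 2, 2, insert_after = 5)
  blocks <- shared_blocks(g, h)
  expect_true(any(vapply(blocks, function(bl)
    identical(bl, c("2", "3")), logical(1))))
})
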
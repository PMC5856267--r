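# Representation layer: parsing, the 2n-representation rule, canonical keys
# and gene-content reduction.

test_that("parsing accepts signed token strings and rejects bad input", {
  g <- parse_genome(paste("cox1 cox2 atp8 atp6 cox3 nad3 nad4L nad4 nad5",
                          "-nad6 cob rrnS rrnL nad1 nad2"))
  expect_equal(genome_size(g), 15L)
  expect_equal(g$labels[10], "nad6")
  expect_equal(g$signs[10], -1L)
  expect_identical(g$topology, "circular")

  g2 <- parse_genome("1 2 -3")
  expect_equal(g2$signs, c(1L, 1L, -1L))

  expect_error(parse_genome("1 2 2"), "duplicate")
  expect_error(parse_genome("   "), "empty")
  expect_error(parse_genome("1 2 --3"), "unparsable")
  expect_error(parse_genome("solo"), "at least 2")
})

test_that("a circular genome has exactly its 2n representations", {
  g <- parse_genome("1 2 -3")
  reps <- vapply(representations(g), paste, character(1), collapse = " ")
  expect_setequal(reps, c("1 2 -3", "2 -3 1", "-3 1 2",
                          "-1 3 -2", "3 -2 -1", "-2 -1 3"))
  for (n in 3:6) {
    r <- rand_genome_int(n)
    reps <- vapply(representations(r), paste, character(1), collapse = " ")
    expect_length(unique(reps), 2L * n)
    expect_setequal(reps, oracle_representations(r))
  }
  lin <- parse_genome("1 -2 3", "linear")
  reps <- vapply(representations(lin), paste, character(1), collapse = " ")
  expect_setequal(reps, c("1 -2 3", "-3 2 -1"))
})

test_that("genomes_equal matches the representation-set definition", {
  expect_true(genomes_equal(parse_genome("1 2 -3"), parse_genome("-1 3 -2")))
  expect_true(genomes_equal(parse_genome("1 2 -3"), parse_genome("1 2 -3")))
  expect_false(genomes_equal(parse_genome("1 2 3"), parse_genome("1 2 -3")))
  expect_false(genomes_equal(parse_genome("1 2 3"), parse_genome("1 2 4")))
  set.seed(101)
  for (i in 1:40) {
    a <- rand_genome_int(4)
    b <- rand_genome_int(4)
    expect_identical(genomes_equal(a, b), oracle_equal(a, b))
    # symmetry and reflexivity
    expect_identical(genomes_equal(a, b), genomes_equal(b, a))
    expect_true(genomes_equal(a, a))
  }
})

test_that("canonical_key is constant on classes and separates them", {
  expect_identical(canonical_key(parse_genome("1 2 -3")),
                   canonical_key(parse_genome("2 -3 1")))
  g <- parse_genome("2 -4 1 -3")
  key_tokens <- strsplit(canonical_key(g), " ")[[1]]
  reps <- vapply(representations(g), paste, character(1), collapse = " ")
  expect_true(paste(key_tokens, collapse = " ") %in% reps)
  # exhaustive for n = 3: keys partition all signed permutations into the
  # expected 2^n n! / 2n classes
  expect_length(all_signed_classes(3), 8L)
  expect_length(all_signed_classes(4), 48L)
  set.seed(7)
  for (i in 1:30) {
    a <- rand_genome_int(4); b <- rand_genome_int(4)
    expect_identical(canonical_key(a) == canonical_key(b),
                     oracle_equal(a, b))
  }
})

test_that("restrict_to_common keeps order and reports removals", {
  r <- restrict_to_common(parse_genome("1 2 3 4"), parse_genome("1 3 2"))
  expect_equal(genome_tokens(r$a), c("1", "2", "3"))
  expect_equal(genome_tokens(r$b), c("1", "3", "2"))
  expect_equal(r$removed_from_a, "4")
  expect_length(r$removed_from_b, 0L)

  same <- restrict_to_common(parse_genome("1 2 3"), parse_genome("3 1 2"))
  expect_length(same$removed_from_a, 0L)
  expect_length(same$removed_from_b, 0L)

  # orientation is preserved and matching ignores sign
  r2 <- restrict_to_common(parse_genome("1 -2 3 4"), parse_genome("2 1 3"))
  expect_equal(genome_tokens(r2$a), c("1", "-2", "3"))

  expect_error(restrict_to_common(parse_genome("1 2 3"),
                                  parse_genome("4 5 6")),
               "fewer than 3")
})

test_that("the CLR anchors at cox1 in + orientation", {
  hs <- homo_sapiens_gene_order()
  expect_equal(clr(hs)[1], "cox1")
  # rotate and flip: the CLR is unchanged
  rot <- parse_genome(paste(genome_tokens(hs)[c(8:15, 1:7)], collapse = " "))
  expect_equal(clr(rot), clr(hs))
  neg <- parse_genome(rev(ifelse(hs$signs < 0, hs$labels,
                                 paste0("-", hs$labels))))
  expect_equal(clr(neg), clr(hs))
})
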
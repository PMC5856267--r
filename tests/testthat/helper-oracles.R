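# Independent oracles used to cross-check the search engine.  Everything
# here is deliberately naive: plain R, brute force, no pruning.

rand_genome_int <- function(n) {
  parse_genome(paste(sample(n) * sample(c(-1L, 1L), n, TRUE)))
}

# representation set computed directly from the definition
oracle_representations <- function(g) {
  tok <- genome_tokens(g)
  n <- length(tok)
  neg <- function(t) ifelse(startsWith(t, "-"), sub("^-", "", t),
                            paste0("-", t))
  refl <- rev(neg(tok))
  reps <- list()
  if (g$topology == "linear") {
    reps <- list(tok, refl)
  } else {
    for (s in seq_len(n)) {
      rot <- c(seq(s, n), seq_len(s - 1L))
      reps[[length(reps) + 1L]] <- tok[rot]
      reps[[length(reps) + 1L]] <- refl[rot]
    }
  }
  unique(vapply(reps, paste, character(1), collapse = " "))
}

oracle_equal <- function(a, b) {
  paste(genome_tokens(b), collapse = " ") %in% oracle_representations(a)
}

# every parameterisation of the three rearrangements, applied one by one
# through apply_rearrangement(), deduplicated by representation set
brute_force_neighbors <- function(g) {
  n <- genome_size(g)
  circ <- g$topology == "circular"
  out <- character(0)
  starts <- seq_len(n)
  for (bs in starts) {
    max_len <- if (circ) n - 1L else n - bs + 1L
    for (bl in seq_len(max_len)) {
      if (!circ && bs == 1L && bl == n) next  # whole genome is not a block
      if (circ && bl > n - 1L) next
      h <- apply_rearrangement(g, "inversion", bs, bl)
      out <- c(out, canonical_key(h))
      inserts <- if (circ) setdiff(seq_len(n),
                                   ((bs - 1L + seq_len(bl) - 1L) %% n) + 1L)
                 else setdiff(0:n, seq(bs, bs + bl - 1L))
      for (ia in inserts) {
        for (kind in c("transposition", "reverse_transposition")) {
          h <- tryCatch(apply_rearrangement(g, kind, bs, bl, ia),
                        error = function(e) NULL)
          if (!is.null(h)) out <- c(out, canonical_key(h))
        }
      }
    }
  }
  sort(setdiff(unique(out), canonical_key(g)))
}

# breadth-first sweep over canonical keys from `a` using the brute-force
# neighbor oracle: named integer vector of exact distances to every
# reachable class
oracle_bfs_all <- function(a) {
  dist <- setNames(0L, canonical_key(a))
  frontier <- list(a)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (g in frontier) {
      for (key in brute_force_neighbors(g)) {
        if (key %in% names(dist)) next
        dist[key] <- d
        nxt[[length(nxt) + 1L]] <- parse_genome(key, a$topology)
      }
    }
    frontier <- nxt
  }
  dist
}

# all equivalence classes of signed circular genomes on 1..n
all_signed_classes <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  keys <- character(0)
  for (p in perms(seq_len(n))) {
    for (r in seq_len(nrow(signs))) {
      keys <- c(keys, canonical_key(parse_genome(paste(p * signs[r, ]))))
    }
  }
  sort(unique(keys))
}

# Three 6-gene orders, pairwise at distance 2, whose 2-path midpoints share
# no common genome: the smallest star tree around one HTU violates P6.
# Found by seeded random search; the conflict itself is re-verified where
# the trio is used.
p6_conflict_trio <- function() {
  list(A = parse_genome("-g3 g2 -g1 g6 -g5 -g4"),
       B = parse_genome("-g5 -g4 g2 g1 g6 g3"),
       C = parse_genome("-g5 g2 g3 g1 -g4 g6"))
}

# independent tree generator: all edge subsets of size V-1 that form a
# tree, filtered by the axioms and deduplicated by exhaustive HTU
# permutation; returns the smallest admissible V and the class count
oracle_trees <- function(d, pphs = list(), root = NULL, max_htus = 4L) {
  taxa <- rownames(d)
  N <- length(taxa)
  for (M in 0:max_htus) {
    V <- N + M
    if (V < 2L) next
    all_edges <- t(combn(V, 2))
    sigs <- character(0)
    count <- 0L
    for (pick in combn(nrow(all_edges), V - 1L, simplify = FALSE)) {
      e <- all_edges[pick, , drop = FALSE]
      tr <- generearr:::new_ptree(e, taxa, V)
      chk <- verify_tree_properties(tr, d, pphs, root)
      if (!chk$ok) next
      deg <- tabulate(tr$edges, V)
      if (M > 0L && any(deg[(N + 1L):V] == 1L)) next
      perms <- if (M <= 1L) list(seq_len(M)) else combinat_perms(M)
      best <- NULL
      for (p in perms) {
        relab <- c(seq_len(N), N + p)
        ee <- cbind(relab[e[, 1]], relab[e[, 2]])
        key <- paste(sort(paste(pmin(ee[, 1], ee[, 2]),
                                pmax(ee[, 1], ee[, 2]))), collapse = ";")
        if (is.null(best) || key < best) best <- key
      }
      if (best %in% sigs) next
      sigs <- c(sigs, best)
      count <- count + 1L
    }
    if (count > 0L) return(list(V = V, count = count))
  }
  NULL
}

combinat_perms <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(m - 1L))
    for (i in 0:(m - 1L))
      out[[length(out) + 1L]] <- append(p, m, after = i)
  out
}

path_is_valid <- function(path) {
  all(vapply(seq_len(length(path) - 1L), function(i) {
    keys <- vapply(enumerate_neighbors(path[[i]]), canonical_key,
                   character(1))
    canonical_key(path[[i + 1L]],
                  order = gene_order_of(path[[i]]$labels)) %in% keys
  }, logical(1)))
}
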
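# Ancestral gene-order inference (property P6): enumerate every gene order
# an HTU can take, given that all rearrangement scenarios between the OTUs
# around it must pass through it, and reject trees whose HTUs admit none.

#' OTU pairs that constrain the HTUs of a tree
#'
#' The gene order of an HTU is pinned down by the OTU pairs whose connecting
#' tree path runs only through HTUs: every scenario of exactly that many
#' steps between the two observed genomes must place some genome at each
#' intermediate node.  Pairs whose path crosses another OTU impose nothing
#' extra (the crossing OTU splits the constraint).
#'
#' @param tree A `ptree`.
#' @return List of entries `list(a, b, k, path)`: the two OTU names, the path
#'   length in edges, and the node indices along the path.
#' @export
constraining_pairs <- function(tree) {
  adj <- adjacency_list(tree)
  N <- tree$n_otu
  out <- list()
  tree_path <- function(from, to) {
    # BFS parents
    parent <- rep.int(0L, tree$V)
    seen <- logical(tree$V); seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == to) break
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      }
    }
    path <- to
    while (path[1L] != from) path <- c(parent[path[1L]], path)
    path
  }
  if (N < 2L) return(out)
  for (i in seq_len(N - 1L)) {
    for (j in seq(i + 1L, N)) {
      p <- tree_path(i, j)
      mid <- p[-c(1L, length(p))]
      if (any(mid <= N)) next  # an OTU interrupts the path
      out[[length(out) + 1L]] <-
        list(a = tree$labels[i], b = tree$labels[j],
             k = length(p) - 1L, path = p)
    }
  }
  out
}

#' Candidate gene orders for every HTU of a tree
#'
#' For each constraining OTU pair the complete set of paths of exactly the
#' tree-path length is enumerated (shared-block pruning disabled, so nothing
#' is missed), and the genomes occurring at an HTU's position are collected.
#' An HTU covered by several pairs keeps the intersection of those sets; an
#' HTU whose covering pairs all run through one common pendant OTU sits on
#' that terminal branch, and every order seen along the branch's paths
#' remains possible (union).
#'
#' @param tree A `ptree` (validated against P1-P5).
#' @param genomes Named list of `genome` objects for the OTUs, all over the
#'   same gene set.
#' @param k_max Guard for the per-pair path enumeration (a constraining pair
#'   whose tree path is longer than this is an error).
#' @return An `htu_assignment`: list with `candidates` (per-HTU list of
#'   canonical gene-order strings), `pair_sets` (per-pair, per-HTU sets),
#'   `pairs` (the constraining pairs), and `failed` (first HTU with an empty
#'   candidate set, or `NA`).
#' @export
candidate_orders <- function(tree, genomes, k_max = 8L) {
  stopifnot(inherits(tree, "ptree"))
  otus <- tree$labels[seq_len(tree$n_otu)]
  if (!all(otus %in% names(genomes)))
    stop("genomes missing for: ",
         paste(setdiff(otus, names(genomes)), collapse = ", "))
  base <- genomes[[otus[1L]]]
  for (nm in otus)
    if (!setequal(genomes[[nm]]$labels, base$labels))
      stop("ancestral inference needs all genomes on one common gene set")
  ord <- gene_order_of(base$labels)

  pairs <- constraining_pairs(tree)
  htus <- if (tree$V > tree$n_otu) seq(tree$n_otu + 1L, tree$V) else integer(0)
  pair_sets <- vector("list", length(pairs))
  deg <- tabulate(tree$edges, tree$V)

  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    if (pr$k > k_max)
      stop("tree path between ", pr$a, " and ", pr$b, " needs ", pr$k,
           " steps > k_max = ", k_max)
    paths <- enumerate_k_paths(genomes[[pr$a]], genomes[[pr$b]], pr$k,
                               ht1 = FALSE, ht2 = TRUE, order = ord)
    sets <- list()
    if (length(paths)) {
      inner <- seq_along(pr$path)[-c(1L, length(pr$path))]
      for (pos in inner) {
        node <- pr$path[pos]
        keys <- unique(vapply(paths, function(p)
          canonical_key(p[[pos]], order = ord), character(1)))
        sets[[as.character(node)]] <- keys
      }
    }
    pair_sets[[pi]] <- sets
  }

  candidates <- list()
  failed <- NA_integer_
  for (h in htus) {
    covering <- which(vapply(pairs, function(pr) h %in% pr$path, logical(1)))
    if (length(covering) == 0L) {
      candidates[[tree$labels[h]]] <- character(0)
      next
    }
    # no k-path at all for a covering pair: the tree cannot be realised
    empty_pair <- covering[vapply(covering, function(pi)
      length(pair_sets[[pi]]) == 0L, logical(1))]
    if (length(empty_pair)) {
      candidates[[tree$labels[h]]] <- character(0)
      if (is.na(failed)) failed <- h
      next
    }
    ends <- unlist(lapply(pairs[covering], function(pr) c(pr$a, pr$b)))
    common_otu <- names(which(table(ends) == length(covering)))
    pendant <- any(vapply(common_otu, function(nm)
      deg[match(nm, tree$labels)] == 1L, logical(1)))
    sets <- lapply(covering, function(pi) pair_sets[[pi]][[as.character(h)]])
    keys <- if (length(covering) > 1L && pendant) {
      # terminal branch: all orders along the branch remain possible
      sort(unique(unlist(sets)))
    } else {
      sort(Reduce(intersect, sets))
    }
    candidates[[tree$labels[h]]] <- keys
    if (length(keys) == 0L && is.na(failed)) failed <- h
  }

  structure(list(candidates = candidates, pair_sets = pair_sets,
                 pairs = pairs, failed = failed, gene_order = ord),
            class = "htu_assignment")
}

#' @export
print.htu_assignment <- function(x, ...) {
  if (length(x$candidates) == 0L) {
    cat("No HTUs: assignment trivially valid\n")
    return(invisible(x))
  }
  for (nm in names(x$candidates)) {
    ks <- x$candidates[[nm]]
    cat(nm, ": ", length(ks), " possible gene order(s)\n", sep = "")
    for (k in ks) cat("   [", k, "]\n", sep = "")
  }
  invisible(x)
}

#' Validate a tree's ancestors (property P6)
#'
#' A candidate tree is a genuine solution only if every HTU admits at least
#' one gene order consistent with all minimal scenarios passing through it.
#' On failure the smallest conflicting neighbourhood is extracted: the
#' failing HTU with a minimal set of constraining paths whose position sets
#' cannot agree.  That fragment is returned as a forbidden subtree usable as
#' an exclusion constraint in the next round of tree enumeration.
#'
#' @inheritParams candidate_orders
#' @return List with `valid` (logical), `assignment` (the
#'   `htu_assignment`), and on failure `invalid_subtree` (a pattern for
#'   [enumerate_parsimonious_trees()]'s `exclusions`).
#' @export
validate_tree_ancestors <- function(tree, genomes, k_max = 8L) {
  asg <- candidate_orders(tree, genomes, k_max = k_max)
  if (is.na(asg$failed))
    return(list(valid = TRUE, assignment = asg, invalid_subtree = NULL))

  h <- asg$failed
  covering <- which(vapply(asg$pairs, function(pr) h %in% pr$path,
                           logical(1)))
  sets <- lapply(covering, function(pi) {
    s <- asg$pair_sets[[pi]][[as.character(h)]]
    if (is.null(s)) character(0) else s
  })
  # greedy minimisation: drop pairs (in order) while the conflict persists
  keep <- seq_along(covering)
  for (i in seq_along(covering)) {
    trial <- setdiff(keep, i)
    if (length(trial) == 0L) next
    if (length(Reduce(intersect, sets[trial])) == 0L) keep <- trial
  }
  nodes <- sort(unique(unlist(lapply(asg$pairs[covering[keep]],
                                     function(pr) pr$path))))
  relab <- match(seq_len(tree$V), nodes)
  edges <- do.call(rbind, lapply(asg$pairs[covering[keep]], function(pr) {
    p <- pr$path
    cbind(relab[p[-length(p)]], relab[p[-1L]])
  }))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  labels <- ifelse(nodes <= tree$n_otu, tree$labels[nodes], NA_character_)
  pattern <- new_tree_pattern(edges, labels)
  list(valid = FALSE, assignment = asg, invalid_subtree = pattern)
}
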
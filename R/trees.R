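# Complete enumeration of most-parsimonious trees under the tree axioms
# P1-P5: simple (P1), undirected (P2), a tree (P3), respecting the distance
# matrix (P4) and the monophyly constraints (P5).  Nodes are OTUs (observed
# taxa, which may sit at internal positions) or anonymous HTUs (hypothetical
# ancestors); each edge is one rearrangement step, so the most parsimonious
# tree is the one on the smallest node domain.

new_ptree <- function(edges, otu_labels, V) {
  N <- length(otu_labels)
  labels <- c(otu_labels,
              if (V > N) paste0("HTU#", seq_len(V - N)) else character(0))
  structure(list(V = as.integer(V), n_otu = as.integer(N),
                 labels = labels,
                 edges = matrix(as.integer(edges), ncol = 2L)),
            class = "ptree")
}

#' @export
print.ptree <- function(x, ...) {
  cat("Parsimony tree:", x$n_otu, "OTUs,", x$V - x$n_otu, "HTUs\n")
  e <- x$edges
  cat(paste0("  ", x$labels[e[, 1]], " -- ", x$labels[e[, 2]],
             collapse = "\n"), "\n")
  invisible(x)
}

adjacency_list <- function(tree) {
  adj <- vector("list", tree$V)
  for (r in seq_len(nrow(tree$edges))) {
    i <- tree$edges[r, 1]; j <- tree$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from node `from` to all nodes (unit edge lengths)
bfs_dist <- function(adj, from, V) {
  dist <- rep.int(NA_integer_, V)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist
}

# For each edge: the OTU labels on the side away from `root_node`.
# Rooted DFS; result is a list parallel to the edge rows.
edge_clades <- function(tree, root_node) {
  adj <- adjacency_list(tree)
  parent <- rep.int(0L, tree$V)
  ord <- integer(0)
  stack <- root_node
  seen <- logical(tree$V); seen[root_node] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w)
    }
  }
  below <- vector("list", tree$V)
  for (v in rev(ord)) {
    own <- if (v <= tree$n_otu) tree$labels[v] else character(0)
    kids <- which(parent == v)
    below[[v]] <- c(own, unlist(below[kids]))
  }
  lapply(seq_len(nrow(tree$edges)), function(r) {
    i <- tree$edges[r, 1]; j <- tree$edges[r, 2]
    child <- if (parent[j] == i) j else i
    sort(below[[child]])
  })
}

#' Test a clade for monophyly
#'
#' With a root taxon fixing the direction of reading, a set of OTUs is
#' monophyletic when removing some edge separates exactly that set (plus any
#' HTUs) from the root's side.
#'
#' @param tree A `ptree`.
#' @param root Name of the root OTU (not in `taxa`).
#' @param taxa Character vector of OTU names.
#' @return Logical.
#' @export
check_monophyly <- function(tree, root, taxa) {
  root_node <- match(root, tree$labels[seq_len(tree$n_otu)])
  if (is.na(root_node)) stop("root '", root, "' is not an OTU of the tree")
  if (root %in% taxa) stop("root must not belong to the clade tested")
  target <- sort(unique(taxa))
  any(vapply(edge_clades(tree, root_node),
             function(cl) identical(cl, target), logical(1)))
}

#' Verify the tree axioms P1-P5
#'
#' Checks, in order: the tree is simple (P1), undirected (P2), connected and
#' acyclic (P3), every leaf-to-leaf path is at least as long as the matrix
#' distance (P4), and all monophyly constraints hold (P5).
#'
#' @param tree A `ptree`.
#' @param dm A `rearr_dmat` (or plain named distance matrix) over the tree's
#'   OTUs.
#' @param pphs List of monophyly constraints, each a character vector of OTU
#'   names (optionally named).
#' @param root Root OTU name (required when `pphs` is non-empty).
#' @return List with `ok` (logical) and `failed` (first violated property or
#'   `NA`).
#' @export
verify_tree_properties <- function(tree, dm, pphs = list(), root = NULL) {
  d <- if (inherits(dm, "rearr_dmat")) dm$d else dm
  e <- tree$edges
  if (any(e[, 1] == e[, 2]))
    return(list(ok = FALSE, failed = "P1"))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(key))
    return(list(ok = FALSE, failed = "P2"))
  adj <- adjacency_list(tree)
  if (nrow(e) != tree$V - 1L || anyNA(bfs_dist(adj, 1L, tree$V)))
    return(list(ok = FALSE, failed = "P3"))
  otus <- tree$labels[seq_len(tree$n_otu)]
  for (i in seq_len(tree$n_otu)) {
    td <- bfs_dist(adj, i, tree$V)
    for (j in seq_len(tree$n_otu)) {
      if (j == i) next
      if (td[j] < d[otus[i], otus[j]])
        return(list(ok = FALSE, failed = "P4"))
    }
  }
  if (length(pphs)) {
    if (is.null(root)) stop("monophyly constraints need a root taxon")
    for (p in pphs) {
      if (!check_monophyly(tree, root, p))
        return(list(ok = FALSE, failed = "P5"))
    }
  }
  list(ok = TRUE, failed = NA_character_)
}

# ---- labeled-tree generation (Pruefer) and isomorphism handling -----------

# Straightforward (quadratic) Pruefer decoding -- V is tiny here and
# correctness is what matters.
prufer_decode_simple <- function(seq, V) {
  degree <- tabulate(seq, V) + 1L
  edges <- matrix(0L, V - 1L, 2L)
  s <- seq
  for (t in seq_along(seq)) {
    leaf <- which(degree == 1L & !(seq_len(V) %in% s))[1L]
    edges[t, ] <- c(leaf, s[1L])
    degree[leaf] <- 0L
    degree[s[1L]] <- degree[s[1L]] - 1L
    s <- s[-1L]
  }
  edges[V - 1L, ] <- which(degree == 1L)
  edges
}

all_labeled_trees <- function(V) {
  if (V == 2L) return(list(matrix(c(1L, 2L), 1L, 2L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(V)), V - 2L)))
  lapply(seq_len(nrow(seqs)), function(r)
    prufer_decode_simple(as.integer(seqs[r, ]), V))
}

tree_igraph <- function(tree, taxa_universe) {
  g <- igraph::graph_from_edgelist(tree$edges, directed = FALSE)
  cols <- integer(tree$V)
  cols[seq_len(tree$n_otu)] <-
    match(tree$labels[seq_len(tree$n_otu)], taxa_universe)
  igraph::V(g)$color <- cols  # HTUs share color 0
  g
}

# canonical signature up to relabeling of the anonymous HTUs
canon_signature <- function(tree, taxa_universe) {
  g <- tree_igraph(tree, taxa_universe)
  cp <- igraph::canonical_permutation(g, colors = igraph::V(g)$color)
  gc <- igraph::permute(g, cp$labeling)
  el <- igraph::as_edgelist(gc)
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(c(igraph::V(gc)$color, t(el)), collapse = ",")
}

# A forbidden subtree pattern: a small tree fragment whose OTU nodes carry
# labels and whose internal HTU nodes are anonymous.
new_tree_pattern <- function(edges, labels) {
  structure(list(V = length(labels),
                 edges = matrix(as.integer(edges), ncol = 2L),
                 labels = labels),  # NA for HTU nodes
            class = "tree_pattern")
}

pattern_igraph <- function(pattern, taxa_universe) {
  g <- igraph::graph_from_edgelist(pattern$edges, directed = FALSE)
  cols <- match(pattern$labels, taxa_universe)
  cols[is.na(cols)] <- 0L
  igraph::V(g)$color <- cols
  g
}

contains_pattern <- function(tree, pattern, taxa_universe) {
  gt <- tree_igraph(tree, taxa_universe)
  gp <- pattern_igraph(pattern, taxa_universe)
  igraph::subgraph_isomorphic(gp, gt, method = "vf2")
}

#' Enumerate all most-parsimonious trees
#'
#' Searches node domains of increasing size `V = N + M` (N OTUs plus M
#' anonymous HTUs) and returns, for the smallest `V` admitting at least one
#' tree satisfying P1-P5 and containing no forbidden subtree, the complete
#' set of such trees up to isomorphism fixing the OTU labels.  Completeness
#' at each `V` comes from generating every labeled tree (Pruefer sequences)
#' and collapsing isomorphic duplicates; trees with pendant HTUs are
#' discarded since removing such a node yields a valid tree on a smaller
#' domain.
#'
#' @param dm A `rearr_dmat` with all cells exact (or a plain named matrix).
#' @param pphs List of monophyly constraints (character vectors of taxa).
#' @param root Root OTU name; required when `pphs` is non-empty.
#' @param exclusions List of forbidden subtree patterns (from
#'   [validate_tree_ancestors()]).
#' @param max_htus Ceiling on M (default N + 4); exceeded is an error.
#' @return List of `ptree` objects, with attribute `V`.
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' enumerate_parsimonious_trees(m)  # the chain A - HTU#1 - B
#' @export
enumerate_parsimonious_trees <- function(dm, pphs = list(), root = NULL,
                                         exclusions = list(),
                                         max_htus = NULL) {
  d <- if (inherits(dm, "rearr_dmat")) dm$d else dm
  if (inherits(dm, "rearr_dmat") && any(dm$status == "lower_bound"))
    stop("distance matrix contains lower-bound cells; tree building needs ",
         "exact distances (drop the affected taxa or raise k_max)")
  taxa <- rownames(d)
  N <- length(taxa)
  if (N < 2L) stop("need at least 2 taxa")
  if (is.null(max_htus)) max_htus <- N + 4L

  for (M in 0L:max_htus) {
    V <- N + M
    if (V < 2L) next
    sols <- list()
    seen <- character(0)
    for (edges in all_labeled_trees(V)) {
      tree <- new_ptree(edges, taxa, V)
      deg <- tabulate(tree$edges, V)
      if (M > 0L && any(deg[(N + 1L):V] == 1L)) next  # pendant HTU
      chk <- verify_tree_properties(tree, d, pphs, root)
      if (!chk$ok) next
      if (length(exclusions) &&
          any(vapply(exclusions, function(p)
            contains_pattern(tree, p, taxa), logical(1)))) next
      sig <- canon_signature(tree, taxa)
      if (sig %in% seen) next
      seen <- c(seen, sig)
      sols[[length(sols) + 1L]] <- tree
    }
    if (length(sols)) return(structure(sols, V = V))
  }
  stop("no admissible tree with at most ", max_htus, " HTUs")
}
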
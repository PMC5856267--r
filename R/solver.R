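# The full inference loop: enumerate most-parsimonious trees, validate each
# tree's ancestors, exclude invalid subtrees, and iterate until the solution
# set is complete; then extract the statements true in every solution.

#' Solve the gene-order phylogeny problem
#'
#' Alternates complete tree enumeration (P1-P5 plus accumulated exclusion
#' constraints) with ancestor validation (P6).  Each round either certifies
#' every enumerated tree or discovers new invalid subtrees; exclusions only
#' ever accumulate, so the loop terminates.  When every tree on the current
#' smallest domain is invalid the search escalates to one more HTU: parsimony
#' asks for the smallest domain on which a fully valid tree exists.
#'
#' @param dataset Named list of `genome` objects (at least 3 taxa, one
#'   common gene set).
#' @param pphs List of monophyly constraints (character vectors of taxon
#'   names, optionally named).
#' @param root Root taxon name (required when `pphs` is non-empty).
#' @param k_max Distance/path search cap.
#' @param max_htus Ceiling on the number of HTUs.
#' @param max_rounds Safety cap on enumeration/validation rounds.
#' @return A `phylo_solutions` object: list with `solutions` (each
#'   `list(tree, assignment)`), `V`, `exclusions`, `rounds`, `dm`, and
#'   `complete` (`FALSE` only when a cap was hit).
#' @export
solve_phylo <- function(dataset, pphs = list(), root = NULL, k_max = 8L,
                        max_htus = NULL, max_rounds = 100L) {
  if (length(dataset) < 2L) stop("need at least 2 taxa")
  dm <- build_distance_matrix(dataset, k_max = k_max)
  genomes <- dm$genomes
  exclusions <- list()
  rounds <- 0L
  log <- list()
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      warning("round cap reached; solution set may be incomplete")
      return(structure(list(solutions = list(), V = NA_integer_,
                            exclusions = exclusions, rounds = rounds,
                            dm = dm, complete = FALSE),
                       class = "phylo_solutions"))
    }
    trees <- enumerate_parsimonious_trees(dm, pphs = pphs, root = root,
                                          exclusions = exclusions,
                                          max_htus = max_htus)
    V <- attr(trees, "V")
    checks <- lapply(trees, validate_tree_ancestors, genomes = genomes,
                     k_max = k_max)
    ok <- vapply(checks, `[[`, logical(1), "valid")
    log[[rounds]] <- list(V = V, n_trees = length(trees),
                          n_invalid = sum(!ok))
    for (ch in checks[!ok])
      exclusions[[length(exclusions) + 1L]] <- ch$invalid_subtree
    if (all(ok)) {
      sols <- Map(function(t, c) list(tree = t, assignment = c$assignment),
                  trees, checks)
      return(structure(list(solutions = unname(sols), V = V,
                            exclusions = exclusions, rounds = rounds,
                            dm = dm, complete = TRUE, log = log),
                       class = "phylo_solutions"))
    }
    # otherwise iterate: the new exclusions remove the invalid trees; when
    # nothing survives at this V the enumeration escalates automatically.
  }
}

#' @export
print.phylo_solutions <- function(x, ...) {
  cat("Complete solution set:", length(x$solutions), "tree(s) on",
      x$V, "nodes after", x$rounds, "round(s);",
      length(x$exclusions), "invalid subtree(s) excluded\n")
  invisible(x)
}

#' Logical consequences of a solution set
#'
#' A statement verified by every tree of the complete solution set is a
#' logical consequence and stands regardless of which solution reflects the
#' true history.  Three families are extracted: clades monophyletic in all
#' solutions, OTU-OTU edges present in all solutions, and ancestral
#' identities ("taxon X realises the ground pattern of clade C": the node at
#' the base of C carries exactly X's gene order in every solution, either
#' because it is X itself or because it is an HTU whose only candidate order
#' is X's).
#'
#' @param x A `phylo_solutions` with at least one solution.
#' @param root Root taxon (defaults to the one implied by the first tree:
#'   must be supplied when no PPHs were used).
#' @return List with `clades` (list of character vectors), `fixed_edges`
#'   (two-column matrix of taxon names), `ur_identities` (data frame with
#'   `taxon` and `clade`).
#' @export
logical_consequences <- function(x, root) {
  stopifnot(inherits(x, "phylo_solutions"))
  if (!isTRUE(x$complete)) stop("solution set is not complete")
  if (length(x$solutions) == 0L) stop("empty solution set")
  trees <- lapply(x$solutions, `[[`, "tree")
  asgs <- lapply(x$solutions, `[[`, "assignment")
  taxa <- trees[[1L]]$labels[seq_len(trees[[1L]]$n_otu)]
  if (!root %in% taxa) stop("unknown root taxon '", root, "'")
  genomes <- x$dm$genomes
  ord <- gene_order_of(genomes[[1L]]$labels)
  otu_key <- vapply(genomes, canonical_key, character(1), order = ord)

  clade_info <- lapply(trees, function(tr) {
    root_node <- match(root, tr$labels)
    cls <- edge_clades(tr, root_node)
    # basal node of each clade = the endpoint of the cut edge on the clade
    # side; for chains of HTUs the realisation closest to the root is kept
    basal <- integer(length(cls))
    di <- bfs_dist(adjacency_list(tr), root_node, tr$V)
    for (r in seq_along(cls)) {
      i <- tr$edges[r, 1]; j <- tr$edges[r, 2]
      # clade side = the endpoint of the cut edge farther from the root
      basal[r] <- if (di[i] > di[j]) i else j
    }
    list(clades = cls, basal = basal, tree = tr)
  })

  clade_sets <- lapply(clade_info, function(ci)
    unique(lapply(ci$clades, paste, collapse = "|")))
  common <- Reduce(intersect, clade_sets)
  common <- setdiff(common, c(paste(sort(setdiff(taxa, root)),
                                    collapse = "|"), ""))
  clades <- lapply(common, function(s) strsplit(s, "\\|")[[1L]])
  clades <- clades[vapply(clades, length, integer(1)) >= 2L]

  edge_sets <- lapply(trees, function(tr) {
    e <- tr$edges
    keep <- e[, 1] <= tr$n_otu & e[, 2] <= tr$n_otu
    if (!any(keep)) return(character(0))
    apply(e[keep, , drop = FALSE], 1L, function(r)
      paste(sort(tr$labels[r]), collapse = "|"))
  })
  fixed <- Reduce(intersect, edge_sets)
  fixed_edges <- if (length(fixed))
    do.call(rbind, strsplit(fixed, "\\|")) else
    matrix(character(0), 0L, 2L)

  # ancestral identities per common clade
  ur <- list()
  for (cl in clades) {
    key_per_sol <- character(0)
    ok <- TRUE
    for (s in seq_along(trees)) {
      ci <- clade_info[[s]]
      hit <- which(vapply(ci$clades, function(x2)
        identical(sort(x2), sort(cl)), logical(1)))
      if (length(hit) == 0L) { ok <- FALSE; break }
      # basal-most realisation: largest root distance is deepest; take the
      # one nearest the root among the cut edges realising the clade
      node <- ci$basal[hit[1L]]
      if (length(hit) > 1L) {
        dists <- bfs_dist(adjacency_list(ci$tree),
                          match(root, ci$tree$labels), ci$tree$V)
        node <- ci$basal[hit[which.min(dists[ci$basal[hit]])]]
      }
      nm <- ci$tree$labels[node]
      keys <- if (node <= ci$tree$n_otu) otu_key[nm] else
        asgs[[s]]$candidates[[nm]]
      if (length(keys) != 1L) { ok <- FALSE; break }
      key_per_sol[s] <- keys
    }
    if (!ok) next
    if (length(unique(key_per_sol)) != 1L) next
    taxon <- names(otu_key)[match(key_per_sol[1L], otu_key)]
    if (is.na(taxon)) next
    ur[[length(ur) + 1L]] <- data.frame(taxon = taxon,
                                        clade = paste(cl, collapse = ","),
                                        stringsAsFactors = FALSE)
  }
  ur_identities <- if (length(ur)) do.call(rbind, ur) else
    data.frame(taxon = character(0), clade = character(0))

  list(clades = clades, fixed_edges = fixed_edges,
       ur_identities = ur_identities)
}
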
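# The backtracking path engine: heuristic test, exhaustive k-path
# enumeration, exact distance by iterative deepening, minimal-path sets, and
# cut detection.

#' Heuristic test of the backtracking search
#'
#' The depth-first search keeps, at each node, the current genome `x`, the
#' target, the number of steps already used and the total budget.  The test
#' answers:
#' \itemize{
#'   \item `"YES"` — the current path is a solution (`x` equals the target
#'     with the budget exactly spent);
#'   \item `"NO"` — the path cannot be extended into a solution: the lower
#'     bound fires (more than three breakpoints can never be resolved per
#'     step, so `nb_breakpoints(x, target) > 3 * remaining` is hopeless), or
#'     the target was reached early (a minimal path never revisits its
#'     endpoint), or the budget is spent elsewhere;
#'   \item `"INDETERMINATE"` — keep searching.
#' }
#'
#' @param x,target `genome` objects over the same genes.
#' @param steps_used Steps already taken (`r`).
#' @param budget Total path length sought (`k`).
#' @param ht2 Apply the breakpoint lower-bound test (exact, never wrong).
#' @return `"YES"`, `"NO"` or `"INDETERMINATE"`.
#' @export
heuristic_test <- function(x, target, steps_used, budget, ht2 = TRUE) {
  stopifnot(steps_used >= 0L, steps_used <= budget)
  remaining <- budget - steps_used
  eq <- genomes_equal(x, target)
  if (eq && remaining == 0L) return("YES")
  if (eq) return("NO")           # early arrival: no zero-cost extension
  if (remaining == 0L) return("NO")
  if (ht2 && nb_breakpoints(x, target) > 3L * remaining) return("NO")
  "INDETERMINATE"
}

#' Enumerate all k-step paths between two genomes
#'
#' Complete depth-first enumeration of every path of length exactly `k` from
#' `a` to `b`.  A path is a sequence of genomes in which consecutive entries
#' differ by one rearrangement; path identity is the sequence of canonical
#' gene orders, so equivalent operation parameterisations are not counted
#' twice.  With `ht1 = TRUE` the shared-block test restricts rearrangements
#' to those that do not break blocks shared between the current genome and
#' `b`; this may discard some valid paths but never all minimal ones.  The
#' lower-bound test (`ht2`) is exact and only prunes dead branches.
#'
#' @param a,b `genome` objects over the same genes.
#' @param k Path length (number of rearrangement steps).
#' @param ht1 Shared-block pruning (default off: full enumeration).
#' @param ht2 Lower-bound pruning (default on).
#' @param order Optional label order for canonical keys.
#' @return A list of paths; each path is a list of `k + 1` `genome` objects.
#' @examples
#' length(enumerate_k_paths(parse_genome("1 -2 -3 -5 -4"),
#'                          parse_genome("1 2 3 4 5"), k = 2))  # 8
#' @export
enumerate_k_paths <- function(a, b, k, ht1 = FALSE, ht2 = TRUE,
                              order = NULL) {
  stopifnot(k >= 0L)
  enc <- encode_pair(a, b, order)
  mats <- .cpp_k_paths(enc$a, enc$b, as.integer(k), ht1, ht2, enc$circular)
  lapply(mats, function(m) {
    lapply(seq_len(nrow(m)), function(r)
      decode_genome(m[r, ], enc$order, a$topology))
  })
}

#' Exact rearrangement distance
#'
#' The length of a minimal path between `a` and `b`, computed by iterative
#' deepening over the path length with complete enumeration at each depth.
#' Both pruning tests are enabled by default; they change the work, never the
#' answer.  When the distance exceeds `k_max` the search reports failure
#' (`NA`) rather than a wrong value.
#'
#' @param a,b `genome` objects over exactly the same genes (reduce with
#'   [restrict_to_common()] first when gene content differs).
#' @param k_max Largest path length tried (default 8).
#' @param ht1,ht2 Pruning tests (shared block / breakpoint lower bound).
#' @return Integer distance, or `NA` (with attribute `k_max`) when
#'   `d > k_max`.
#' @examples
#' genome_distance(parse_genome("1 -2 -3 -5 -4"), parse_genome("1 2 3 4 5"))
#' @export
genome_distance <- function(a, b, k_max = 8L, ht1 = TRUE, ht2 = TRUE) {
  stopifnot(k_max >= 0L)
  enc <- encode_pair(a, b)
  d <- .cpp_distance(enc$a, enc$b, as.integer(k_max), ht1, ht2, enc$circular)
  if (d < 0L) return(structure(NA_integer_, k_max = as.integer(k_max)))
  d
}

#' All minimal paths between two genomes
#'
#' Computes the exact distance, then enumerates every path of that length.
#' For ancestral-gene-order inference the enumeration must be run with the
#' shared-block test disabled (`ht1 = FALSE`, the default) so that no minimal
#' path is missed.
#'
#' @inheritParams enumerate_k_paths
#' @param k_max Passed to [genome_distance()].
#' @return List of minimal paths (see [enumerate_k_paths()]).
#' @export
enumerate_minimal_paths <- function(a, b, ht1 = FALSE, k_max = 8L,
                                    order = NULL) {
  d <- genome_distance(a, b, k_max = k_max)
  if (is.na(d))
    stop("distance exceeds k_max = ", k_max, "; cannot enumerate minimal ",
         "paths")
  enumerate_k_paths(a, b, d, ht1 = ht1, ht2 = TRUE, order = order)
}

#' Locate cuts along a path
#'
#' A step of a path is a cut when it breaks a block that is present in the
#' path's two endpoints and in the genome just before the step.  Minimal
#' circular paths without cuts always exist (the shared-block property);
#' the linear case can force a cut.
#'
#' @param path A list of `genome` objects (as returned by the enumeration
#'   functions).
#' @return Integer vector of step indices (step `i` is `path[[i]]` to
#'   `path[[i + 1]]`) that are cuts; empty when the path is cut-free.
#' @export
path_cuts <- function(path) {
  k <- length(path) - 1L
  if (k < 1L) return(integer(0))
  g0 <- path[[1L]]; gk <- path[[k + 1L]]
  ord <- gene_order_of(g0$labels)
  adj_set <- function(g) {
    iv <- encode_genome(g, ord)
    n <- length(iv)
    if (g$topology == "circular") {
      u <- iv
      v <- iv[c(seq_len(n)[-1L], 1L)]
    } else {
      u <- iv[-n]
      v <- iv[-1L]
    }
    # an adjacency and its reversal-with-negation count as one
    unique(c(paste0(u, ",", v), paste0(-v, ",", -u)))
  }
  ends <- intersect(adj_set(g0), adj_set(gk))
  cuts <- integer(0)
  for (i in seq_len(k)) {
    common <- intersect(ends, adj_set(path[[i]]))
    if (length(setdiff(common, adj_set(path[[i + 1L]]))) > 0L)
      cuts <- c(cuts, i)
  }
  cuts
}
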
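# Pairwise distance matrices over a taxon dataset, with common-gene
# reduction, gain/loss annotation and the fast-evolver removal rule.

#' Pairwise rearrangement distance matrix
#'
#' For every unordered pair of taxa the genomes are reduced to their common
#' genes, the exact distance is computed, and removed genes are recorded as
#' gain/loss annotations.  Taxa with identical gene orders are merged first
#' (with a warning): the tree stage works on distinct gene orders.  Cells
#' whose distance exceeds `k_max` are stored as `k_max + 1` with status
#' `"lower_bound"`; such cells are excluded from tree building.
#'
#' @param dataset Named list of `genome` objects (e.g. from
#'   [read_gene_orders()]), at least two taxa.
#' @param k_max Largest distance searched exactly (default 8).
#' @param ht1,ht2 Pruning tests, both on by default.
#' @param merge_duplicates Merge taxa with equal gene orders (default TRUE).
#' @return A `rearr_dmat` object: list with `d` (symmetric integer matrix),
#'   `status` (`"exact"`/`"lower_bound"`), `removals` (per-pair gain/loss
#'   annotations), `k_max`, `merged` (duplicate-taxon map).
#' @export
build_distance_matrix <- function(dataset, k_max = 8L, ht1 = TRUE,
                                  ht2 = TRUE, merge_duplicates = TRUE) {
  if (length(dataset) < 2L) stop("need at least 2 taxa")
  if (is.null(names(dataset)) || any(!nzchar(names(dataset))))
    stop("dataset must be a named list of genomes")
  if (anyDuplicated(names(dataset)))
    stop("duplicate taxon names")

  merged <- character(0)
  if (merge_duplicates) {
    keys <- vapply(dataset, function(g)
      paste(sort(g$labels), collapse = "|", sep = ""), character(1))
    keys <- paste(keys, vapply(dataset, canonical_key, character(1)))
    dup <- duplicated(keys)
    if (any(dup)) {
      kept <- names(dataset)[match(keys[dup], keys)]
      merged <- setNames(kept, names(dataset)[dup])
      warning("merged duplicate gene orders: ",
              paste(names(merged), "->", merged, collapse = ", "))
      dataset <- dataset[!dup]
    }
  }

  taxa <- names(dataset)
  N <- length(taxa)
  d <- matrix(0L, N, N, dimnames = list(taxa, taxa))
  status <- matrix("exact", N, N, dimnames = list(taxa, taxa))
  removals <- list()
  for (i in seq_len(N - 1L)) {
    for (j in seq(i + 1L, N)) {
      a <- dataset[[i]]; b <- dataset[[j]]
      if (!setequal(a$labels, b$labels)) {
        red <- restrict_to_common(a, b)
        removals[[paste(taxa[i], taxa[j], sep = "|")]] <-
          list(from_a = red$removed_from_a, from_b = red$removed_from_b)
        a <- red$a; b <- red$b
      }
      dij <- genome_distance(a, b, k_max = k_max, ht1 = ht1, ht2 = ht2)
      if (is.na(dij)) {
        d[i, j] <- d[j, i] <- k_max + 1L
        status[i, j] <- status[j, i] <- "lower_bound"
      } else {
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  structure(list(d = d, status = status, removals = removals,
                 k_max = as.integer(k_max), merged = merged,
                 genomes = dataset),
            class = "rearr_dmat")
}

#' @export
print.rearr_dmat <- function(x, ...) {
  cat("Rearrangement distance matrix over", nrow(x$d), "taxa",
      sprintf("(k_max = %d)\n", x$k_max))
  print(x$d)
  nlb <- sum(x$status == "lower_bound") / 2L
  if (nlb > 0)
    cat(nlb, "pair(s) exceeded k_max; shown as k_max + 1 (lower bound)\n")
  if (length(x$merged))
    cat("merged duplicates:",
        paste(names(x$merged), "->", x$merged, collapse = ", "), "\n")
  invisible(x)
}

#' Flag fast-evolving taxa
#'
#' Random gene orders of mitochondrial size land at distance 6--7 from almost
#' everything, so large distances carry little signal.  A taxon is flagged
#' when its distance exceeds `dist_threshold` to strictly more than
#' `frac_threshold` of the other taxa; cells that only carry a lower bound
#' count as exceeding.
#'
#' @param dm A `rearr_dmat`.
#' @param dist_threshold Distance threshold (default 5).
#' @param frac_threshold Fraction of other taxa (default 0.95, strict).
#' @return Character vector of flagged taxon names.
#' @export
flag_fast_evolving <- function(dm, dist_threshold = 5, frac_threshold = 0.95) {
  stopifnot(inherits(dm, "rearr_dmat"))
  N <- nrow(dm$d)
  if (N < 3L) stop("need at least 3 taxa")
  exceeds <- dm$d > dist_threshold | dm$status == "lower_bound"
  diag(exceeds) <- FALSE
  frac <- rowSums(exceeds) / (N - 1L)
  rownames(dm$d)[frac > frac_threshold]
}
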
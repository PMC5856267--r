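# The three elementary rearrangements, neighbor enumeration, breakpoints and
# shared blocks.

#' Apply one elementary rearrangement
#'
#' A rearrangement detaches a block (a strict contiguous run of genes) and
#' re-inserts it: in place but reversed-with-negation (`"inversion"`),
#' elsewhere between two successive genes (`"transposition"`), or elsewhere
#' and reversed (`"reverse_transposition"`).  Positions refer to the genome's
#' stored representation, 1-based; circular blocks may wrap.
#'
#' @param g A `genome`.
#' @param kind One of `"inversion"`, `"transposition"`,
#'   `"reverse_transposition"`.
#' @param block_start,block_length Block position and length
#'   (`1 <= block_length <= n - 1`).
#' @param insert_after For (reverse) transpositions: the position of the gene
#'   after which the block is re-inserted (`0` = before the first gene of a
#'   linear genome).  Must lie outside the block and differ from the block's
#'   original position.
#' @return The rearranged `genome`.
#' @examples
#' g <- parse_genome("A B C")
#' apply_rearrangement(g, "transposition", block_start = 2, block_length = 1,
#'                     insert_after = 0)   # [B A C]
#' @export
apply_rearrangement <- function(g, kind = c("inversion", "transposition",
                                            "reverse_transposition"),
                                block_start, block_length,
                                insert_after = NULL) {
  kind <- match.arg(kind)
  n <- genome_size(g)
  circ <- g$topology == "circular"
  if (block_length < 1L || block_length > n - 1L)
    stop("block_length must be between 1 and n - 1")
  if (block_start < 1L || block_start > n) stop("block_start out of range")
  if (!circ && block_start + block_length - 1L > n)
    stop("block extends past the end of a linear genome")

  pos <- if (circ) ((block_start - 1L + seq_len(block_length) - 1L) %% n) + 1L
         else block_start + seq_len(block_length) - 1L
  tok <- genome_tokens(g)
  blk <- tok[pos]
  inv_blk <- rev(ifelse(startsWith(blk, "-"), sub("^-", "", blk),
                        paste0("-", blk)))

  if (kind == "inversion") {
    tok[pos] <- inv_blk
    return(parse_genome(tok, g$topology))
  }

  if (is.null(insert_after))
    stop("insert_after is required for (reverse) transpositions")
  before <- if (circ) ((block_start - 2L) %% n) + 1L else block_start - 1L
  if (insert_after %in% pos)
    stop("insertion point lies inside the moved block")
  if (insert_after == before)
    stop("re-insertion at the block's original position is not a ",
         "transposition")
  if (!circ && (insert_after < 0L || insert_after > n))
    stop("insert_after out of range")
  rest <- tok[-pos]
  # position of the insertion gene among the remaining genes
  if (insert_after == 0L) {
    at <- 0L
  } else {
    at <- match(tok[insert_after], rest)
  }
  piece <- if (kind == "transposition") blk else inv_blk
  out <- append(rest, piece, after = at)
  parse_genome(out, g$topology)
}

#' All genomes one rearrangement away
#'
#' Every genome reachable from `g` by exactly one inversion, transposition or
#' reverse transposition.  Because of circularity, distinct operation
#' parameters can produce the same gene order (three equivalent
#' transpositions, two equivalent inversions); neighbors are therefore
#' deduplicated by canonical key and returned in that order, and `g` itself
#' never appears.
#'
#' @param g A `genome`.
#' @param order Optional label order for canonical keys.
#' @return List of `genome` objects (canonical representations), sorted.
#' @export
enumerate_neighbors <- function(g, order = NULL) {
  ord <- gene_order_of(g$labels, order)
  out <- .cpp_neighbors(encode_genome(g, ord), g$topology == "circular")
  lapply(out, decode_genome, order = ord, topology = g$topology)
}

#' Number of breakpoints between two gene orders
#'
#' A position between two successive genes of `a` is a breakpoint when those
#' genes are not successive (in the same reading direction, allowing for the
#' reversal-with-negation of the whole genome) in `b`.  The count is
#' symmetric in its arguments.
#'
#' @param a,b `genome` objects over exactly the same genes.
#' @return Integer count.
#' @examples
#' nb_breakpoints(parse_genome("1 2 3 4 5"), parse_genome("1 -2 -3 -5 -4"))
#' @export
nb_breakpoints <- function(a, b) {
  enc <- encode_pair(a, b)
  .cpp_breakpoints(enc$a, enc$b, enc$circular)
}

#' Maximal blocks shared by two genomes
#'
#' All maximal runs of two or more genes that appear contiguously (possibly
#' inverted) in both genomes.  A block internal to both genomes is exactly a
#' run of shared adjacencies, so the result is the complement of the
#' breakpoint structure.  Identical genomes are rejected: every proper block
#' is shared and callers are expected to have filtered equality upstream.
#'
#' @param a,b `genome` objects over exactly the same genes.
#' @return A list of character vectors of signed tokens (blocks as they read
#'   in `a`).
#' @examples
#' shared_blocks(parse_genome("1 2 3 4 5"), parse_genome("1 -2 -3 -5 -4"))
#' @export
shared_blocks <- function(a, b) {
  if (genomes_equal(a, b))
    stop("genomes are equal: every proper block is shared")
  enc <- encode_pair(a, b)
  n <- length(enc$a)
  circ <- enc$circular
  # shared[j]: adjacency between positions j and j+1 of `a` also in `b`
  succ <- integer(2L * n + 1L)
  m <- if (circ) n else n - 1L
  for (i in seq_len(m)) {
    u <- enc$b[i]; v <- enc$b[if (i == n) 1L else i + 1L]
    succ[u + n + 1L] <- v
    succ[-v + n + 1L] <- -u
  }
  shared <- vapply(seq_len(m), function(i) {
    u <- enc$a[i]; v <- enc$a[if (i == n) 1L else i + 1L]
    succ[u + n + 1L] == v
  }, logical(1))

  tok <- genome_tokens(decode_genome(enc$a, enc$order, a$topology))
  blocks <- list()
  if (circ) {
    # walk maximal runs of shared adjacencies around the circle
    js <- which(shared)
    if (length(js) == 0L) return(blocks)
    is_start <- vapply(js, function(j) !shared[((j - 2L) %% n) + 1L],
                       logical(1))
    starts <- js[is_start]
    for (s in starts) {
      len <- 1L
      while (shared[((s + len - 1L) %% n) + 1L]) len <- len + 1L
      idx <- ((s - 1L + 0:len) %% n) + 1L
      blocks[[length(blocks) + 1L]] <- tok[idx]
    }
  } else {
    r <- rle(shared)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      blocks[[length(blocks) + 1L]] <- tok[starts[i]:(ends[i] + 1L)]
    }
  }
  blocks
}
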
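# Signed gene-order representation: parsing, equivalence, canonical keys,
# and gene-content reduction.

TOKEN_RE <- "^-?[A-Za-z0-9][A-Za-z0-9_.]*$"

new_genome <- function(labels, signs, topology) {
  structure(list(labels = as.character(labels), signs = as.integer(signs),
                 topology = topology),
            class = "genome")
}

#' Parse a signed gene order
#'
#' A genome is a sequence of signed genes such as
#' \code{"cox1 cox2 atp8 ... -nad6 ..."}: a leading \code{-} marks a gene read
#' from the opposite strand.  A circular genome is identified with all its
#' rotations and with its reversal-with-negation, a linear genome only with
#' the latter.
#'
#' @param text A single whitespace-separated string of signed tokens, or a
#'   character vector with one token per element.
#' @param topology `"circular"` (the default, the mitochondrial case) or
#'   `"linear"`.
#' @return A `genome` object.
#' @examples
#' parse_genome("1 2 -3")
#' parse_genome(
#'   "cox1 cox2 atp8 atp6 cox3 nad3 nad4L nad4 nad5 -nad6 cob rrnS rrnL nad1 nad2")
#' @export
parse_genome <- function(text, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (length(text) == 1L) {
    tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  } else {
    tokens <- as.character(text)
  }
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty gene order")
  bad <- tokens[!grepl(TOKEN_RE, tokens)]
  if (length(bad)) stop("unparsable token(s): ", paste(bad, collapse = ", "))
  signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  labels <- sub("^-", "", tokens)
  if (anyDuplicated(labels))
    stop("duplicate gene label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(labels) < 2L) stop("a genome needs at least 2 genes")
  new_genome(labels, signs, topology)
}

#' @export
format.genome <- function(x, ...) {
  paste0("[", paste(genome_tokens(x), collapse = " "), "]",
         if (x$topology == "linear") " (linear)" else "")
}

#' @export
print.genome <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Signed tokens of a genome
#'
#' @param g A `genome`.
#' @return Character vector of signed tokens (`"-nad6"` style).
#' @export
genome_tokens <- function(g) {
  paste0(ifelse(g$signs < 0L, "-", ""), g$labels)
}

#' Number of genes
#' @param g A `genome`.
#' @return Integer.
#' @export
genome_size <- function(g) length(g$labels)

# ---- integer encoding shared with the C++ engine ---------------------------

# Reference label order used to encode a genome as a signed permutation of
# 1..n.  The default depends only on the gene set: numeric ascending when the
# whole alphabet is integer-like, C-locale radix order otherwise.  Dataset
# functions pass their registration order explicitly so keys are comparable
# across the dataset.
gene_order_of <- function(labels, order = NULL) {
  if (!is.null(order)) {
    if (!all(labels %in% order))
      stop("gene label(s) missing from the supplied order: ",
           paste(setdiff(labels, order), collapse = ", "))
    return(order)
  }
  if (all(grepl("^[0-9]+$", labels))) {
    labels[base::order(as.integer(labels))]
  } else {
    labels[base::order(labels, method = "radix")]
  }
}

encode_genome <- function(g, order) {
  idx <- match(g$labels, order)
  if (anyNA(idx)) stop("gene label(s) not in the reference order")
  as.integer(g$signs * idx)
}

decode_genome <- function(iv, order, topology) {
  new_genome(order[abs(iv)], sign(iv), topology)
}

# Both genomes encoded against one shared order; errors if gene sets differ.
encode_pair <- function(a, b, order = NULL) {
  if (a$topology != b$topology)
    stop("genomes have different topologies")
  if (!setequal(a$labels, b$labels) || length(a$labels) != length(b$labels))
    stop("genomes do not have exactly the same genes (reduce to common ",
         "genes first, see restrict_to_common())")
  ord <- gene_order_of(a$labels, order)
  list(a = encode_genome(a, ord), b = encode_genome(b, ord), order = ord,
       circular = a$topology == "circular")
}

# ---- representations, equality, canonical key ------------------------------

#' All representations of a genome
#'
#' A circular genome of n genes can be written in 2n ways (n rotations of the
#' sequence and n rotations of its reversal-with-negation); a linear genome in
#' exactly 2.
#'
#' @param g A `genome`.
#' @return A list of character vectors of signed tokens, one per
#'   representation, without duplicates.
#' @examples
#' representations(parse_genome("1 2 -3"))
#' @export
representations <- function(g) {
  tok <- genome_tokens(g)
  n <- length(tok)
  refl <- rev(ifelse(startsWith(tok, "-"), sub("^-", "", tok),
                     paste0("-", tok)))
  if (g$topology == "linear") return(list(tok, refl))
  out <- vector("list", 2L * n)
  for (s in seq_len(n)) {
    rot <- c(seq(s, n), seq_len(s - 1L))
    out[[s]] <- tok[rot]
    out[[n + s]] <- refl[rot]
  }
  out
}

#' Canonical key of a genome
#'
#' A deterministic representative among all representations: the
#' lexicographically least under a total order on signed tokens (label
#' ascending in the reference order, \code{+} before \code{-}).  Equal genomes
#' always yield identical keys, so keys support hashing and deduplication.
#'
#' @param g A `genome`.
#' @param order Optional explicit label order (e.g. the registration order of
#'   a dataset); by default labels sort ascending.
#' @return A single string of space-separated signed tokens.
#' @examples
#' canonical_key(parse_genome("1 2 -3")) == canonical_key(parse_genome("2 -3 1"))
#' @export
canonical_key <- function(g, order = NULL) {
  ord <- gene_order_of(g$labels, order)
  iv <- .cpp_canonical(encode_genome(g, ord), g$topology == "circular")
  paste(paste0(ifelse(iv < 0L, "-", ""), ord[abs(iv)]), collapse = " ")
}

canonical_genome <- function(g, order = NULL) {
  ord <- gene_order_of(g$labels, order)
  decode_genome(.cpp_canonical(encode_genome(g, ord),
                               g$topology == "circular"),
                ord, g$topology)
}

#' Are two gene orders the same genome?
#'
#' True when `b` is one of the representations of `a` (same topology).
#' Different gene sets give `FALSE`, not an error.
#'
#' @param a,b `genome` objects.
#' @return Logical.
#' @examples
#' genomes_equal(parse_genome("1 2 -3"), parse_genome("-1 3 -2"))
#' @export
genomes_equal <- function(a, b) {
  if (a$topology != b$topology) return(FALSE)
  if (length(a$labels) != length(b$labels)) return(FALSE)
  if (!setequal(a$labels, b$labels)) return(FALSE)
  ord <- gene_order_of(a$labels)
  circ <- a$topology == "circular"
  identical(.cpp_canonical(encode_genome(a, ord), circ),
            .cpp_canonical(encode_genome(b, ord), circ))
}

#' Reduce two genomes to their common genes
#'
#' Pairwise comparison ignores gains and losses: both genomes are restricted
#' to the gene labels they share (matching is sign-insensitive), preserving
#' relative order and orientation, and the removed genes are reported so that
#' gain/loss events can be annotated downstream.
#'
#' @param a,b `genome` objects.
#' @return A list with `a`, `b` (the reduced genomes), `removed_from_a`
#'   and `removed_from_b` (character vectors of labels).
#' @examples
#' restrict_to_common(parse_genome("1 2 3 4"), parse_genome("1 3 2"))
#' @export
restrict_to_common <- function(a, b) {
  shared <- intersect(a$labels, b$labels)
  if (length(shared) < 3L)
    stop("genomes share fewer than 3 genes (", length(shared), ")")
  keep_a <- a$labels %in% shared
  keep_b <- b$labels %in% shared
  list(a = new_genome(a$labels[keep_a], a$signs[keep_a], a$topology),
       b = new_genome(b$labels[keep_b], b$signs[keep_b], b$topology),
       removed_from_a = a$labels[!keep_a],
       removed_from_b = b$labels[!keep_b])
}

#' Canonical linear representation (CLR)
#'
#' By convention a mitochondrial gene order is printed starting at an anchor
#' gene (cox1) in \code{+} orientation.
#'
#' @param g A circular `genome` containing the anchor.
#' @param anchor Anchor gene label, default `"cox1"`.
#' @return Character vector of signed tokens starting at `+anchor`.
#' @export
clr <- function(g, anchor = "cox1") {
  if (g$topology != "circular") stop("CLR is defined for circular genomes")
  i <- match(anchor, g$labels)
  if (is.na(i)) stop("anchor gene '", anchor, "' not present")
  labels <- g$labels; signs <- g$signs
  if (signs[i] < 0L) {  # reverse-negate so the anchor reads +
    labels <- rev(labels); signs <- rev(-signs)
    i <- match(anchor, labels)
  }
  n <- length(labels)
  rot <- c(seq(i, n), seq_len(i - 1L))
  paste0(ifelse(signs[rot] < 0L, "-", ""), labels[rot])
}
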
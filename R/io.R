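# File formats: gene-order tables, PPH configuration, Newick export and
# report writers.

#' Read a gene-order table
#'
#' One taxon per line: `taxon_name<TAB>signed tokens separated by spaces`.
#' Lines starting with `#` are comments.  Duplicate taxon names and mixed
#' alphabets (integer-like and name-like labels in one dataset) are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @param topology Topology of all genomes (default circular).
#' @return Named list of `genome` objects with attribute `gene_table` (the
#'   dataset registration order of labels), class `gene_order_set`.
#' @export
read_gene_orders <- function(path, topology = "circular") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene-order table: ", path)
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed row(s) (need taxon<TAB>tokens): line ", bad[1L])
  taxa <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(taxa))
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  genomes <- lapply(parts, function(p) parse_genome(p[[2L]], topology))
  names(genomes) <- taxa
  all_labels <- unique(unlist(lapply(genomes, `[[`, "labels")))
  numeric_like <- grepl("^[0-9]+$", all_labels)
  if (any(numeric_like) && !all(numeric_like))
    stop("mixed gene alphabets (integer-like and named labels) in one ",
         "dataset")
  structure(genomes, gene_table = all_labels,
            class = c("gene_order_set", "list"))
}

#' Write a gene-order table
#'
#' @param dataset Named list of `genome` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_orders <- function(dataset, path) {
  lines <- vapply(names(dataset), function(nm)
    paste0(nm, "\t", paste(genome_tokens(dataset[[nm]]), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPH (monophyly constraint) configuration
#'
#' YAML with an optional `root` scalar and a `pphs` mapping of constraint
#' name to taxa list:
#' \preformatted{
#' root: Tethya_actinia
#' pphs:
#'   Bilateria: [Homo_sapiens, Limulus_polyphemus, Katharina_tunicata]
#' }
#'
#' @param path Path to the YAML file.
#' @return List with `root` (or `NULL`) and `pphs` (named list of character
#'   vectors).
#' @export
read_pph_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pphs <- lapply(cfg$pphs, as.character)
  list(root = cfg$root, pphs = pphs)
}

#' Write a tree as Newick
#'
#' The tree is rooted at `root` for writing; every edge carries branch
#' length 1 (one rearrangement step).  HTU nodes are labelled `HTU#k`, and an
#' OTU sitting at an internal position becomes an internal node label.  When
#' an HTU assignment is given, a sidecar TSV `<path>.htu.tsv` lists the
#' candidate gene orders per HTU.
#'
#' @param tree A `ptree`.
#' @param path Output path.
#' @param root Root taxon name (default: first OTU).
#' @param assignment Optional `htu_assignment`.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path, root = NULL,
                         assignment = NULL) {
  if (is.null(root)) root <- tree$labels[1L]
  root_node <- match(root, tree$labels)
  if (is.na(root_node)) stop("unknown root '", root, "'")
  adj <- adjacency_list(tree)
  build <- function(v, from) {
    kids <- setdiff(adj[[v]], from)
    lab <- tree$labels[v]
    if (length(kids) == 0L) return(paste0(lab, ":1"))
    paste0("(", paste(vapply(kids, build, character(1), from = v),
                      collapse = ","),
           ")", lab, if (v == root_node) "" else ":1")
  }
  nwk <- paste0(build(root_node, 0L), ";")
  writeLines(nwk, path)
  if (!is.null(assignment) && length(assignment$candidates)) {
    side <- unlist(lapply(names(assignment$candidates), function(nm)
      paste0(nm, "\t", assignment$candidates[[nm]])))
    writeLines(c("# HTU\tcandidate_gene_order", side),
               paste0(path, ".htu.tsv"))
  }
  invisible(nwk)
}

#' Write a distance matrix as TSV (with a JSON status sidecar)
#'
#' @param dm A `rearr_dmat`.
#' @param path Output TSV path; per-cell status and gain/loss annotations go
#'   to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  write.table(dm$d, path, sep = "\t", quote = FALSE, col.names = NA)
  meta <- list(k_max = dm$k_max,
               status = as.data.frame(dm$status),
               removals = dm$removals,
               merged = as.list(dm$merged))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Homo sapiens mitochondrial gene order (protein-coding + rRNA genes)
#'
#' The canonical linear representation of the human mtDNA without tRNA
#' genes, used as a worked example throughout.
#'
#' @return A 15-gene circular `genome`.
#' @export
homo_sapiens_gene_order <- function() {
  parse_genome(paste("cox1 cox2 atp8 atp6 cox3 nad3 nad4L nad4 nad5 -nad6",
                     "cob rrnS rrnL nad1 nad2"))
}
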
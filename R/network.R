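#' Assemble a pedigree network
#'
#' Collects PO and FS edges (with any inferred directions) and accepted
#' trios into one network object. Trios are encoded as their two directed
#' parental edges sharing a `trio_id`.
#'
#' @param po_edges Directed/undirected PO edges from [infer_directions()]
#'   (or [find_po_duos()]).
#' @param fs_edges FS edges from [find_fullsibs()].
#' @param trios Trio table from [find_trios()]; accepted rows assign
#'   `trio_id`s.
#' @param nodes Optional data frame of node metadata (column `id` plus any
#'   others, e.g. accession names).
#' @return Object of class `pedigree_network`: list with `edges`, `nodes`.
#' @export
pedigree_network <- function(po_edges, fs_edges = NULL, trios = NULL,
                             nodes = NULL) {
  cols <- c("id1", "id2", "relation", "parent", "child", "direction_evidence",
            "k0", "k1", "k2", "kinship", "duo_errors", "trio_id")
  pad <- function(e) {
    if (is.null(e) || !nrow(e)) return(NULL)
    for (cl in setdiff(cols, names(e)))
      e[[cl]] <- if (cl %in% c("duo_errors")) NA_integer_ else NA_character_
    e[cols]
  }
  po <- pad(po_edges)
  if (!is.null(po) && !is.null(trios) && nrow(trios)) {
    acc <- trios[trios$accepted, , drop = FALSE]
    if (nrow(acc)) {
      acc$trio_id <- sprintf("trio%03d", seq_len(nrow(acc)))
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      ek <- key(po$id1, po$id2)
      for (r in seq_len(nrow(acc))) {
        for (par in c(acc$parent1[r], acc$parent2[r])) {
          i <- which(ek == key(acc$offspring[r], par))
          if (length(i) == 1) po$trio_id[i] <- acc$trio_id[r]
        }
      }
    }
  }
  edges <- do.call(rbind, Filter(Negate(is.null), list(po, pad(fs_edges))))
  if (is.null(edges)) {
    edges <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(edges) <- cols
  }
  if (any(edges$id1 == edges$id2)) stop("self-edge in pedigree network")
  key <- paste(pmin(edges$id1, edges$id2), pmax(edges$id1, edges$id2),
               edges$relation)
  if (anyDuplicated(key)) stop("duplicate edge for a pair/relation")
  ids <- unique(c(edges$id1, edges$id2,
                  if (!is.null(nodes)) nodes$id))
  nd <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(nodes)) nd <- merge(nd, nodes, by = "id", all.x = TRUE, sort = TRUE)
  structure(list(edges = edges, nodes = nd), class = "pedigree_network")
}

#' @export
print.pedigree_network <- function(x, ...) {
  cat("pedigree_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$relation)
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
    cat("  directed:", sum(!is.na(x$edges$parent)), "of",
        sum(x$edges$relation == "PO"), "PO edges\n")
  }
  invisible(x)
}

# igraph view of the network: directed graph; undirected relations are kept
# as a single arc with edge attribute directed = FALSE.
.network_igraph <- function(net) {
  e <- net$edges
  from <- ifelse(!is.na(e$parent), e$parent, e$id1)
  to <- ifelse(!is.na(e$parent), e$child, e$id2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, relation = e$relation,
               directed = as.integer(!is.na(e$parent)),
               evidence = ifelse(is.na(e$direction_evidence), "",
                                 e$direction_evidence),
               trio_id = ifelse(is.na(e$trio_id), "", e$trio_id),
               kinship = e$kinship, stringsAsFactors = FALSE),
    directed = TRUE, vertices = net$nodes)
  g
}

#' Export a pedigree network
#'
#' `edge_tsv` is lossless (all support columns; read back with
#' [read_network()]); `graphml` and `dot` carry relation type, direction
#' flag, evidence and node metadata for downstream graph tools.
#'
#' @param net A [pedigree_network()].
#' @param path Output file.
#' @param format `"edge_tsv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- .network_igraph(net)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read back an edge-TSV network export
#'
#' @param path File written by [export_network()] with format `edge_tsv`.
#' @param nodes Optional node metadata to reattach.
#' @return A [pedigree_network()].
#' @export
read_network <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (cl in c("id1", "id2", "relation", "parent", "child",
               "direction_evidence", "trio_id"))
    if (cl %in% names(e)) e[[cl]] <- as.character(e[[cl]])
  net <- structure(list(edges = e, nodes = NULL), class = "pedigree_network")
  ids <- unique(c(e$id1, e$id2, if (!is.null(nodes)) nodes$id))
  nd <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(nodes)) nd <- merge(nd, nodes, by = "id", all.x = TRUE, sort = TRUE)
  net$nodes <- nd
  net
}
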
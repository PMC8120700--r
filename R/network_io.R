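#' Construct a PPI network from an edge table
#'
#' Builds an undirected simple graph over protein identifiers. Self-loops and
#' duplicate edges (in either orientation) are removed; isolated nodes may be
#' supplied through `nodes`.
#'
#' @param edges a two-column character matrix or data frame of interacting
#'   protein pairs, one interaction per row.
#' @param nodes optional character vector of node identifiers; the final node
#'   set is the union of `nodes` and all edge endpoints. Allows isolated
#'   proteins.
#' @return an object of class `ppi_network` with components `nodes` (sorted
#'   character vector), `edges` (data frame with columns `a`, `b`, each edge
#'   stored with the lexicographically smaller identifier first, rows sorted)
#'   and `graph` (the underlying [igraph] graph).
#' @seealso [read_ppi()], [write_ppi()]
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.null(dim(edges)) || ncol(edges) < 2L) {
    if (length(edges) == 0L) {
      edges <- matrix(character(), ncol = 2L)
    } else {
      stop("`edges` must have two columns of protein identifiers")
    }
  }
  a <- as.character(edges[[1L]] %||% edges[, 1L])
  b <- as.character(edges[[2L]] %||% edges[, 2L])
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edf <- data.frame(a = lo[!dup], b = hi[!dup], stringsAsFactors = FALSE)
  edf <- edf[order(edf$a, edf$b), , drop = FALSE]
  rownames(edf) <- NULL
  node_set <- sort(unique(c(as.character(nodes), edf$a, edf$b)))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = node_set)
  structure(list(nodes = node_set, edges = edf, graph = g),
            class = "ppi_network")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI network from an edge-list file
#'
#' Parses a whitespace- or tab-separated edge list (DIP/BioGRID-style export
#' after identifier conversion). The first two fields of each line are the
#' interacting protein identifiers; further columns are ignored. Lines
#' starting with `#` are comments. Self-interactions and repeated
#' interactions (in either orientation) are dropped, and the number of
#' dropped lines is reported via [message()].
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network] object.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) stop("cannot read PPI file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("line %d of '%s' has fewer than 2 fields",
                 idx[which(nf < 2L)[1L]], path))
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  # keep every mentioned protein, even if all its lines are dropped
  net <- ppi_network(data.frame(a, b, stringsAsFactors = FALSE),
                     nodes = unique(c(a, b)))
  dropped <- length(a) - nrow(net$edges)
  if (dropped > 0L) {
    message(sprintf("read_ppi: dropped %d self-interaction/duplicate line(s)",
                    dropped))
  }
  net
}

#' Write a PPI network as a canonical two-column edge list
#'
#' Each edge is emitted with the lexicographically smaller identifier first
#' and rows sorted, so equal networks serialize byte-identically.
#'
#' @param net a [ppi_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.node_index <- function(net, ids) {
  ix <- match(ids, net$nodes)
  if (anyNA(ix)) stop("unknown protein id(s): ",
                      paste(ids[is.na(ix)], collapse = ", "))
  ix
}

#' Degree of proteins in a PPI network
#'
#' @param net a [ppi_network].
#' @param ids protein identifier(s); defaults to all nodes.
#' @return named integer vector of distinct-neighbour counts.
#' @export
ppi_degree <- function(net, ids = net$nodes) {
  stopifnot(inherits(net, "ppi_network"))
  ix <- .node_index(net, ids)
  d <- igraph::degree(net$graph)[ix]
  names(d) <- ids
  d
}

#' Neighbour identifiers of a protein
#'
#' @param net a [ppi_network].
#' @param id a protein identifier.
#' @return character vector of neighbouring protein identifiers.
#' @export
ppi_neighbors <- function(net, id) {
  ix <- .node_index(net, id)
  names(igraph::neighbors(net$graph, ix))
}

#' Number of common neighbours of two proteins
#'
#' For an interacting pair this is the number of triangles the edge
#' participates in.
#'
#' @param net a [ppi_network].
#' @param i,j distinct protein identifiers.
#' @return nonnegative integer `|D_i intersect D_j|`.
#' @export
common_neighbor_count <- function(net, i, j) {
  if (identical(i, j)) stop("common_neighbor_count requires i != j")
  length(intersect(ppi_neighbors(net, i), ppi_neighbors(net, j)))
}
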
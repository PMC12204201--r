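#' Read an interaction network from a file
#'
#' Parses a protein interaction network (PIN) from one of three plain-text
#' dialects and returns a simple undirected [igraph::igraph] graph. Edge
#' direction in the source file is discarded, duplicate edges (including
#' reversed duplicates) are collapsed, and self-loops are dropped with a
#' warning: the entropy calculation treats interactions as symmetric
#' neighbourhood relations.
#'
#' Supported formats:
#' \describe{
#'   \item{`edgelist`}{two whitespace-separated columns; lines starting with
#'     `#` are ignored.}
#'   \item{`sif`}{`node1 relation node2`; the relation label is ignored.}
#'   \item{`string_links`}{the STRING protein-links dialect with header
#'     `protein1 protein2 combined_score` (score 0--1000). Only the network
#'     structure is read here; use [load_string_scores()] for the scores.}
#' }
#'
#' @param path path to the network file.
#' @param format one of `"edgelist"`, `"sif"`, `"string_links"`.
#' @param mapping optional identifier harmonisation table: a two-column
#'   data.frame (or path to a two-column TSV) mapping source identifiers to
#'   target identifiers (e.g. STRING ENSP ids to gene symbols). Unmapped
#'   identifiers are kept as-is.
#' @param name label stored as the graph's `name` attribute.
#' @return a simple undirected igraph object.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B C", "C A"), f)
#' net <- read_network(f, "edgelist")
#' igraph::ecount(net)
read_network <- function(path, format = c("edgelist", "sif", "string_links"),
                         mapping = NULL, name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (format == "string_links") {
    if (length(lines) == 0L || !grepl("^\\s*protein1\\s+protein2\\s+combined_score",
                                      lines[1])) {
      stop("string_links file must start with header 'protein1 protein2 combined_score': ",
           path)
    }
    keep[1] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no interaction records in file: ", path)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nfield <- lengths(fields)
  want <- switch(format, edgelist = 2L, sif = 3L, string_links = 3L)
  bad <- which(nfield < want)
  if (length(bad)) {
    stop("malformed line ", idx[bad[1]], " in ", path, ": '",
         lines[idx[bad[1]]], "' (expected ", want, " fields)")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", if (format == "sif") 3L else 2L)
  if (format == "string_links") {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(sc) || any(sc < 0 | sc > 1000)) {
      stop("combined_score outside 0-1000 in ", path)
    }
  }
  if (!is.null(mapping)) {
    map <- if (is.character(mapping)) {
      read.table(mapping, header = FALSE, sep = "\t",
                 col.names = c("from", "to"), colClasses = "character")
    } else {
      stats::setNames(as.data.frame(mapping)[, 1:2], c("from", "to"))
    }
    lut <- stats::setNames(as.character(map$to), as.character(map$from))
    a <- ifelse(a %in% names(lut), lut[a], a)
    b <- ifelse(b %in% names(lut), lut[b], b)
  }
  network_from_edges(a, b, name = name)
}

# build a simple undirected graph from endpoint vectors; warns on self-loops
network_from_edges <- function(a, b, nodes = NULL, name = "network") {
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  key <- edge_key(a, b)
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  verts <- unique(c(nodes, a, b))
  if (any(!nzchar(verts))) stop("empty node identifier")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(match(a, verts), match(b, verts)))
  }
  igraph::graph_attr(g, "name") <- name
  g
}

# edge keys of a graph, canonical order
graph_edge_keys <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  edge_key(el[, 1], el[, 2])
}

#' Write a network as a two-column edge list
#'
#' @param net an igraph network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  write.table(el, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union and intersection of interaction networks
#'
#' Combines PINs drawn from different databases. The union keeps every node
#' and every edge seen in any input; the intersection keeps edges present in
#' all inputs, and drops nodes left isolated (a node only matters to the
#' entropy calculation through its interactions).
#'
#' @param networks non-empty list of igraph networks.
#' @param name label for the combined network.
#' @return an igraph network.
#' @export
network_union <- function(networks, name = "union") {
  if (!length(networks)) stop("empty network list")
  nodes <- unique(unlist(lapply(networks, function(g) igraph::V(g)$name)))
  el <- do.call(rbind, lapply(networks, igraph::as_edgelist, names = TRUE))
  network_from_edges(el[, 1], el[, 2], nodes = nodes, name = name)
}

#' @rdname network_union
#' @export
network_intersection <- function(networks, name = "intersection") {
  if (!length(networks)) stop("empty network list")
  keys <- lapply(networks, graph_edge_keys)
  common <- Reduce(intersect, keys)
  if (!length(common)) {
    return(network_from_edges(character(0), character(0), name = name))
  }
  ends <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  network_from_edges(ends[, 1], ends[, 2], name = name)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component of the
#' network. The equilibrium entropy rate is defined through the stationary
#' distribution of the expression-weighted walk, which only exists on a
#' connected graph, so it is always computed on this component. Ties between
#' equally large components are broken in favour of the component whose
#' sorted node-name list is lexicographically smallest.
#'
#' @param net a non-empty igraph network.
#' @return the induced subgraph on the largest component.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # components are disjoint, so the smallest member name decides the tie
    first <- vapply(big, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, "")
    big <- big[order(first)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Degree histogram of a network
#'
#' Tabulates node degrees (degree >= 1 only; isolated nodes carry no
#' interaction information).
#'
#' @param net a non-empty igraph network.
#' @return data.frame with columns `degree` and `count`.
#' @export
degree_histogram <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  d <- igraph::degree(net)
  d <- d[d >= 1]
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

# expand a degree histogram (or pass a raw degree vector through)
degrees_from_input <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("degree", "count") %in% names(x)))
    rep(x$degree, x$count)
  } else {
    as.numeric(x)
  }
}
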
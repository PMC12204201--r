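#' Edge reliability score table
#'
#' Container for per-interaction reliability scores in `[0, 1]`, keyed by
#' unordered node pair. All scoring methods (topological, semantic, STRING)
#' emit this structure, and [filter_network()] consumes it.
#'
#' @param node1,node2 edge endpoint identifiers.
#' @param score numeric scores in `[0, 1]`.
#' @param method label of the scoring method.
#' @return data.frame of class `reliability_scores` with columns `node1`,
#'   `node2` (canonically ordered so `node1 <= node2`), `score`, and a
#'   `method` attribute.
#' @export
reliability_scores <- function(node1, node2, score, method = "unknown") {
  stopifnot(length(node1) == length(node2), length(node1) == length(score))
  if (length(score) && (any(score < 0) || any(score > 1))) {
    stop("reliability scores must lie in [0, 1]")
  }
  df <- data.frame(node1 = pmin(node1, node2), node2 = pmax(node1, node2),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (anyDuplicated(edge_key(df$node1, df$node2))) {
    stop("duplicate edge in score table")
  }
  attr(df, "method") <- method
  class(df) <- c("reliability_scores", "data.frame")
  df
}

score_lookup <- function(scores, a, b) {
  i <- match(edge_key(a, b), edge_key(scores$node1, scores$node2))
  scores$score[i]
}

#' Topological edge-reliability scores
#'
#' Scores each existing edge (i, j) by the similarity of the endpoints'
#' neighbourhoods, on the premise that genuine interactors share partners:
#' \describe{
#'   \item{`jaccard`}{`|A \ B| / |A u B|` on neighbour sets excluding the
#'     endpoints themselves (0 when both sets are empty).}
#'   \item{`dice`}{Czekanowski-Dice `1 - |Int_i delta Int_j| /
#'     (|Int_i u Int_j| + |Int_i n Int_j|)` with `Int_x = N_x u {x}`, so
#'     the interaction itself counts as shared context.}
#'   \item{`invlog`}{`sum over common neighbours z of 1 / log(k_z)`
#'     (common neighbours have degree >= 2, so the log is positive),
#'     min-max rescaled over the scored edges into `[0, 1]`.}
#' }
#'
#' @param net a non-empty igraph network.
#' @param method one of `"jaccard"`, `"dice"`, `"invlog"`.
#' @return a `reliability_scores` table with one row per network edge.
#' @export
topological_scores <- function(net, method = c("jaccard", "dice", "invlog")) {
  method <- match.arg(method)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) stop("network has no edges")
  nodes <- igraph::V(net)$name
  nbr <- lapply(seq_along(nodes), function(i) {
    nodes[igraph::neighbors(net, i)]
  })
  names(nbr) <- nodes
  deg <- igraph::degree(net)
  names(deg) <- nodes
  raw <- vapply(seq_len(nrow(el)), function(r) {
    i <- el[r, 1]; j <- el[r, 2]
    ni <- nbr[[i]]; nj <- nbr[[j]]
    switch(method,
      jaccard = {
        a <- setdiff(ni, c(i, j)); b <- setdiff(nj, c(i, j))
        u <- union(a, b)
        if (!length(u)) 0 else length(intersect(a, b)) / length(u)
      },
      dice = {
        a <- union(ni, i); b <- union(nj, j)
        inter <- length(intersect(a, b)); uni <- length(union(a, b))
        1 - (uni - inter) / (uni + inter)
      },
      invlog = {
        z <- intersect(ni, nj)
        if (!length(z)) 0 else sum(1 / log(deg[z]))
      })
  }, 0)
  if (method == "invlog") {
    rng <- range(raw)
    if (rng[2] > rng[1]) {
      raw <- (raw - rng[1]) / (rng[2] - rng[1])
    } else {
      warning("constant inverse-log scores: rescaling degenerate, all set to 1")
      raw <- rep(1, length(raw))
    }
  }
  reliability_scores(el[, 1], el[, 2], raw, method = method)
}

#' Load STRING combined confidence scores
#'
#' Reads a STRING protein-links table (`protein1 protein2 combined_score`,
#' space-separated, integer scores 0--1000) and rescales the combined
#' scores to `[0, 1]`. Duplicate pairs keep the maximum score with a
#' warning.
#'
#' @param path path to the protein-links file.
#' @param scale divisor applied to the raw scores (STRING uses 1000).
#' @return a `reliability_scores` table with method `"string"`.
#' @export
load_string_scores <- function(path, scale = 1000) {
  if (!file.exists(path)) stop("score file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*protein1\\s+protein2\\s+combined_score",
                               lines[1])) {
    stop("missing header 'protein1 protein2 combined_score' in ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no score records in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed line ", bad[1] + 1L, " in ", path)
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(sc)) stop("non-numeric combined_score in ", path)
  if (any(sc < 0 | sc > scale)) {
    stop("combined_score outside 0-", scale, " in ", path)
  }
  key <- edge_key(a, b)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate pair(s): keeping maximum score")
    mx <- tapply(sc, key, max)
    first <- !duplicated(key)
    sc <- as.numeric(mx[key[first]])
    a <- a[first]; b <- b[first]
  }
  reliability_scores(a, b, sc / scale, method = "string")
}

#' Filter a network by reliability scores
#'
#' Keeps edges whose reliability score is at least `threshold`. Edges
#' missing from the score table are treated as score 0 (an interaction
#' with no supporting evidence is exactly the suspected false positive the
#' filtering targets) and are therefore removed at any positive threshold.
#' Nodes left isolated are dropped. Removal statistics are attached as the
#' `filter_stats` graph attribute.
#'
#' @param net an igraph network.
#' @param scores a `reliability_scores` table.
#' @param threshold score cutoff in `[0, 1]`.
#' @return the filtered igraph network; `graph_attr(., "filter_stats")`
#'   holds `n_input`, `n_kept`, `n_removed`, `n_unscored`, `threshold`.
#' @export
filter_network <- function(net, scores, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  el <- igraph::as_edgelist(net, names = TRUE)
  sc <- score_lookup(scores, el[, 1], el[, 2])
  n_unscored <- sum(is.na(sc))
  sc[is.na(sc)] <- 0
  keep <- sc >= threshold
  g <- igraph::delete_edges(net, which(!keep))
  iso <- which(igraph::degree(g) == 0)
  if (length(iso)) g <- igraph::delete_vertices(g, iso)
  if (igraph::ecount(g) == 0L) {
    warning("all edges removed at threshold ", threshold)
  }
  igraph::graph_attr(g, "filter_stats") <- list(
    n_input = nrow(el), n_kept = sum(keep), n_removed = sum(!keep),
    n_unscored = n_unscored, threshold = threshold)
  g
}
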
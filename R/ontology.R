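#' Read an ontology from an OBO file
#'
#' Minimal OBO parser for the needs of semantic edge scoring: `[Term]`
#' stanzas with `id`, `is_a` and `relationship: part_of` lines are kept
#' (obsolete terms skipped, other relationship types dropped with a
#' warning). The result must be a single-rooted directed acyclic graph.
#'
#' @param path path to an OBO file.
#' @return an object of class `ontology`: list with `terms` (character),
#'   `edges` (data.frame `child`, `parent`, `relation`), `root`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  child <- character(0); parent <- character(0); rel <- character(0)
  cur <- NA_character_; in_term <- FALSE; obsolete <- FALSE
  dropped <- 0L
  flush <- function() {
    if (in_term && !obsolete && !is.na(cur)) terms[length(terms) + 1L] <<- cur
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- NA; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^is_obsolete: *true", ln)) obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      child <- c(child, cur); parent <- c(parent, trimws(sub("^is_a:", "", ln)))
      rel <- c(rel, "is_a")
    } else if (grepl("^relationship:", ln)) {
      parts <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        child <- c(child, cur); parent <- c(parent, parts[2])
        rel <- c(rel, "part_of")
      } else dropped <- dropped + 1L
    }
  }
  flush()
  if (dropped > 0) warning(dropped, " relationship line(s) of unsupported type ignored")
  keep <- child %in% terms & parent %in% terms
  ontology(terms, data.frame(child = child[keep], parent = parent[keep],
                             relation = rel[keep], stringsAsFactors = FALSE))
}

#' Construct and validate an ontology object
#'
#' @param terms character vector of term identifiers.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @return an `ontology` object (see [read_obo()]).
#' @export
ontology <- function(terms, edges) {
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (!all(edges$relation %in% c("is_a", "part_of"))) {
    stop("relations must be is_a or part_of")
  }
  if (!all(c(edges$child, edges$parent) %in% terms)) {
    stop("edge endpoints must be declared terms")
  }
  roots <- setdiff(terms, edges$child)
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root, found ", length(roots))
  }
  ont <- structure(list(terms = terms, edges = edges, root = roots),
                   class = "ontology")
  ont$order <- topological_order(ont)   # also proves acyclicity
  anc <- ancestor_sets(ont)
  if (!all(vapply(anc, function(a) ont$root %in% a, TRUE))) {
    stop("every term must reach the root")
  }
  ont$ancestors <- anc
  ont
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d relations, root %s\n",
              length(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

# Kahn topological sort, parents before children; errors on cycles
topological_order <- function(ont) {
  terms <- ont$terms
  indeg <- stats::setNames(integer(length(terms)), terms)
  tab <- table(ont$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  kids_of <- split(ont$edges$child, ont$edges$parent)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    out <- c(out, t)
    for (ch in kids_of[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) stop("ontology contains a cycle")
  out
}

# list term -> character vector of ancestors (inclusive of the term itself)
ancestor_sets <- function(ont) {
  parents_of <- split(ont$edges$parent, ont$edges$child)
  anc <- list()
  for (t in ont$order) {           # parents appear before children
    ps <- parents_of[[t]]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Read gene-to-term annotations
#'
#' Reads direct gene annotations either from a two-column TSV (`gene`,
#' `term`) or from a GAF 2.x file (columns 2 and 5; `!` comment lines
#' skipped). Annotations to unknown terms are dropped with a warning when
#' an ontology is supplied.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param ontology optional `ontology` object used to validate terms.
#' @return named list mapping gene identifier to a character vector of
#'   directly annotated terms.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"), ontology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gaf") {
    df <- read.table(path, header = FALSE, sep = "\t", comment.char = "!",
                     quote = "", colClasses = "character")
    if (ncol(df) < 5) stop("GAF file needs at least 5 columns")
    df <- df[, c(2, 5)]
  } else {
    df <- read.table(path, header = FALSE, sep = "\t",
                     colClasses = "character")
    if (ncol(df) < 2) stop("annotation TSV needs two columns")
    df <- df[, 1:2]
  }
  names(df) <- c("gene", "term")
  if (!is.null(ontology)) {
    bad <- !(df$term %in% ontology$terms)
    if (any(bad)) {
      warning(sum(bad), " annotation(s) to unknown terms dropped")
      df <- df[!bad, , drop = FALSE]
    }
  }
  lapply(split(df$term, df$gene), unique)
}

#' Information content of ontology terms
#'
#' Applies true-path propagation (a gene annotated to a term is implicitly
#' annotated to all its ancestors) and computes each term's annotation
#' probability `p(t)` = fraction of annotated genes carrying `t`, and its
#' information content `IC(t) = -log p(t)` in nats. The root covers every
#' annotated gene, so `IC(root) = 0`; terms with no propagated annotation
#' are excluded with a warning.
#'
#' @param ont an `ontology` object.
#' @param ann an annotation map as from [read_annotations()].
#' @return data.frame with columns `term`, `p`, `ic`.
#' @export
information_content <- function(ont, ann) {
  if (!length(ann)) stop("need at least one annotated gene")
  bad <- !unlist(ann) %in% ont$terms
  if (any(bad)) stop("annotations reference unknown terms")
  # propagated term set per gene
  prop <- lapply(ann, function(ts) {
    unique(unlist(ont$ancestors[ts], use.names = FALSE))
  })
  counts <- table(unlist(prop, use.names = FALSE))
  n_genes <- length(ann)
  absent <- setdiff(ont$terms, names(counts))
  if (length(absent)) {
    warning(length(absent), " term(s) with no propagated annotations excluded")
  }
  p <- as.numeric(counts) / n_genes
  data.frame(term = names(counts), p = p, ic = -log(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

ic_lookup <- function(ic, term) {
  i <- match(term, ic$term)
  if (is.na(i)) stop("term not in information-content table: ", term)
  i
}

#' Semantic similarity between two ontology terms
#'
#' Computes a similarity in `[0, 1]` between two terms. The IC-based
#' measures use the most informative common ancestor (MICA): Resnik
#' (`IC(MICA)` normalised by the maximum IC of the corpus), Lin
#' (`2 IC(MICA) / (IC(t1) + IC(t2))`, 0 when both ICs are 0), Jiang-Conrath
#' (`1 - min(1, IC(t1) + IC(t2) - 2 IC(MICA))`), and Schlicker's relevance
#' measure (`Lin * (1 - p(MICA))`). Wang's measure is graph-based: it
#' propagates semantic contributions up each term's ancestor DAG with
#' factors 0.8 (`is_a`) and 0.6 (`part_of`) and compares aggregated
#' S-values over shared ancestors.
#'
#' @param t1,t2 term identifiers.
#' @param ont an `ontology` object.
#' @param ic an [information_content()] table (required for all methods
#'   except `"wang"`).
#' @param method one of `"resnik"`, `"lin"`, `"jiang"`, `"schlicker"`,
#'   `"wang"`.
#' @param wang_weights named contribution factors for Wang's method.
#' @return similarity score in `[0, 1]`.
#' @export
term_similarity <- function(t1, t2, ont, ic = NULL,
                            method = c("resnik", "lin", "jiang", "schlicker",
                                       "wang"),
                            wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  method <- match.arg(method)
  if (!(t1 %in% ont$terms) || !(t2 %in% ont$terms)) {
    stop("both terms must be in the ontology")
  }
  if (method == "wang") {
    return(wang_similarity(t1, t2, ont, wang_weights))
  }
  if (is.null(ic)) stop("IC-based methods need an information-content table")
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  common <- common[common %in% ic$term]
  if (!length(common)) return(0)
  mica_i <- ic_lookup(ic, common[which.max(ic$ic[match(common, ic$term)])])
  ic_mica <- ic$ic[mica_i]
  switch(method,
    resnik = {
      max_ic <- max(ic$ic)
      if (max_ic == 0) 0 else ic_mica / max_ic
    },
    lin = {
      denom <- ic$ic[ic_lookup(ic, t1)] + ic$ic[ic_lookup(ic, t2)]
      if (denom == 0) 0 else 2 * ic_mica / denom
    },
    jiang = {
      dist <- ic$ic[ic_lookup(ic, t1)] + ic$ic[ic_lookup(ic, t2)] - 2 * ic_mica
      1 - min(1, dist)
    },
    schlicker = {
      denom <- ic$ic[ic_lookup(ic, t1)] + ic$ic[ic_lookup(ic, t2)]
      lin <- if (denom == 0) 0 else 2 * ic_mica / denom
      lin * (1 - ic$p[mica_i])
    })
}

# Wang S-values: S_A(A) = 1; S_A(t) = max over children c of t in DAG_A of
# w(t<-c) * S_A(c); computed children-before-parents
wang_svalues <- function(t, ont, weights) {
  dag <- ont$ancestors[[t]]
  sv <- stats::setNames(numeric(length(dag)), dag)
  sv[t] <- 1
  e <- ont$edges[ont$edges$child %in% dag & ont$edges$parent %in% dag, ]
  for (term in rev(ont$order[ont$order %in% dag])) {   # children before parents
    if (term == t) next
    kids <- e[e$parent == term, ]
    if (!nrow(kids)) next
    sv[term] <- max(weights[kids$relation] * sv[kids$child])
  }
  sv
}

wang_similarity <- function(t1, t2, ont, weights) {
  s1 <- wang_svalues(t1, ont, weights)
  s2 <- wang_svalues(t2, ont, weights)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

#' Semantic similarity between two genes
#'
#' Combines term-level similarities into a gene-level score by the
#' best-match average: for each term of one gene take its best match in the
#' other gene's term set, average these maxima, and average the two
#' directions.
#'
#' @param g1,g2 gene identifiers.
#' @param ann annotation map (direct annotations).
#' @param ont an `ontology` object.
#' @param ic an [information_content()] table (not needed for `"wang"`).
#' @param method term-similarity method, see [term_similarity()].
#' @return similarity score in `[0, 1]`.
#' @export
gene_similarity <- function(g1, g2, ann, ont, ic = NULL, method = "lin") {
  ts1 <- ann[[g1]]; ts2 <- ann[[g2]]
  if (is.null(ts1) || is.null(ts2)) stop("both genes must be annotated")
  simmat <- outer(seq_along(ts1), seq_along(ts2),
                  Vectorize(function(i, j) {
                    term_similarity(ts1[i], ts2[j], ont, ic, method)
                  }))
  (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
}

#' Semantic edge-reliability scores for a network
#'
#' Scores every network edge whose endpoints are both annotated with the
#' gene-level semantic similarity; edges with an unannotated endpoint get
#' no score (downstream filtering treats missing scores as 0). Term-pair
#' similarities are cached across edges.
#'
#' @param net an igraph network.
#' @param ann annotation map.
#' @param ont an `ontology` object.
#' @param ic an [information_content()] table (not needed for `"wang"`).
#' @param method term-similarity method, see [term_similarity()].
#' @return a `reliability_scores` data.frame (see [reliability_scores()]).
#' @export
semantic_edge_scores <- function(net, ann, ont, ic = NULL, method = "lin") {
  el <- igraph::as_edgelist(net, names = TRUE)
  ok <- el[, 1] %in% names(ann) & el[, 2] %in% names(ann)
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warning(n_skip, " edge(s) with unannotated endpoint(s) left unscored")
  }
  el <- el[ok, , drop = FALSE]
  cache <- new.env(hash = TRUE, parent = emptyenv())
  tsim <- function(a, b) {
    k <- edge_key(a, b)
    if (!exists(k, envir = cache, inherits = FALSE)) {
      assign(k, term_similarity(a, b, ont, ic, method), envir = cache)
    }
    get(k, envir = cache, inherits = FALSE)
  }
  score <- vapply(seq_len(nrow(el)), function(i) {
    ts1 <- ann[[el[i, 1]]]; ts2 <- ann[[el[i, 2]]]
    simmat <- outer(seq_along(ts1), seq_along(ts2),
                    Vectorize(function(p, q) tsim(ts1[p], ts2[q])))
    (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
  }, 0)
  reliability_scores(el[, 1], el[, 2], score, method = method)
}
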
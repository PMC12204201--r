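#' Generate a scale-free interactome
#'
#' Barabasi-Albert preferential attachment: starting from `m` unconnected
#' seed nodes, each new node attaches to `m` distinct existing nodes with
#' probability proportional to their current degree (plus one, so the seed
#' nodes can be chosen). The result is a connected simple graph with
#' exactly `m * (n_nodes - m)` edges and an approximately power-law degree
#' distribution (exponent near 3 for large graphs).
#'
#' @param n_nodes number of nodes (>= 10).
#' @param m edges attached per new node (`m < n_nodes`).
#' @param seed integer seed.
#' @param prefix node-name prefix.
#' @return a connected igraph network with nodes `g1 ... g<n_nodes>`.
#' @export
generate_network <- function(n_nodes = 500L, m = 2L, seed = 1L,
                             prefix = "g") {
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (m < 1 || m >= n_nodes) stop("m must satisfy 1 <= m < n_nodes")
  withr::with_seed(seed, {
    deg <- integer(n_nodes)
    src <- integer(m * (n_nodes - m))
    dst <- integer(m * (n_nodes - m))
    e <- 0L
    for (v in (m + 1L):n_nodes) {
      existing <- seq_len(v - 1L)
      w <- deg[existing] + 1
      targets <- sample(existing, m, prob = w)
      for (t in targets) {
        e <- e + 1L
        src[e] <- v; dst[e] <- t
        deg[v] <- deg[v] + 1L; deg[t] <- deg[t] + 1L
      }
    }
    nodes <- paste0(prefix, seq_len(n_nodes))
    network_from_edges(nodes[src], nodes[dst], nodes = nodes,
                       name = "synthetic")
  })
}

#' Generate two-class expression data
#'
#' Emulates a two-condition expression experiment on a given interactome.
#' Each gene g receives a log-normal baseline `b_g ~ LogNormal(mu, sigma)`
#' shared across samples; each sample value is `b_g * exp(N(0,
#' sigma_noise))`. Two designs are available:
#' \describe{
#'   \item{`"dual_ko"`}{class 2 samples are dual knockouts: in each sample
#'     a fresh pair of genes (`n_knockout` of them, redrawn per sample)
#'     from the largest connected component is set to one tenth of the
#'     sample's smallest positive value, matching the zero-replacement
#'     epsilon used at integration time so the walk stays defined.}
#'   \item{`"shift"`}{class 2 samples scale a random fraction
#'     `frac_affected` of genes by `fold_change`.}
#' }
#'
#' @param net igraph network whose node names become the gene set.
#' @param n_samples samples per class.
#' @param design `"dual_ko"` or `"shift"`.
#' @param mu,sigma log-normal baseline parameters (log scale).
#' @param sigma_noise per-sample multiplicative noise (log scale).
#' @param n_knockout genes knocked out per dual-KO sample.
#' @param frac_affected,fold_change shift-design parameters.
#' @param seed integer seed.
#' @param class_names labels for the two classes.
#' @return list with `expr` (genes x 2*n_samples matrix), `classes`
#'   (character vector of class labels per sample), `ko_genes` (list of
#'   knocked-out genes per class-2 sample, `dual_ko` design only).
#' @export
generate_expression <- function(net, n_samples = 20L,
                                design = c("dual_ko", "shift"),
                                mu = 2, sigma = 0.5, sigma_noise = 0.1,
                                n_knockout = 2L, frac_affected = 0.1,
                                fold_change = 3, seed = 1L,
                                class_names = NULL) {
  design <- match.arg(design)
  if (is.null(class_names)) {
    class_names <- if (design == "dual_ko") c("wildtype", "dual_ko")
                   else c("condition_a", "condition_b")
  }
  genes <- igraph::V(net)$name
  n_genes <- length(genes)
  lcc_genes <- igraph::V(largest_connected_component(net))$name
  if (design == "dual_ko" && length(lcc_genes) < n_knockout) {
    stop("largest connected component smaller than the knockout demand")
  }
  withr::with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = mu, sdlog = sigma)
    n_total <- 2L * n_samples
    expr <- matrix(0, n_genes, n_total,
                   dimnames = list(genes, paste0("s", seq_len(n_total))))
    for (s in seq_len(n_total)) {
      expr[, s] <- baseline * exp(stats::rnorm(n_genes, 0, sigma_noise))
    }
    classes <- rep(class_names, each = n_samples)
    ko_genes <- NULL
    if (design == "dual_ko") {
      ko_genes <- vector("list", n_samples)
      for (s in seq_len(n_samples)) {
        col <- n_samples + s
        ko <- sample(lcc_genes, n_knockout)
        eps <- min(expr[, col]) / 10
        expr[ko, col] <- eps
        ko_genes[[s]] <- ko
      }
      names(ko_genes) <- colnames(expr)[n_samples + seq_len(n_samples)]
    } else {
      affected <- sample(genes, max(1L, round_half_up(frac_affected * n_genes)))
      for (s in seq_len(n_samples)) {
        expr[affected, n_samples + s] <- expr[affected, n_samples + s] * fold_change
      }
    }
    list(expr = expr, classes = classes, ko_genes = ko_genes)
  })
}

#' Generate a toy ontology with gene annotations
#'
#' Builds a random single-rooted DAG of `n_terms` terms arranged in
#' levels: each non-root term draws one or two parents from the previous
#' levels, with relation `is_a` (probability 0.8) or `part_of`. Each gene
#' is annotated to one to three leaf-or-deep terms, so every gene has at
#' least one annotation.
#'
#' @param n_terms number of terms (>= 3).
#' @param genes character vector of gene identifiers to annotate.
#' @param depth number of DAG levels below the root.
#' @param seed integer seed.
#' @return list with `ontology` (an `ontology` object) and `annotations`
#'   (named list gene -> terms).
#' @export
generate_ontology <- function(n_terms = 30L, genes = paste0("g", 1:20),
                              depth = 4L, seed = 1L) {
  if (n_terms < 3) stop("n_terms must be >= 3")
  withr::with_seed(seed, {
    terms <- sprintf("T%04d", seq_len(n_terms))
    level <- c(0L, sort(sample(seq_len(depth), n_terms - 1L, replace = TRUE)))
    child <- character(0); parent <- character(0); rel <- character(0)
    for (i in seq(2L, n_terms)) {
      cand <- which(level < level[i])
      np <- min(length(cand), sample(1:2, 1))
      ps <- sample(cand, np)
      child <- c(child, rep(terms[i], np))
      parent <- c(parent, terms[ps])
      rel <- c(rel, sample(c("is_a", "part_of"), np, replace = TRUE,
                           prob = c(0.8, 0.2)))
    }
    ont <- ontology(terms, data.frame(child = child, parent = parent,
                                      relation = rel,
                                      stringsAsFactors = FALSE))
    deep <- terms[level >= max(1L, max(level) - 1L)]
    ann <- lapply(genes, function(g) {
      unique(sample(deep, sample(1:3, 1), replace = TRUE))
    })
    names(ann) <- genes
    list(ontology = ont, annotations = ann)
  })
}

#' Generate an edge-reliability score table with known ground truth
#'
#' Assigns Beta-distributed reliability scores to a network whose edges
#' are partitioned into true and spurious interactions: true edges draw
#' from `Beta(8, 2)` (mean 0.8) and spurious edges from `Beta(2, 8)`
#' (mean 0.2), emulating an informative confidence score such as STRING's
#' around a contaminated network.
#'
#' @param net igraph network to score.
#' @param true_edges,spurious_edges two-column matrices (or data.frames)
#'   of edge endpoints partitioning the network's edge set.
#' @param seed integer seed.
#' @param shape_true,shape_spurious Beta shape pairs.
#' @return a `reliability_scores` table covering every network edge.
#' @export
generate_score_table <- function(net, true_edges, spurious_edges, seed = 1L,
                                 shape_true = c(8, 2),
                                 shape_spurious = c(2, 8)) {
  true_edges <- as.matrix(true_edges)
  spurious_edges <- as.matrix(spurious_edges)
  kt <- if (nrow(true_edges)) edge_key(true_edges[, 1], true_edges[, 2]) else character(0)
  ks <- if (nrow(spurious_edges)) edge_key(spurious_edges[, 1], spurious_edges[, 2]) else character(0)
  if (length(intersect(kt, ks))) {
    stop("true and spurious edge sets overlap")
  }
  net_keys <- graph_edge_keys(net)
  if (!setequal(union(kt, ks), net_keys)) {
    stop("edge partition must cover exactly the network's edges")
  }
  withr::with_seed(seed, {
    el <- igraph::as_edgelist(net, names = TRUE)
    keys <- edge_key(el[, 1], el[, 2])
    is_true <- keys %in% kt
    sc <- numeric(length(keys))
    sc[is_true] <- stats::rbeta(sum(is_true), shape_true[1], shape_true[2])
    sc[!is_true] <- stats::rbeta(sum(!is_true), shape_spurious[1],
                                 shape_spurious[2])
    reliability_scores(el[, 1], el[, 2], sc, method = "synthetic")
  })
}

#' Write a toy ontology to OBO format
#'
#' Round-trip support for [read_obo()].
#'
#' @param ont an `ontology` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    e <- ont$edges[ont$edges$child == t, ]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[i]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[i]), con)
      }
    }
  }
  invisible(path)
}

#' Write an annotation map as two-column TSV
#'
#' @param ann named list gene -> terms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(gene = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE))
  write.table(df, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
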
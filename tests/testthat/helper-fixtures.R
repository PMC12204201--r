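# fixture builders and independent oracles shared across the test files

make_net <- function(a, b, nodes = NULL) {
  entropin:::network_from_edges(a, b, nodes = nodes)
}

# path A - B - C
path_net <- function() make_net(c("A", "B"), c("B", "C"))

# star with k leaves around "hub"
star_net <- function(k = 5) make_net(rep("hub", k), paste0("L", seq_len(k)))

# complete graph on n labelled nodes
complete_net <- function(n) {
  pairs <- t(combn(paste0("v", seq_len(n)), 2))
  make_net(pairs[, 1], pairs[, 2])
}

uniform_expr <- function(net, samples = "s1", value = 1) {
  genes <- igraph::V(net)$name
  matrix(value, length(genes), length(samples),
         dimnames = list(genes, samples))
}

# Erdos-Renyi style random simple graph, guaranteed >= 1 edge
random_net <- function(n, p = 0.2) {
  pairs <- t(combn(paste0("n", seq_len(n)), 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  make_net(pairs[keep, 1], pairs[keep, 2], nodes = paste0("n", seq_len(n)))
}

random_expr <- function(net, n_samples = 1) {
  genes <- igraph::V(net)$name
  matrix(stats::rlnorm(length(genes) * n_samples, 1, 0.7),
         length(genes), n_samples,
         dimnames = list(genes, paste0("s", seq_len(n_samples))))
}

# --- oracles ---------------------------------------------------------------

# component sizes by hand-rolled BFS over an edge list (igraph-independent)
bfs_component_sizes <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  nodes <- igraph::V(net)$name
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), c)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  seen <- character(0)
  sizes <- integer(0)
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    sizes <- c(sizes, length(comp))
  }
  sizes
}

# stationary distribution by dense power iteration (oracle for closed form);
# iterates the lazy chain (I + P)/2, which shares the stationary vector but
# is aperiodic, so it converges on bipartite graphs too
power_iteration_pi <- function(P, iters = 100000, tol = 1e-15) {
  P <- as.matrix(P)
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    v2 <- 0.5 * v + 0.5 * as.numeric(v %*% P)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# all ancestors of a term by naive repeated parent expansion
brute_ancestors <- function(term, edges) {
  anc <- term
  repeat {
    more <- edges$parent[edges$child %in% anc]
    new <- setdiff(more, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}

# brute-force IC-based term similarity: enumerate common ancestors explicitly
brute_term_similarity <- function(t1, t2, edges, ic, method) {
  common <- intersect(brute_ancestors(t1, edges), brute_ancestors(t2, edges))
  common <- common[common %in% ic$term]
  if (!length(common)) return(0)
  ics <- ic$ic[match(common, ic$term)]
  ic_mica <- max(ics)
  p_mica <- ic$p[match(common[which.max(ics)], ic$term)]
  ic1 <- ic$ic[match(t1, ic$term)]
  ic2 <- ic$ic[match(t2, ic$term)]
  switch(method,
         resnik = if (max(ic$ic) == 0) 0 else ic_mica / max(ic$ic),
         lin = if (ic1 + ic2 == 0) 0 else 2 * ic_mica / (ic1 + ic2),
         jiang = 1 - min(1, ic1 + ic2 - 2 * ic_mica),
         schlicker = (if (ic1 + ic2 == 0) 0 else 2 * ic_mica / (ic1 + ic2)) *
           (1 - p_mica))
}

# brute-force Wang S-value: max product of edge weights over all upward paths
brute_wang_svalue <- function(from, to, edges, weights) {
  if (from == to) return(1)
  ps <- edges[edges$child == from, ]
  if (!nrow(ps)) return(-Inf)
  best <- -Inf
  for (i in seq_len(nrow(ps))) {
    sub <- brute_wang_svalue(ps$parent[i], to, edges, weights)
    best <- max(best, weights[[ps$relation[i]]] * sub)
  }
  best
}

brute_wang_similarity <- function(t1, t2, edges,
                                  weights = c(is_a = 0.8, part_of = 0.6)) {
  a1 <- brute_ancestors(t1, edges); a2 <- brute_ancestors(t2, edges)
  s1 <- vapply(a1, function(t) brute_wang_svalue(t1, t, edges, weights), 0)
  s2 <- vapply(a2, function(t) brute_wang_svalue(t2, t, edges, weights), 0)
  shared <- intersect(a1, a2)
  if (!length(shared)) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# rank assignments (no ties assumed)
enumerate_wilcox_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# random DAG ontology for oracle-equivalence tests
random_dag <- function(n_terms = 50, depth = 5) {
  terms <- sprintf("R%03d", seq_len(n_terms))
  level <- c(0L, sort(sample(seq_len(depth), n_terms - 1L, replace = TRUE)))
  child <- character(0); parent <- character(0); rel <- character(0)
  for (i in 2:n_terms) {
    cand <- which(level < level[i])
    np <- min(length(cand), sample(1:2, 1))
    ps <- sample(cand, np)
    child <- c(child, rep(terms[i], np))
    parent <- c(parent, terms[ps])
    rel <- c(rel, sample(c("is_a", "part_of"), np, replace = TRUE))
  }
  ontology(terms, data.frame(child = child, parent = parent, relation = rel,
                             stringsAsFactors = FALSE))
}

# random annotation map over the deeper half of a DAG's terms
random_annotations <- function(ont, n_genes = 15) {
  pool <- setdiff(ont$terms, ont$root)
  ann <- lapply(seq_len(n_genes), function(i) {
    unique(sample(pool, sample(1:3, 1)))
  })
  names(ann) <- paste0("gene", seq_len(n_genes))
  ann
}
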
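#' Read an expression matrix
#'
#' Reads a genes x samples expression table (TSV or CSV; first column gene
#' identifiers, header row of sample identifiers). Values must be
#' nonnegative expression intensities.
#'
#' @param path path to the table.
#' @param sep field separator; `"\t"` (default) or `","`. Guessed from the
#'   file extension when `NULL`.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#' @param expr genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  if (anyNA(expr)) stop("expression matrix contains NA values")
  if (any(expr < 0)) stop("expression values must be nonnegative")
  invisible(expr)
}

#' Integrate a network with an expression matrix
#'
#' Restricts a PIN and an expression matrix to their common gene set, drops
#' nodes left without interactions, and replaces zero expression values so
#' the mass-action transition probabilities are everywhere defined. The
#' replacement value is per sample: one tenth of the smallest positive
#' expression value observed in that sample (overridable via `epsilon`).
#'
#' @param net an igraph PIN.
#' @param expr genes x samples nonnegative matrix.
#' @param epsilon optional fixed zero-replacement value (recycled per
#'   sample); default derives it per sample as `min(positive values)/10`.
#' @return an object of class `integrated_system`: list with `graph` (the
#'   restricted PIN), `expr` (gene-aligned expression, zeros replaced),
#'   `epsilon` (per-sample replacement values used).
#' @export
integrate_system <- function(net, expr, epsilon = NULL) {
  validate_expression(expr)
  common <- intersect(igraph::V(net)$name, rownames(expr))
  if (!length(common)) stop("network and expression share no genes")
  g <- igraph::induced_subgraph(net, common)
  iso <- igraph::degree(g) == 0
  if (any(iso)) g <- igraph::delete_vertices(g, which(iso))
  if (igraph::vcount(g) == 0L) {
    stop("no interacting genes left after integration")
  }
  genes <- igraph::V(g)$name
  e <- expr[genes, , drop = FALSE]
  eps <- numeric(ncol(e))
  for (s in seq_len(ncol(e))) {
    pos <- e[, s] > 0
    if (!any(pos)) stop("sample '", colnames(e)[s], "' is all zero")
    eps[s] <- if (is.null(epsilon)) min(e[pos, s]) / 10 else epsilon
    nz <- sum(!pos)
    if (nz > 0) {
      message("sample '", colnames(e)[s], "': ", nz,
              " zero value(s) replaced by ", signif(eps[s], 4))
      e[!pos, s] <- eps[s]
    }
  }
  names(eps) <- colnames(e)
  structure(list(graph = g, expr = e, epsilon = eps),
            class = "integrated_system")
}

#' @export
print.integrated_system <- function(x, ...) {
  cat(sprintf("integrated system: %d genes, %d interactions, %d sample(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              ncol(x$expr)))
  invisible(x)
}

# sparse adjacency of the integrated graph, node order = rownames(expr)
system_adjacency <- function(system) {
  igraph::as_adjacency_matrix(system$graph, sparse = TRUE)
}

#' Mass-action transition matrix for one sample
#'
#' Builds the row-stochastic transition matrix P of the expression-weighted
#' random walk: under the mass-action principle the intensity of the
#' interaction between neighbours i and j in sample s is proportional to
#' the product of their expression values, so
#' `p_ij = E_is E_js / sum_k in N_i E_is E_ks` for j in N_i and 0 otherwise.
#'
#' @param system an [integrate_system()] result.
#' @param sample sample identifier (column of the expression matrix).
#' @return sparse `dgCMatrix` with dimnames = gene identifiers; every row
#'   sums to 1.
#' @export
transition_matrix <- function(system, sample) {
  stopifnot(inherits(system, "integrated_system"))
  if (!sample %in% colnames(system$expr)) stop("unknown sample: ", sample)
  e <- system$expr[, sample]
  A <- system_adjacency(system)
  if (any(Matrix::rowSums(A) == 0)) {
    stop("integrated graph contains an isolated node")  # integrate() forbids
  }
  # p_ij = A_ij e_j / (A e)_i ; the e_i factor cancels within each row
  r <- as.numeric(A %*% e)
  P <- Matrix::Diagonal(x = 1 / r) %*% A %*% Matrix::Diagonal(x = e)
  dimnames(P) <- dimnames(A)
  methods::as(P, "CsparseMatrix")
}

#' Local signalling entropies
#'
#' `local_entropies()` returns the Shannon entropy (nats) of each node's
#' transition distribution, `S_i = -sum_j p_ij log p_ij`, quantifying the
#' promiscuity of the node's signalling. `normalized_local_entropies()`
#' rescales by the maximum attainable value `log(k_i)` for degree `k_i >= 2`
#' so each value lies in `[0, 1]`; degree-1 nodes have a degenerate
#' one-point distribution and are assigned 0.
#'
#' @param P a row-stochastic transition matrix from [transition_matrix()].
#' @param degrees optional per-node degree vector `k_i`; defaults to the
#'   number of nonzero entries in each row of `P`.
#' @return named numeric vector of entropies per node.
#' @export
local_entropies <- function(P) {
  Pt <- methods::as(P, "TsparseMatrix")
  x <- Pt@x
  contrib <- ifelse(x > 0, -x * log(x), 0)
  s <- numeric(nrow(P))
  agg <- tapply(contrib, Pt@i, sum)
  s[as.integer(names(agg)) + 1L] <- agg
  names(s) <- rownames(P)
  s
}

#' @rdname local_entropies
#' @export
normalized_local_entropies <- function(P, degrees = NULL) {
  s <- local_entropies(P)
  if (is.null(degrees)) {
    Pt <- methods::as(P, "TsparseMatrix")
    degrees <- tabulate(Pt@i + 1L, nbins = nrow(P))
  }
  st <- ifelse(degrees >= 2, s / log(pmax(degrees, 2)), 0)
  names(st) <- names(s)
  st
}

#' Stationary distribution of the expression-weighted walk
#'
#' The mass-action chain is reversible (edge weight `E_i E_j` is symmetric),
#' so its stationary distribution has the closed form
#' `pi_i = E_i * sum_{k in N_i} E_k / Z`. The result is verified against the
#' fixed-point condition `pi P = pi` (infinity-norm residual < 1e-10).
#' Requires a connected graph; apply [largest_connected_component()] first.
#'
#' @inheritParams transition_matrix
#' @return named probability vector over nodes (sums to 1).
#' @export
stationary_distribution <- function(system, sample) {
  stopifnot(inherits(system, "integrated_system"))
  if (!igraph::is_connected(system$graph)) {
    stop("graph is disconnected; restrict to the largest connected ",
         "component before computing the stationary distribution")
  }
  if (!sample %in% colnames(system$expr)) stop("unknown sample: ", sample)
  e <- system$expr[, sample]
  A <- system_adjacency(system)
  w <- e * as.numeric(A %*% e)
  pi <- w / sum(w)
  P <- transition_matrix(system, sample)
  resid <- max(abs(as.numeric(pi %*% P) - pi))
  if (resid >= 1e-10) {
    stop("stationary residual ", signif(resid, 3), " exceeds 1e-10")
  }
  names(pi) <- rownames(system$expr)
  pi
}

#' Maximum entropy rate of a network
#'
#' The maximum entropy rate attainable by any random walk on an undirected
#' graph is `log(lambda_max)`, the log of the dominant (Perron) eigenvalue
#' of the adjacency matrix. It is the normalising constant of the
#' equilibrium entropy rate and depends only on the network topology.
#'
#' @param net a connected igraph network with at least one node of degree
#'   >= 2.
#' @return maximum entropy rate in nats.
#' @export
max_entropy_rate <- function(net) {
  if (!igraph::is_connected(net)) stop("network must be connected")
  lambda <- igraph::eigen_centrality(net)$value
  if (lambda <= 1) stop("M_R nonpositive: dominant eigenvalue <= 1")
  log(lambda)
}

#' Global signalling entropy rates
#'
#' `equilibrium_rate()` computes the equilibrium entropy rate: the
#' stationary-distribution-weighted mean of the (non-normalized) local
#' entropies, scaled by the maximum entropy rate,
#' `SR_eq = sum_i pi_i S_i / M_R`. `nonequilibrium_rate()` computes the
#' non-equilibrium entropy rate: the plain mean of the normalized local
#' entropies, `SR_neq = mean(S~_i)`, which lies in `[0, 1]` and does not
#' depend on the stationary distribution.
#'
#' @param s local entropies `S_i` (nats), as from [local_entropies()].
#' @param pi stationary distribution over the same nodes.
#' @param m_r maximum entropy rate (> 0).
#' @param s_norm normalized local entropies, as from
#'   [normalized_local_entropies()].
#' @return a single entropy rate.
#' @export
equilibrium_rate <- function(s, pi, m_r) {
  if (m_r <= 0) stop("M_R must be positive")
  stopifnot(length(s) == length(pi))
  sum(pi * s) / m_r
}

#' @rdname equilibrium_rate
#' @export
nonequilibrium_rate <- function(s_norm) {
  if (!length(s_norm)) stop("empty entropy profile")
  mean(s_norm)
}

# vectorised local entropies for all samples at once:
# for node i with neighbour expression e_j, S_i = log r_i - q_i / r_i where
# r_i = sum_j A_ij e_j and q_i = sum_j A_ij e_j log e_j
entropy_matrix <- function(A, E) {
  R <- as.matrix(A %*% E)
  Q <- as.matrix(A %*% (E * log(E)))
  log(R) - Q / R
}

#' Per-sample entropy rate table
#'
#' Computes the requested global entropy rates for every sample of an
#' integrated system. The non-equilibrium rate is computed on all
#' integrated nodes (all have degree >= 1); the equilibrium rate is
#' computed on the largest connected component, where the stationary
#' distribution exists.
#'
#' @param system an [integrate_system()] result.
#' @param measures subset of `c("neq", "eq")`.
#' @return data.frame with one row per sample and columns `sample`,
#'   `sr_neq`, `sr_eq`, `m_r`, `n_nodes`, `n_edges_used` (the last two
#'   describe the graph each measure used: full integrated graph for `neq`,
#'   LCC for `eq`; when both are requested the full graph is reported).
#' @export
entropy_table <- function(system, measures = c("neq", "eq")) {
  stopifnot(inherits(system, "integrated_system"))
  measures <- match.arg(measures, c("neq", "eq"), several.ok = TRUE)
  samples <- colnames(system$expr)
  out <- data.frame(sample = samples, sr_neq = NA_real_, sr_eq = NA_real_,
                    m_r = NA_real_,
                    n_nodes = igraph::vcount(system$graph),
                    n_edges_used = igraph::ecount(system$graph),
                    stringsAsFactors = FALSE)
  if ("neq" %in% measures) {
    A <- system_adjacency(system)
    k <- as.numeric(Matrix::rowSums(A))
    S <- entropy_matrix(A, system$expr)
    Sn <- S / ifelse(k >= 2, log(pmax(k, 2)), Inf)  # degree-1 rows -> 0
    out$sr_neq <- colMeans(Sn)
  }
  if ("eq" %in% measures) {
    lcc <- largest_connected_component(system$graph)
    sys_lcc <- system
    sys_lcc$graph <- lcc
    sys_lcc$expr <- system$expr[igraph::V(lcc)$name, , drop = FALSE]
    m_r <- max_entropy_rate(lcc)
    A <- system_adjacency(sys_lcc)
    E <- sys_lcc$expr
    S <- entropy_matrix(A, E)
    R <- as.matrix(A %*% E)
    W <- E * R                       # unnormalised stationary weights
    Pi <- sweep(W, 2, colSums(W), "/")
    out$sr_eq <- colSums(Pi * S) / m_r
    out$m_r <- m_r
    if (identical(measures, "eq")) {
      out$n_nodes <- igraph::vcount(lcc)
      out$n_edges_used <- igraph::ecount(lcc)
    }
  }
  out
}
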
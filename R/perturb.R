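#' Edge perturbation operators
#'
#' Four null-model operators that distort a PIN by a stated fraction of its
#' original edge count, emulating database noise: `add_edges_random()`
#' inserts spurious interactions between non-adjacent pairs (the
#' false-positive scenario), `remove_edges_random()` deletes true
#' interactions (false negatives), `flip_edges_random()` relocates existing
#' edges to random non-adjacent pairs (edge count preserved, degrees not),
#' and `rewire_edges_random()` performs degree-preserving double-edge swaps
#' until the requested fraction of original edges has been displaced.
#'
#' The perturbation count is `round(level * |E|)` (half-up) measured
#' against the *original* edge set, so `level = 0.9` means 90% of the
#' initial interactions are affected. All operators are deterministic given
#' `seed`.
#'
#' @param net an igraph network.
#' @param level fraction of the original edge count to perturb, in
#'   `(0, 0.9]` (0 is allowed only through rounding).
#' @param seed integer seed.
#' @return the perturbed igraph network.
#' @name perturb_ops
NULL

check_level <- function(level) {
  if (!is.numeric(level) || level < 0 || level > 0.9) {
    stop("perturbation level must lie in (0, 0.9]")
  }
}

#' @rdname perturb_ops
#' @export
add_edges_random <- function(net, level, seed = 1L) {
  check_level(level)
  m <- round_half_up(level * igraph::ecount(net))
  if (m == 0) return(net)
  n <- igraph::vcount(net)
  free <- choose(n, 2) - igraph::ecount(net)
  if (free < m) stop("not enough non-adjacent pairs to add ", m, " edges")
  withr::with_seed(seed, {
    existing <- new.env(hash = TRUE, parent = emptyenv())
    for (k in graph_edge_keys(net)) assign(k, TRUE, envir = existing)
    nodes <- igraph::V(net)$name
    new_a <- character(m); new_b <- character(m); got <- 0L
    while (got < m) {
      todo <- (m - got) * 2L + 10L
      i <- sample.int(n, todo, replace = TRUE)
      j <- sample.int(n, todo, replace = TRUE)
      ok <- i != j
      i <- i[ok]; j <- j[ok]
      for (t in seq_along(i)) {
        k <- edge_key(nodes[i[t]], nodes[j[t]])
        if (!exists(k, envir = existing, inherits = FALSE)) {
          got <- got + 1L
          new_a[got] <- nodes[i[t]]; new_b[got] <- nodes[j[t]]
          assign(k, TRUE, envir = existing)
          if (got == m) break
        }
      }
    }
    igraph::add_edges(net, rbind(match(new_a, nodes), match(new_b, nodes)))
  })
}

#' @rdname perturb_ops
#' @export
remove_edges_random <- function(net, level, seed = 1L) {
  check_level(level)
  m <- round_half_up(level * igraph::ecount(net))
  if (m == 0) return(net)
  withr::with_seed(seed, {
    idx <- sample.int(igraph::ecount(net), m)
    igraph::delete_edges(net, idx)  # isolated nodes stay in the node set
  })
}

#' @rdname perturb_ops
#' @export
flip_edges_random <- function(net, level, seed = 1L) {
  check_level(level)
  m <- round_half_up(level * igraph::ecount(net))
  if (m == 0) return(net)
  n <- igraph::vcount(net)
  if (choose(n, 2) - igraph::ecount(net) < m) {
    stop("not enough non-adjacent pairs to relocate ", m, " edges")
  }
  withr::with_seed(seed, {
    victims <- sample.int(igraph::ecount(net), m)
    g <- igraph::delete_edges(net, victims)
    existing <- new.env(hash = TRUE, parent = emptyenv())
    for (k in graph_edge_keys(g)) assign(k, TRUE, envir = existing)
    nodes <- igraph::V(g)$name
    got <- 0L; new_a <- character(m); new_b <- character(m)
    while (got < m) {
      i <- sample.int(n, 1L); j <- sample.int(n, 1L)
      if (i == j) next
      k <- edge_key(nodes[i], nodes[j])
      if (!exists(k, envir = existing, inherits = FALSE)) {
        got <- got + 1L
        new_a[got] <- nodes[i]; new_b[got] <- nodes[j]
        assign(k, TRUE, envir = existing)
      }
    }
    igraph::add_edges(g, rbind(match(new_a, nodes), match(new_b, nodes)))
  })
}

#' @rdname perturb_ops
#' @export
rewire_edges_random <- function(net, level, seed = 1L) {
  check_level(level)
  ecnt <- igraph::ecount(net)
  if (ecnt < 2) stop("rewiring needs at least 2 edges")
  m <- round_half_up(level * ecnt)
  if (m == 0) return(net)
  withr::with_seed(seed, {
    el <- igraph::as_edgelist(net, names = TRUE)
    original_keys <- edge_key(el[, 1], el[, 2])
    existing <- new.env(hash = TRUE, parent = emptyenv())
    is_original <- new.env(hash = TRUE, parent = emptyenv())
    for (k in original_keys) {
      assign(k, TRUE, envir = existing)
      assign(k, TRUE, envir = is_original)
    }
    n_original_present <- ecnt   # displaced count = ecnt - this
    max_trials <- 10L * ecnt
    trials <- 0L
    while ((ecnt - n_original_present) < m && trials < max_trials) {
      trials <- trials + 1L
      pick <- sample.int(nrow(el), 2L)
      u <- el[pick[1], 1]; v <- el[pick[1], 2]
      x <- el[pick[2], 1]; y <- el[pick[2], 2]
      if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
      # propose (u,v),(x,y) -> (u,y),(x,v)
      if (u == y || x == v) next
      k_new1 <- edge_key(u, y); k_new2 <- edge_key(x, v)
      if (exists(k_new1, envir = existing, inherits = FALSE) ||
          exists(k_new2, envir = existing, inherits = FALSE) ||
          k_new1 == k_new2) next
      k_old1 <- edge_key(u, v); k_old2 <- edge_key(x, y)
      for (k in c(k_old1, k_old2)) {
        if (exists(k, envir = is_original, inherits = FALSE)) {
          n_original_present <- n_original_present - 1L
        }
      }
      for (k in c(k_new1, k_new2)) {
        if (exists(k, envir = is_original, inherits = FALSE)) {
          n_original_present <- n_original_present + 1L
        }
      }
      rm(list = c(k_old1, k_old2), envir = existing)
      assign(k_new1, TRUE, envir = existing)
      assign(k_new2, TRUE, envir = existing)
      el[pick[1], ] <- c(u, y); el[pick[2], ] <- c(x, v)
    }
    if ((ecnt - n_original_present) < m) {
      stop(sprintf(
        "rewiring stalled after %d trials: displaced %.1f%% of original edges (target %.1f%%)",
        trials, 100 * (ecnt - n_original_present) / ecnt, 100 * m / ecnt))
    }
    nodes <- igraph::V(net)$name
    g <- igraph::delete_edges(net, seq_len(ecnt))
    igraph::add_edges(g, rbind(match(el[, 1], nodes), match(el[, 2], nodes)))
  })
}

#' Apply a perturbation by name
#'
#' @param net an igraph network.
#' @param kind one of `"add"`, `"remove"`, `"flip"`, `"rewire"`.
#' @inheritParams perturb_ops
#' @return the perturbed network.
#' @export
perturb_network <- function(net, kind = c("add", "remove", "flip", "rewire"),
                            level, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
         add = add_edges_random(net, level, seed),
         remove = remove_edges_random(net, level, seed),
         flip = flip_edges_random(net, level, seed),
         rewire = rewire_edges_random(net, level, seed))
}

#' Perturbation sweep experiment
#'
#' For every combination of perturbation kind, level and replicate: perturb
#' the network, integrate it with the expression matrix, and record both
#' entropy rates per sample together with the size of the largest connected
#' component and the fitted power-law exponent of the perturbed degree
#' distribution. Replicate seeds are derived deterministically from
#' `(seed, kind, level, replicate)` so individual rows can be reproduced in
#' isolation.
#'
#' @param net reference igraph PIN.
#' @param expr genes x samples expression matrix.
#' @param kinds subset of `c("add", "remove", "flip", "rewire")`.
#' @param levels perturbation levels in `(0, 0.9]`.
#' @param replicates number of independent replicates per cell.
#' @param seed master seed.
#' @param measures entropy measures to compute, see [entropy_table()].
#' @return long data.frame with columns `kind`, `level`, `replicate`,
#'   `sample`, `sr_neq`, `sr_eq`, `lcc_nodes`, `lcc_edges`, `gamma`.
#' @export
perturbation_sweep <- function(net, expr,
                               kinds = c("add", "remove", "flip", "rewire"),
                               levels = seq(0.1, 0.9, by = 0.1),
                               replicates = 5L, seed = 1L,
                               measures = c("neq", "eq")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  rows <- list()
  for (kind in kinds) for (lv in levels) for (rep in seq_len(replicates)) {
    rows[[length(rows) + 1L]] <- sweep_cell(net, expr, kind, lv, rep, seed,
                                            measures)
  }
  do.call(rbind, rows)
}

# one (kind, level, replicate) cell; seed derived so any cell can be
# recomputed in isolation
sweep_cell <- function(net, expr, kind, lv, rep, seed, measures) {
  sub_seed <- derive_seed(seed, kind, format(lv), rep)
  g <- perturb_network(net, kind, lv, seed = sub_seed)
  lcc <- largest_connected_component(g)
  gam <- tryCatch(fit_power_law(degree_histogram(g))$gamma,
                  error = function(e) NA_real_)
  tab <- entropy_table(suppressMessages(integrate_system(g, expr)),
                       measures = measures)
  data.frame(
    kind = kind, level = lv, replicate = rep, sample = tab$sample,
    sr_neq = tab$sr_neq, sr_eq = tab$sr_eq,
    lcc_nodes = igraph::vcount(lcc), lcc_edges = igraph::ecount(lcc),
    gamma = gam, stringsAsFactors = FALSE)
}
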
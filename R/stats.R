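#' Compare entropy rates between two groups
#'
#' Two-sided Wilcoxon rank-sum test of per-sample entropy rates between two
#' conditions (e.g. healthy versus cancer). The exact null distribution is
#' used when the combined sample size is at most 20 (and no ties are
#' present); otherwise the normal approximation with continuity correction.
#' A Welch t-test is selectable as an alternative.
#'
#' @param a,b numeric vectors of per-sample entropy rates (each length >=
#'   2).
#' @param test `"wilcox"` (default) or `"t"`.
#' @return an object of class `comparison_result`: list with `p_value`,
#'   `test`, `n_a`, `n_b`, `median_a`, `median_b`.
#' @export
compare_groups <- function(a, b, test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  p <- if (test == "wilcox") {
    if (length(unique(c(a, b))) == 1L) {
      1   # all observations tied: no shift information
    } else {
      exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
      suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = TRUE)$p.value)
    }
  } else {
    stats::t.test(a, b)$p.value
  }
  structure(list(p_value = p, test = test, n_a = length(a), n_b = length(b),
                 median_a = stats::median(a), median_b = stats::median(b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g (n = %d vs %d, medians %.4g vs %.4g)\n",
              x$test, x$p_value, x$n_a, x$n_b, x$median_a, x$median_b))
  invisible(x)
}

#' Within-class null distribution of the group comparison
#'
#' A sound correction method must not manufacture significant differences
#' inside a homogeneous class. This routine repeatedly splits one class
#' into two disjoint random halves (size `floor(n/2)` each), applies
#' [compare_groups()], and returns the resulting p-value distribution with
#' its median as summary.
#'
#' @param x per-sample entropy rates of one class (length >= 4).
#' @param repetitions number of random splits.
#' @param seed integer seed.
#' @param test passed to [compare_groups()].
#' @return list with `p_values` (length `repetitions`), `p_median`,
#'   `repetitions`.
#' @export
within_class_null <- function(x, repetitions = 50L, seed = 1L,
                              test = "wilcox") {
  n <- length(x)
  if (n < 4) stop("class needs >= 4 samples for within-class splitting")
  h <- n %/% 2
  p <- withr::with_seed(seed, {
    vapply(seq_len(repetitions), function(r) {
      idx <- sample.int(n, 2 * h)
      compare_groups(x[idx[1:h]], x[idx[(h + 1):(2 * h)]],
                     test = test)$p_value
    }, 0)
  })
  list(p_values = p, p_median = stats::median(p), repetitions = repetitions)
}

#' Evaluation grid over PINs, corrections and thresholds
#'
#' Reproduces the stabilisation benchmark: for every combination of
#' (dataset, PIN) system, correction-score table and threshold, the network
#' is filtered, the non-equilibrium entropy rate recomputed, and two
#' quantities recorded: the between-class p-value and the median
#' within-class p-value of the designated reference class. An uncorrected
#' baseline (`threshold = "none"`) is always included per system. Cells
#' whose filtered network retains no usable genes are marked `NA`.
#'
#' @param systems list of systems; each element a list with `dataset`
#'   (label), `pin` (label), `net` (igraph), `expr` (genes x samples
#'   matrix), `classes` (factor/character of length `ncol(expr)` with
#'   exactly two levels; the first level is the within-class reference).
#' @param corrections named list of `reliability_scores` tables.
#' @param thresholds numeric thresholds in `[0, 1]`.
#' @param alpha significance level for error tallies.
#' @param repetitions within-class split count.
#' @param seed integer seed.
#' @return list with `grid` (data.frame: `dataset`, `pin`, `method`,
#'   `threshold`, `p_between`, `p_within_median`, `n_edges_after_filter`,
#'   `na_flag`) and `errors` (see [count_errors()]).
#' @export
evaluation_grid <- function(systems, corrections,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            alpha = 0.05, repetitions = 50L, seed = 1L) {
  rows <- list()
  eval_cell <- function(ds, pin, method, thr_label, net, expr, classes) {
    cls <- as.character(classes)
    lv <- unique(cls)
    if (length(lv) != 2) stop("each system needs exactly two classes")
    res <- tryCatch({
      sys <- suppressMessages(integrate_system(net, expr))
      tab <- entropy_table(sys, measures = "neq")
      sr <- stats::setNames(tab$sr_neq, tab$sample)[colnames(expr)]
      pb <- compare_groups(sr[cls == lv[1]], sr[cls == lv[2]])$p_value
      pw <- within_class_null(sr[cls == lv[1]], repetitions = repetitions,
                              seed = derive_seed(seed, ds, pin, method,
                                                 thr_label))$p_median
      list(pb = pb, pw = pw, ne = igraph::ecount(net), na = FALSE)
    }, error = function(e) {
      list(pb = NA_real_, pw = NA_real_, ne = igraph::ecount(net), na = TRUE)
    })
    data.frame(dataset = ds, pin = pin, method = method,
               threshold = thr_label, p_between = res$pb,
               p_within_median = res$pw, n_edges_after_filter = res$ne,
               na_flag = res$na, stringsAsFactors = FALSE)
  }
  for (sys in systems) {
    rows[[length(rows) + 1L]] <- eval_cell(
      sys$dataset, sys$pin, "uncorrected", "none",
      sys$net, sys$expr, sys$classes)
    for (method in names(corrections)) {
      for (thr in thresholds) {
        fn <- suppressWarnings(
          filter_network(sys$net, corrections[[method]], thr))
        rows[[length(rows) + 1L]] <- eval_cell(
          sys$dataset, sys$pin, method, format(thr),
          fn, sys$expr, sys$classes)
      }
    }
  }
  grid <- do.call(rbind, rows)
  list(grid = grid, errors = count_errors(grid, alpha = alpha))
}

#' Tally stabilisation errors from an evaluation grid
#'
#' Counts, per correction method, the grid cells where the between-class
#' difference is *not* significant (`p_between >= alpha`: lost
#' discriminatory power) and where the within-class summary *is*
#' significant (`p_within_median < alpha`: a manufactured difference).
#' `NA` cells are counted separately.
#'
#' @param grid the `grid` component of [evaluation_grid()].
#' @param alpha significance level.
#' @return data.frame with columns `method`, `n_cells`,
#'   `between_class_errors`, `within_class_errors`, `n_na`, `alpha`.
#' @export
count_errors <- function(grid, alpha = 0.05) {
  out <- lapply(split(grid, grid$method), function(d) {
    data.frame(method = d$method[1],
               n_cells = nrow(d),
               between_class_errors = sum(d$p_between >= alpha, na.rm = TRUE),
               within_class_errors = sum(d$p_within_median < alpha,
                                         na.rm = TRUE),
               n_na = sum(d$na_flag),
               alpha = alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
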
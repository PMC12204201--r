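# worked example used throughout: path A - B - C with expression (1, 2, 3)
path_system <- function(E = c(A = 1, B = 2, C = 3)) {
  expr <- matrix(E, 3, 1, dimnames = list(names(E), "s1"))
  integrate_system(path_net(), expr)
}

test_that("integration restricts to common genes and drops isolated nodes", {
  net <- make_net(c("A", "B", "C"), c("B", "C", "D"))
  expr <- matrix(1:3, 3, 1, dimnames = list(c("A", "B", "E"), "s1"))
  sys <- integrate_system(net, expr)
  expect_setequal(rownames(sys$expr), c("A", "B"))

  expr0 <- matrix(c(0, 2, 3), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  expect_message(sys0 <- integrate_system(path_net(), expr0), "zero")
  expect_equal(sys0$expr["A", "s1"], 0.2)  # min positive / 10

  bad <- matrix(c(-1, 1, 1), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  expect_error(integrate_system(path_net(), bad), "nonnegative")
  disj <- matrix(1, 1, 1, dimnames = list("Z", "s1"))
  expect_error(integrate_system(path_net(), disj), "no genes")
})

test_that("transition matrix follows the mass-action rule on the path example", {
  P <- transition_matrix(path_system(), "s1")
  expect_equal(P["A", "B"], 1)
  expect_equal(P["B", "A"], 0.25)
  expect_equal(P["B", "C"], 0.75)
  expect_equal(P["C", "B"], 1)
  expect_equal(as.numeric(Matrix::rowSums(P)), rep(1, 3), tolerance = 1e-12)
})

test_that("rows are stochastic and scale-invariant on random systems", {
  withr::local_seed(99)
  for (rep in 1:50) {
    net <- largest_connected_component(random_net(10, 0.3))
    expr <- random_expr(net, 2)
    sys <- integrate_system(net, expr)
    P <- transition_matrix(sys, "s1")
    expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-9)
    # scaling a sample leaves P, pi and the rates unchanged
    sys2 <- integrate_system(net, expr * 7.3)
    expect_equal(as.matrix(transition_matrix(sys2, "s1")), as.matrix(P),
                 tolerance = 1e-12)
    expect_equal(entropy_table(sys2), entropy_table(sys), tolerance = 1e-12)
  }
})

test_that("local entropies match hand arithmetic", {
  P <- transition_matrix(path_system(), "s1")
  s <- local_entropies(P)
  expect_equal(unname(s["A"]), 0)                      # degree-1 node
  expect_equal(unname(s["B"]),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-12)
  expect_equal(unname(s["B"]), 0.5623, tolerance = 1e-4)

  sn <- normalized_local_entropies(P)
  expect_equal(unname(sn["B"]), unname(s["B"]) / log(2), tolerance = 1e-12)
  expect_equal(unname(sn["B"]), 0.8113, tolerance = 1e-4)
  expect_equal(unname(sn["A"]), 0)                     # degree-1 convention

  # star centre under uniform expression: S = log k, normalized = 1
  sys <- integrate_system(star_net(5), uniform_expr(star_net(5)))
  Ps <- transition_matrix(sys, "s1")
  expect_equal(unname(local_entropies(Ps)["hub"]), log(5), tolerance = 1e-12)
  expect_equal(unname(normalized_local_entropies(Ps)["hub"]), 1,
               tolerance = 1e-12)
})

test_that("closed-form stationary distribution matches the worked example and power iteration", {
  sys <- path_system()
  pi <- stationary_distribution(sys, "s1")
  expect_equal(unname(pi), c(0.125, 0.5, 0.375), tolerance = 1e-12)
  expect_equal(sum(pi), 1, tolerance = 1e-12)

  withr::local_seed(11)
  for (rep in 1:40) {
    net <- largest_connected_component(random_net(12, 0.25))
    sys <- integrate_system(net, random_expr(net))
    pi <- stationary_distribution(sys, "s1")
    expect_equal(unname(pi),
                 power_iteration_pi(transition_matrix(sys, "s1")),
                 tolerance = 1e-8)
  }

  disc <- make_net(c("A", "C"), c("B", "D"))
  sysd <- integrate_system(disc, uniform_expr(disc))
  expect_error(stationary_distribution(sysd, "s1"), "connected")
})

test_that("maximum entropy rate is log of the dominant adjacency eigenvalue", {
  expect_equal(max_entropy_rate(complete_net(4)), log(3), tolerance = 1e-9)
  expect_equal(max_entropy_rate(star_net(5)), 0.5 * log(5), tolerance = 1e-9)
  expect_equal(max_entropy_rate(path_net()), log(sqrt(2)), tolerance = 1e-9)
  expect_error(max_entropy_rate(make_net("A", "B")), "nonpositive")
})

test_that("equilibrium rate is 1 on uniform-expression symmetric cases", {
  # path: weighted local entropy sum equals M_R exactly
  sys <- integrate_system(path_net(), uniform_expr(path_net()))
  tab <- entropy_table(sys)
  expect_equal(tab$sr_eq, 1, tolerance = 1e-9)
  expect_equal(tab$sr_neq, 1 / 3, tolerance = 1e-12)

  for (n in c(3, 5, 8)) {
    k <- complete_net(n)
    expect_equal(entropy_table(integrate_system(k, uniform_expr(k)))$sr_eq,
                 1, tolerance = 1e-9)
  }

  # star with k leaves: non-equilibrium rate = 1 / (k + 1)
  s <- star_net(7)
  expect_equal(entropy_table(integrate_system(s, uniform_expr(s)))$sr_neq,
               1 / 8, tolerance = 1e-12)
})

test_that("extreme expression concentration drives the equilibrium rate to 0", {
  # stationary mass piles onto A and B while B's transition distribution
  # degenerates onto A, so every weighted local entropy vanishes
  sys <- path_system(c(A = 1e9, B = 1, C = 1e-9))
  tab <- entropy_table(sys, measures = "eq")
  expect_lt(tab$sr_eq, 0.01)
})

test_that("non-equilibrium rate stays in [0, 1]; 1 only on uniform regular graphs", {
  withr::local_seed(5)
  for (rep in 1:30) {
    net <- random_net(9, 0.3)
    sys <- integrate_system(net, random_expr(net, 2))
    tab <- entropy_table(sys, measures = "neq")
    expect_true(all(tab$sr_neq >= 0 & tab$sr_neq <= 1))
  }
  tri <- complete_net(3)   # 2-regular
  expect_equal(entropy_table(integrate_system(tri, uniform_expr(tri)),
                             measures = "neq")$sr_neq, 1, tolerance = 1e-12)
  # non-uniform expression on the same regular graph stays strictly below 1
  e <- matrix(c(1, 2, 9), 3, 1, dimnames = list(igraph::V(tri)$name, "s1"))
  expect_lt(entropy_table(integrate_system(tri, e),
                          measures = "neq")$sr_neq, 1)
})

test_that("entropy table has one deterministic row per sample, order-stable", {
  net <- largest_connected_component(random_net(10, 0.35))
  withr::local_seed(2)
  expr <- random_expr(net, 3)
  expr[, 2] <- expr[, 1]   # identical samples -> identical rows
  sys <- integrate_system(net, expr)
  tab <- entropy_table(sys)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$sr_neq[1], tab$sr_neq[2], tolerance = 1e-14)
  expect_equal(tab$sr_eq[1], tab$sr_eq[2], tolerance = 1e-14)
  # permuting samples permutes rows only
  sys_p <- integrate_system(net, expr[, c(3, 1, 2)])
  tab_p <- entropy_table(sys_p)
  expect_equal(tab_p$sr_neq, tab$sr_neq[c(3, 1, 2)], tolerance = 1e-14)
})

test_that("expression round-trips through TSV", {
  net <- path_net()
  expr <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, f)
  expect_equal(read_expression(f), expr)
})
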
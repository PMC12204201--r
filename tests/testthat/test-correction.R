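# small fixture: edge i-j sharing neighbours a, b; pendant c on i, d on j
shared_net <- function() {
  make_net(c("i", "i", "i", "j", "j"), c("j", "a", "b", "a", "b"))
}

test_that("topological scores match the committed formulas", {
  # identical closed neighbourhoods -> dice = 1
  sc_d <- topological_scores(shared_net(), "dice")
  expect_equal(entropin:::score_lookup(sc_d, "i", "j"), 1)

  # no shared neighbours -> jaccard = 0
  chain <- make_net(c("c", "i", "j"), c("i", "j", "d"))
  sc_j <- topological_scores(chain, "jaccard")
  expect_equal(entropin:::score_lookup(sc_j, "i", "j"), 0)

  # jaccard with partial overlap: N_i\{i,j} = {a,b,c}, N_j\{i,j} = {a,b}
  g <- make_net(c("i", "i", "i", "i", "j", "j"),
                c("j", "a", "b", "c", "a", "b"))
  expect_equal(entropin:::score_lookup(topological_scores(g, "jaccard"),
                                       "i", "j"), 2 / 3)

  # invlog: unique maximum rescales to 1, edges without common neighbours to 0
  sc_i <- topological_scores(shared_net(), "invlog")
  expect_equal(entropin:::score_lookup(sc_i, "i", "j"), 1)  # two shared nbrs
  expect_equal(entropin:::score_lookup(sc_i, "i", "a"), 0)  # one shared (min? )
  expect_true(all(sc_i$score >= 0 & sc_i$score <= 1))
})

test_that("all scoring methods stay in [0, 1] on random graphs", {
  withr::local_seed(31)
  for (rep in 1:10) {
    g <- largest_connected_component(random_net(12, 0.3))
    for (m in c("jaccard", "dice", "invlog")) {
      sc <- suppressWarnings(topological_scores(g, m))
      expect_true(all(sc$score >= 0 & sc$score <= 1))
    }
  }
})

# chain ontology root -> a -> b used by several blocks
chain_ont <- function() {
  ontology(c("root", "a", "b"),
           data.frame(child = c("a", "b"), parent = c("root", "a"),
                      relation = c("is_a", "is_a")))
}

test_that("information content applies true-path propagation", {
  ont <- chain_ont()
  ann <- list(g1 = "b", g2 = "a", g3 = "a", g4 = "b")
  ic <- information_content(ont, ann)
  expect_equal(ic$ic[ic$term == "root"], 0)
  expect_equal(ic$p[ic$term == "a"], 1)        # all genes reach a
  expect_equal(ic$ic[ic$term == "b"], log(2))  # half of the genes
  # monotone along every edge
  withr::local_seed(17)
  for (rep in 1:10) {
    ont <- random_dag(30)
    ann <- random_annotations(ont)
    ic <- suppressWarnings(information_content(ont, ann))
    for (i in seq_len(nrow(ont$edges))) {
      icc <- ic$ic[match(ont$edges$child[i], ic$term)]
      icp <- ic$ic[match(ont$edges$parent[i], ic$term)]
      if (!is.na(icc) && !is.na(icp)) expect_gte(icc, icp)
    }
  }
})

test_that("term similarity honours self-similarity and root-MICA limits", {
  ont <- chain_ont()
  ann <- list(g1 = "b", g2 = "a", g3 = "a", g4 = "b")
  ic <- information_content(ont, ann)
  for (m in c("resnik", "lin", "jiang", "wang")) {
    expect_equal(term_similarity("b", "b", ont, ic, m), 1,
                 info = m, tolerance = 1e-12)
  }
  # siblings meeting only at the root
  ont2 <- ontology(c("root", "x", "y"),
                   data.frame(child = c("x", "y"), parent = c("root", "root"),
                              relation = c("is_a", "is_a")))
  ic2 <- information_content(ont2, list(g1 = "x", g2 = "y"))
  expect_equal(term_similarity("x", "y", ont2, ic2, "resnik"), 0)
  expect_equal(term_similarity("x", "y", ont2, ic2, "schlicker"), 0)
  # Wang hand example: chain root -> a -> b, S_b = {b:1, a:0.8, root:0.64}
  sv <- entropin:::wang_svalues("b", chain_ont(), c(is_a = 0.8, part_of = 0.6))
  expect_equal(unname(sv[c("b", "a", "root")]), c(1, 0.8, 0.64))
  expect_equal(term_similarity("b", "b", chain_ont(), method = "wang"), 1)
})

test_that("term similarity equals brute-force ancestor enumeration on random DAGs", {
  withr::local_seed(202)
  for (rep in 1:25) {
    ont <- random_dag(50)
    ann <- random_annotations(ont, 20)
    ic <- suppressWarnings(information_content(ont, ann))
    pool <- intersect(ont$terms, ic$term)
    ts <- sample(pool, 2)
    for (m in c("resnik", "lin", "jiang", "schlicker")) {
      expect_equal(term_similarity(ts[1], ts[2], ont, ic, m),
                   brute_term_similarity(ts[1], ts[2], ont$edges, ic, m),
                   tolerance = 1e-12, info = m)
    }
    expect_equal(term_similarity(ts[1], ts[2], ont, method = "wang"),
                 brute_wang_similarity(ts[1], ts[2], ont$edges),
                 tolerance = 1e-12)
  }
})

test_that("gene similarity is the best-match average of term similarities", {
  # branch c alongside the a -> b chain keeps IC(a) > 0
  ont <- ontology(c("root", "a", "b", "c"),
                  data.frame(child = c("a", "b", "c"),
                             parent = c("root", "a", "root"),
                             relation = rep("is_a", 3)))
  ann <- list(g1 = "b", g2 = "a", g3 = c("a", "b"))
  ic <- information_content(ont, list(x = "b", y = "a", z = "c", w = "b"))
  # single-term genes reduce to term similarity
  expect_equal(gene_similarity("g1", "g2", ann, ont, ic, "lin"),
               term_similarity("b", "a", ont, ic, "lin"))
  # identical annotation sets -> 1 under lin
  expect_equal(gene_similarity("g1", "g1", ann, ont, ic, "lin"), 1)
  # BMA expansion for {a} vs {a, b}
  s_ab <- term_similarity("a", "b", ont, ic, "lin")
  expect_gt(s_ab, 0)
  expect_equal(gene_similarity("g2", "g3", ann, ont, ic, "lin"),
               (1 + (1 + s_ab) / 2) / 2, tolerance = 1e-12)
  expect_error(gene_similarity("g1", "nope", ann, ont, ic), "annotated")
})

test_that("semantic edge scoring skips unannotated endpoints with a warning", {
  net <- make_net(c("g1", "g2", "g2"), c("g2", "g3", "g4"))
  ont <- chain_ont()
  ann <- list(g1 = "b", g2 = "a", g3 = c("a", "b"))   # g4 unannotated
  ic <- information_content(ont, ann)
  expect_warning(sc <- semantic_edge_scores(net, ann, ont, ic, "lin"),
                 "unannotated")
  expect_equal(nrow(sc), 2)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("STRING score loading rescales, deduplicates, and validates", {
  f <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                       "p1 p2 900", "p2 p3 400"))
  sc <- load_string_scores(f)
  expect_equal(entropin:::score_lookup(sc, "p1", "p2"), 0.9)

  fdup <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                          "p1 p2 300", "p2 p1 700"))
  expect_warning(scd <- load_string_scores(fdup), "duplicate")
  expect_equal(entropin:::score_lookup(scd, "p1", "p2"), 0.7)

  fbad <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                          "p1 p2 1001"))
  expect_error(load_string_scores(fbad), "0-1000")
  fnoh <- withr::local_tempfile(lines = c("p1 p2 900"))
  expect_error(load_string_scores(fnoh), "header")
})

test_that("threshold filtering keeps scored edges and drops unscored ones", {
  net <- make_net(c("A", "B", "C"), c("B", "C", "D"))
  sc <- reliability_scores(c("A", "B", "C"), c("B", "C", "D"),
                           c(0.3, 0.5, 0.9))
  expect_equal(igraph::ecount(filter_network(net, sc, 0.4)), 2)
  expect_equal(igraph::ecount(filter_network(net, sc, 0)), 3)
  expect_warning(g0 <- filter_network(net, sc, 0.95), "all edges")
  expect_equal(igraph::ecount(g0), 0)
  # unscored edge removed at any positive threshold, counted in stats
  sc2 <- reliability_scores("A", "B", 0.8)
  g2 <- filter_network(net, sc2, 0.1)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::graph_attr(g2, "filter_stats")$n_unscored, 2)
  # monotone non-increasing edge count across the threshold sweep
  withr::local_seed(77)
  g <- random_net(15, 0.3)
  el <- igraph::as_edgelist(g)
  scr <- reliability_scores(el[, 1], el[, 2], stats::runif(nrow(el)))
  counts <- vapply(seq(0.1, 0.9, 0.1), function(th) {
    igraph::ecount(suppressWarnings(filter_network(g, scr, th)))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("Beta-separated scores let a 0.4 threshold recover the true network", {
  net <- generate_network(n_nodes = 150, m = 2, seed = 44)
  contaminated <- add_edges_random(net, 0.6, seed = 44)
  orig <- entropin:::graph_edge_keys(net)
  el <- igraph::as_edgelist(contaminated, names = TRUE)
  keys <- entropin:::edge_key(el[, 1], el[, 2])
  sc <- generate_score_table(contaminated, el[keys %in% orig, ],
                             el[!keys %in% orig, ], seed = 44)
  filt <- filter_network(contaminated, sc, 0.4)
  kept <- entropin:::graph_edge_keys(filt)
  spurious <- keys[!keys %in% orig]
  expect_gte(mean(!spurious %in% kept), 0.9)   # >= 90% of spurious removed
  expect_lte(mean(!orig %in% kept), 0.1)       # <= 10% of true edges lost
})

test_that("OBO and annotation files round-trip", {
  gen <- generate_ontology(n_terms = 20, genes = paste0("g", 1:8), seed = 9)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(gen$ontology, f)
  ont2 <- read_obo(f)
  expect_setequal(ont2$terms, gen$ontology$terms)
  expect_equal(nrow(ont2$edges), nrow(gen$ontology$edges))
  expect_equal(ont2$root, gen$ontology$root)

  fa <- withr::local_tempfile()
  write_annotations(gen$annotations, fa)
  ann2 <- read_annotations(fa, "tsv", ontology = gen$ontology)
  expect_equal(ann2[order(names(ann2))],
               gen$annotations[order(names(gen$annotations))])

  # GAF dialect: columns 2 and 5
  fg <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.2",
    paste("DB", "g1", "sym", "", "T0001", "ref", "IEA", "", "P",
          sep = "\t")))
  expect_equal(read_annotations(fg, "gaf"), list(g1 = "T0001"))
})
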
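test_that("disease DAGs reproduce the published example topologies", {
  fx <- worked_example()
  ln <- build_disease_dag(fx$ontology, "liver neoplasms")
  pn <- build_disease_dag(fx$ontology, "pancreatic neoplasms")

  expect_equal(nrow(ln$nodes), 6)
  expect_equal(unname(table(ln$nodes$depth)), c(1L, 2L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(nrow(pn$nodes), 8)
  expect_equal(unname(table(pn$nodes$depth)), c(1L, 3L, 3L, 1L),
               ignore_attr = TRUE)
  expect_equal(ln$nodes$depth[ln$nodes$term_id == ln$disease], 0L)

  # a bare root term is its own one-node DAG
  ont <- as_ontology(data.frame(term_id = "r", name = "root",
                                tree_numbers = "C01"))
  dag <- build_disease_dag(ont, "r")
  expect_equal(nrow(dag$nodes), 1)
  expect_equal(dag$nodes$depth, 0L)

  expect_error(build_disease_dag(fx$ontology, "no such disease"),
               class = "hdmp_lookup_error")
  expect_error(
    as_ontology(data.frame(term_id = "x", name = "x",
                           tree_numbers = "C01.100.200")),
    regexp = "dangling"
  )
})

test_that("layer contributions follow delta^depth and sum to the published DV", {
  fx <- worked_example()
  ln <- build_disease_dag(fx$ontology, "liver neoplasms")
  pn <- build_disease_dag(fx$ontology, "pancreatic neoplasms")

  cl <- contribution_map(ln, "layer", delta = 0.5)
  expect_equal(semantic_value(cl), 2.625)
  expect_equal(semantic_value(contribution_map(pn, "layer", delta = 0.5)), 3.375)

  # contributions strictly decrease with depth for delta < 1, equal within a layer
  expect_true(all(diff(cl$contribution[order(cl$depth)]) <= 0))
  by_depth <- split(cl$contribution, cl$depth)
  expect_true(all(vapply(by_depth, function(v) length(unique(v)) == 1,
                         logical(1))))

  # delta = 1 flattens every layer
  c1 <- contribution_map(ln, "layer", delta = 1)
  expect_true(all(c1$contribution == 1))

  expect_error(contribution_map(ln, "layer", delta = 0), "delta")
  expect_error(semantic_value(cl[0, ]), class = "hdmp_empty_input_error")
})

test_that("IC contributions reproduce the published DV and coverage is enforced", {
  fx <- worked_example()
  ln <- build_disease_dag(fx$ontology, "liver neoplasms")
  ci <- contribution_map(ln, "ic", ic = fx$ic_table)
  expect_equal(semantic_value(ci), 34.313)

  # DV is order-invariant (plain additivity)
  expect_equal(semantic_value(ci[sample(nrow(ci)), ]), 34.313)

  pn <- build_disease_dag(fx$ontology, "pancreatic neoplasms")
  expect_error(contribution_map(pn, "ic", ic = fx$ic_table),
               class = "hdmp_coverage_error")
})

test_that("information content matches hand enumeration and the -log2 convention", {
  # 3-term chain a -> b -> c (c is the root): n = (1, 2, 3)
  ont <- as_ontology(data.frame(
    term_id = c("a", "b", "c"), name = c("a", "b", "c"),
    tree_numbers = c("R.1.1", "R.1", "R")
  ))
  ic <- compute_information_content(ont)
  expect_equal(ic$n_dags[match(c("a", "b", "c"), ic$term_id)], c(1L, 2L, 3L))
  expect_equal(ic$ic[match(c("a", "b", "c"), ic$term_id)],
               c(log2(3), log2(1.5), 0))

  # the printed convention: 40 of 4577 DAGs -> 6.838 at base 2
  expect_equal(round(-log(40 / 4577, base = 2), 3), 6.838)

  # antitone in n_t, and a term present in every DAG has IC exactly 0
  for (s in 1:3) {
    ont_r <- random_ontology(s)
    ic_r <- compute_information_content(ont_r)
    o <- order(ic_r$n_dags)
    expect_true(all(diff(ic_r$ic[o]) <= 1e-12))
    expect_true(all(ic_r$ic >= 0))
    expect_true(all(ic_r$ic[ic_r$n_dags == nrow(ont_r)] == 0))
  }
})

test_that("node depth equals exhaustive shortest-path enumeration", {
  for (s in 1:10) {
    ont <- random_ontology(s)
    for (d in ont$term_id) {
      dag <- build_disease_dag(ont, d)
      bf <- bf_min_path(dag)
      expect_equal(dag$nodes$depth[match(names(bf), dag$nodes$term_id)],
                   as.integer(bf))
      # recursive max rule: max over paths of delta^len = delta^min-depth
      delta <- 0.5
      expect_equal(delta ^ dag$nodes$depth,
                   delta ^ unname(bf[dag$nodes$term_id]))
    }
  }
})
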
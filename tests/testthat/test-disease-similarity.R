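fx <- worked_example()
ln <- build_disease_dag(fx$ontology, "liver neoplasms")
pn <- build_disease_dag(fx$ontology, "pancreatic neoplasms")
bn <- build_disease_dag(fx$ontology, "breast neoplasms")

test_that("semantic similarity: identity, disjointness, published value", {
  expect_equal(semantic_similarity(bn, bn, "layer"), 1)
  expect_equal(semantic_similarity(ln, pn, "layer", delta = 0.5),
               (1.125 + 1.125) / (2.625 + 3.375))

  # disjoint hierarchies share no node
  ont2 <- as_ontology(data.frame(
    term_id = c("x", "y"), name = c("x", "y"),
    tree_numbers = c("Z.1", "Z")
  ))
  skin <- build_disease_dag(fx$ontology, "skin diseases")
  expect_equal(semantic_similarity(ln, skin, "layer"), 0)

  # DAGs from different ontologies must not be mixed
  other <- build_disease_dag(ont2, "x")
  expect_error(semantic_similarity(ln, other, "layer"),
               class = "hdmp_mixed_source_error")
})

test_that("semantic similarity matches a brute-force shared-node oracle", {
  for (s in 1:6) {
    ont <- random_ontology(s)
    dags <- lapply(ont$term_id, function(d) build_disease_dag(ont, d))
    pick <- withr::with_seed(s, sample(length(dags), 4))
    for (i in pick) for (j in pick) {
      ss <- semantic_similarity(dags[[i]], dags[[j]], "layer", delta = 0.5)
      expect_equal(ss, bf_semantic_similarity(dags[[i]], dags[[j]], 0.5))
      expect_gte(ss, 0); expect_lte(ss, 1)
      # symmetry
      expect_equal(ss, semantic_similarity(dags[[j]], dags[[i]], "layer"))
    }
    # self-similarity: shared-node numerator is exactly 2 * DV
    expect_equal(semantic_similarity(dags[[1]], dags[[1]], "layer"), 1)
  }
})

test_that("phenotype lookup takes the max over mapped pairs, absent is a value", {
  tab <- phenotype_table(data.frame(
    pheno_a = c("p1", "p2"), pheno_b = c("p3", "p3"),
    similarity = c(0.2, 0.4)
  ))
  map <- data.frame(term_id = c("A", "A", "B", "C"),
                    phenotype_id = c("p1", "p2", "p3", "p1"))
  expect_equal(phenotype_similarity("A", "B", tab, map), 0.4)
  expect_equal(phenotype_similarity("A", "C", tab, map), 1)  # shared p1
  expect_true(is.na(phenotype_similarity("A", "unmapped", tab, map)))

  expect_error(
    phenotype_table(data.frame(pheno_a = "p1", pheno_b = "p2",
                               similarity = 1.2)),
    class = "hdmp_validation_error"
  )
})

test_that("fused disease similarity: mean fusion, fallback, identity", {
  # lambda-weighted fusion reproduces the published DS example arithmetic
  expect_equal(0.5 * 0.215 + 0.5 * 0.375, 0.295)

  # with phenotype data the fusion is applied ...
  map <- data.frame(term_id = c(ln$disease, pn$disease),
                    phenotype_id = c("p1", "p2"))
  tab <- phenotype_table(data.frame(pheno_a = "p1", pheno_b = "p2",
                                    similarity = 0.8))
  ds <- disease_similarity(ln, pn, "layer", phenotypes = tab, mapping = map,
                           lambda = 0.5)
  expect_equal(ds, 0.5 * 0.375 + 0.5 * 0.8)

  # ... and absent mappings degrade to semantic-only, never an error
  expect_equal(
    disease_similarity(ln, pn, "layer", phenotypes = tab,
                       mapping = data.frame(term_id = ln$disease,
                                            phenotype_id = "p1")),
    0.375
  )
  expect_equal(disease_similarity(ln, ln, "layer"), 1)
})

test_that("group similarity is the best match and grows with the group", {
  ds <- matrix(c(1, 0.319, 0.287,
                 0.319, 1, 0.1,
                 0.287, 0.1, 1), 3, 3,
               dimnames = list(c("d", "x", "y"), c("d", "x", "y")))
  expect_equal(group_similarity("d", c("d", "x"), ds), 1)
  expect_equal(group_similarity("d", "x", ds), 0.319)
  expect_equal(group_similarity("d", c("x", "y"), ds), 0.319)
  # monotone non-decreasing under group enlargement
  expect_gte(group_similarity("d", c("x", "y"), ds),
             group_similarity("d", "y", ds))
  expect_error(group_similarity("d", character(0), ds),
               class = "hdmp_empty_group_error")
})
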
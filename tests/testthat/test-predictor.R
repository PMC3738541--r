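test_that("neighbor selection is top-k with id tie-breaking", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["a", c("b", "c", "d")] <- c(0.5, 0.5, 0.4)
  m[c("b", "c", "d"), "a"] <- c(0.5, 0.5, 0.4)
  diag(m) <- 1

  nb <- select_neighbors(m, "a", 2)
  expect_equal(nb$mirna_id, c("b", "c"))  # tie at 0.5 broken by id

  expect_equal(nrow(select_neighbors(m, "a", 10)), 3)  # pool-limited
  expect_false("a" %in% select_neighbors(m, "a", 3)$mirna_id)
  expect_error(select_neighbors(m, "zz", 2), class = "hdmp_lookup_error")

  # invariant to permuted matrix order
  p <- c(3, 1, 4, 2)
  expect_equal(select_neighbors(m[p, p], "a", 2), nb)
})

test_that("subscores: zero when unlabeled, similarity times shared-group weights", {
  fx <- worked_example()
  nb <- fx$neighborhood
  expect_equal(neighbor_subscore(nb, "mir-1", "mir-2", "d"), 0)
  expect_equal(neighbor_subscore(nb, "mir-1", "mir-5", "d"), 0.6)
  expect_equal(neighbor_subscore(nb, "mir-1", "mir-20", "d"), 0.6 * 1.15)

  # shared family (w = 1.2) and shared cluster (w = 1.1) multiply
  ids <- c("u", "v", "f1", "f2", "f3")
  m <- matrix(0.3, 5, 5, dimnames = list(ids, ids)); diag(m) <- 1
  m["u", "v"] <- m["v", "u"] <- 0.6
  both <- hdmp_data(
    associations = data.frame(
      mirna_id = c("v", "f1", "f2", "v", "f1"),
      disease_id = c("dz", "dz", "dz", "other", "other")
    ),
    similarity = m,
    families = data.frame(group_id = "fam",
                          mirna_id = c("u", "v", "f1", "f2", "f3")),
    clusters = data.frame(group_id = "clu",
                          mirna_id = c("u", "v", "f1", "f2", "f3")),
    alpha = 4, beta = 6
  )
  # family rate 3/5 -> 1.15 at alpha 4; cluster rate 3/5 -> 1.1 at beta 6
  expect_equal(neighbor_subscore(both, "u", "v", "dz"), 0.6 * 1.15 * 1.1)
})

test_that("relevance score sums the k neighbor subscores", {
  fx <- worked_example()
  nb <- fx$neighborhood
  expect_equal(relevance_score(nb, "mir-1", "d"), 1.99)

  # no labeled neighbor in reach -> 0
  expect_equal(relevance_score(nb, "mir-1", "d", k = 0 + 1,
                               labels = data.frame(mirna_id = "mir-23",
                                                   disease_id = "d")), 0)

  # k = pool-1 with all weights 1 reduces to the labeled similarity sum
  ids <- paste0("m", 1:6)
  m <- random_ms(ids, seed = 7)
  lab <- data.frame(mirna_id = c("m2", "m5"), disease_id = "dz")
  d <- hdmp_data(lab, similarity = m)
  expect_equal(relevance_score(d, "m1", "dz", k = 5),
               m["m1", "m2"] + m["m1", "m5"])
})

test_that("candidate ranking is deterministic, dense and score-sorted", {
  fx <- worked_example()
  r <- rank_candidates(fx$neighborhood, "d")
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$score) <= 0))
  expect_equal(r$mirna_id[1], "mir-1")
  expect_equal(r$score[1], 1.99)
  # candidates are exactly the unlabeled miRNAs
  expect_setequal(r$mirna_id,
                  c("mir-1", "mir-2", "mir-8", "mir-16", "mir-23"))

  # equal scores order by ascending id
  ids <- c("b", "a", "c")
  m <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(m) <- 1
  d <- hdmp_data(data.frame(mirna_id = "c", disease_id = "dz"),
                 similarity = m, k = 2)
  r2 <- rank_candidates(d, "dz")
  expect_equal(r2$mirna_id, c("a", "b"))
  expect_equal(r2$rank, c(1L, 2L))

  expect_error(rank_candidates(d, "no-labels-here"),
               class = "hdmp_no_labels_error")
})

test_that("scoring matches an exhaustive reference implementation", {
  for (s in 1:6) {
    n <- 6 + (s %% 5)  # up to 10 miRNAs
    ids <- paste0("m", sprintf("%02d", seq_len(n)))
    m <- random_ms(ids, seed = s)
    inst <- withr::with_seed(200 + s, {
      lab <- data.frame(
        mirna_id = sample(ids, n, replace = TRUE),
        disease_id = sample(c("d1", "d2"), n, replace = TRUE)
      )
      fam <- data.frame(group_id = paste0("f", rep(1:2, each = 3)),
                        mirna_id = sample(ids, 6))
      clus <- data.frame(group_id = "c1", mirna_id = sample(ids, 4))
      list(lab = lab, fam = fam, clus = clus, k = sample(2:6, 1))
    })
    d <- hdmp_data(inst$lab, similarity = m, families = inst$fam,
                   clusters = inst$clus, alpha = 4, beta = 4, k = inst$k)
    r <- rank_candidates(d, "d1")
    for (u in r$mirna_id) {
      expect_equal(r$score[r$mirna_id == u],
                   bf_score(u, "d1", m, as_associations(inst$lab),
                            d$families, d$clusters, 4, 4, inst$k),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores never decrease when labels are added or weights raised", {
  ids <- paste0("m", 1:8)
  m <- random_ms(ids, seed = 11)
  lab <- data.frame(mirna_id = c("m2", "m3"), disease_id = "dz")
  fam <- data.frame(group_id = "f", mirna_id = c("m1", "m2", "m4"))
  base <- hdmp_data(lab, similarity = m, families = fam, alpha = 4, k = 5)
  s0 <- relevance_score(base, "m1", "dz")

  # add a labeled neighbor
  more <- rbind(lab, data.frame(mirna_id = "m4", disease_id = "dz"))
  s1 <- relevance_score(hdmp_data(more, similarity = m, families = fam,
                                  alpha = 4, k = 5), "m1", "dz")
  expect_gte(s1, s0)

  # smaller alpha means a larger family boost
  s2 <- relevance_score(hdmp_data(more, similarity = m, families = fam,
                                  alpha = 1, k = 5), "m1", "dz")
  expect_gte(s2, s1)
})
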
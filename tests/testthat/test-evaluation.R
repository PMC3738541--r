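test_that("fold splits are balanced, disjoint and seed-reproducible", {
  f <- make_folds(paste0("m", 1:10), 5, seed = 3)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  f11 <- make_folds(paste0("m", 1:11), 5, seed = 3)
  expect_equal(sort(unname(table(f11$fold)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L), ignore_attr = TRUE)
  expect_setequal(f11$mirna_id, paste0("m", 1:11))
  expect_equal(make_folds(paste0("m", 1:11), 5, seed = 3), f11)
  expect_false(identical(make_folds(paste0("m", 1:11), 5, seed = 4), f11))
  expect_error(make_folds(paste0("m", 1:3), 5),
               class = "hdmp_insufficient_labels_error")
})

test_that("ROC curve endpoints, closed form and degenerate cases", {
  expect_equal(roc_curve(1:3, 10)$auc, 1)
  expect_equal(roc_curve(8:10, 10)$auc, 0)

  # one positive at rank r in a pool of n: AUC = (n - r) / (n - 1)
  for (n in c(5, 9, 12)) for (r in c(1, 3, n)) {
    expect_equal(roc_curve(r, n)$auc, (n - r) / (n - 1))
  }

  rc <- roc_curve(c(2, 5), 8)
  expect_equal(rc$points$fpr[1], 0)
  expect_equal(rc$points$tpr[nrow(rc$points)], 1)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))

  expect_error(roc_curve(integer(0), 5), class = "hdmp_undefined_curve_error")
})

test_that("AUC equals the Mann-Whitney pair statistic by brute force", {
  for (s in 1:10) {
    inst <- withr::with_seed(s, {
      n <- sample(4:12, 1)
      n_pos <- sample(1:(n - 1), 1)
      # scores with deliberate ties
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      list(pos = scores[1:n_pos], neg = scores[-(1:n_pos)])
    })
    expect_equal(hdmp:::auc_from_scores(inst$pos, inst$neg),
                 bf_auc_pairs(inst$pos, inst$neg))
  }
  # and the rank-based curve agrees when ranks are distinct
  ranks <- c(2, 4, 7)
  scores <- rev(seq_len(9)) / 10  # rank i -> score
  expect_equal(roc_curve(ranks, 9)$auc,
               bf_auc_pairs(scores[ranks], scores[-ranks]))
})

test_that("cross-validation recovers a planted block and stays null on noise", {
  n <- 30
  ids <- paste0("m", sprintf("%02d", 1:n))
  block <- ids[1:10]

  planted_auc <- null_auc <- numeric(20)
  for (s in 1:20) {
    # planted: block members mutually similar, dissimilar to the rest
    m <- random_ms(ids, seed = s) * 0.05
    m[block, block] <- 0.9
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    lab <- data.frame(mirna_id = block, disease_id = "dz")
    d <- hdmp_data(lab, similarity = m, k = 5)
    planted_auc[s] <- attr(evaluate_disease_cv(d, "dz", seed = s), "mean_auc")

    # null: i.i.d. similarity, random labels
    m0 <- random_ms(ids, seed = 1000 + s)
    lab0 <- withr::with_seed(s, data.frame(mirna_id = sample(ids, 10),
                                           disease_id = "dz"))
    d0 <- hdmp_data(lab0, similarity = m0, k = 5)
    null_auc[s] <- attr(evaluate_disease_cv(d0, "dz", seed = s), "mean_auc")
  }
  expect_gte(mean(planted_auc), 0.95)
  expect_gte(mean(null_auc), 0.4)
  expect_lte(mean(null_auc), 0.6)

  # determinism: same data, same seed, same result
  m <- random_ms(ids, seed = 1)
  lab <- data.frame(mirna_id = ids[1:8], disease_id = "dz")
  d <- hdmp_data(lab, similarity = m, k = 5)
  expect_equal(evaluate_disease_cv(d, "dz", seed = 9),
               evaluate_disease_cv(d, "dz", seed = 9))
})

test_that("disabling group weights equals running without group inputs", {
  co <- generate_corpus(n_mirnas = 24, n_modules = 2, seed = 5)
  with_groups <- suppressMessages(
    corpus_data(co, scheme = "layer", alpha = Inf, beta = Inf, k = 10))
  without <- suppressMessages(hdmp_data(
    co$associations, ontology = co$ontology,
    phenotypes = co$phenotypes, phenotype_map = co$phenotype_map,
    scheme = "layer", k = 10))
  cv_a <- hdmp_cv(with_groups, min_labels = 5, seed = 2)
  cv_b <- hdmp_cv(without, min_labels = 5, seed = 2)
  expect_equal(cv_a$folds$auc, cv_b$folds$auc, tolerance = 1e-7)
})

test_that("grand mean is the unweighted mean of per-disease means", {
  co <- generate_corpus(n_mirnas = 24, n_modules = 2, seed = 3)
  d <- suppressMessages(corpus_data(co, scheme = "layer"))
  cv <- hdmp_cv(d, min_labels = 5, seed = 1)
  ev <- cv$diseases[cv$diseases$status == "evaluated", ]
  expect_equal(cv$mean_auc, mean(ev$mean_auc))
  per_fold <- tidy(cv)
  by_disease <- tapply(per_fold$auc, per_fold$disease_id, mean)
  expect_equal(as.numeric(by_disease[ev$disease_id]), ev$mean_auc)
  expect_equal(glance(cv)$mean_auc, cv$mean_auc)
})

test_that("temporal hold-out: skips, perfect single addition, planted signal", {
  ids <- paste0("m", 1:10)
  m <- random_ms(ids, seed = 2) * 0.1
  m["m1", "m2"] <- m["m2", "m1"] <- 0.95  # m1 is m2's obvious partner
  diag(m) <- 1
  old <- data.frame(mirna_id = c("m2", "m3"), disease_id = "dz")
  d <- hdmp_data(old, similarity = m, k = 3)

  # no additions -> skipped
  h0 <- hdmp_holdout(d, old)
  expect_equal(h0$diseases$status, "skipped")

  # a single addition that tops the ranking -> AUC 1
  new <- rbind(old, data.frame(mirna_id = "m1", disease_id = "dz"))
  h1 <- hdmp_holdout(d, new)
  expect_equal(h1$diseases$auc, 1)

  # planted temporal split beats the null across seeds
  aucs <- numeric(10)
  for (s in 1:10) {
    co <- generate_corpus(n_mirnas = 30, n_modules = 2, seed = 300 + s)
    assoc <- co$associations
    split_idx <- withr::with_seed(s, {
      keep <- rep(TRUE, nrow(assoc))
      keep[sample(nrow(assoc), floor(nrow(assoc) * 0.3))] <- FALSE
      keep
    })
    old_assoc <- assoc[split_idx, ]
    dd <- suppressMessages(hdmp_data(old_assoc, ontology = co$ontology,
                                     scheme = "layer", k = 10))
    h <- hdmp_holdout(dd, assoc)
    aucs[s] <- h$mean_auc
  }
  expect_gt(mean(aucs), 0.6)
})

test_that("parameter sweep reports one mean AUC per grid value", {
  co <- generate_corpus(n_mirnas = 20, n_modules = 2, seed = 8)
  d <- suppressMessages(corpus_data(co, scheme = "layer"))
  sw <- hdmp_sweep(d, "k", c(3, 10), min_labels = 5, seed = 1)
  expect_equal(sw$value, c(3, 10))
  expect_true(all(sw$mean_auc >= 0 & sw$mean_auc <= 1))
  sw_a <- hdmp_sweep(d, "alpha", c(1, 4), min_labels = 5, seed = 1)
  expect_equal(nrow(sw_a), 2)
})
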
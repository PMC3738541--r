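# Independent brute-force oracles and small random-instance generators.
# These deliberately re-derive quantities by definition (loops, path
# enumeration, pair counting) so they share no code with the implementation
# paths they check.

# minimum path length disease -> term by Bellman-Ford edge relaxation
bf_min_path <- function(dag) {
  best <- stats::setNames(rep(Inf, nrow(dag$nodes)), dag$nodes$term_id)
  best[dag$disease] <- 0
  for (iter in seq_len(nrow(dag$nodes))) {
    for (i in seq_len(nrow(dag$edges))) {
      ch <- dag$edges$child[i]
      pa <- dag$edges$parent[i]
      if (best[[ch]] + 1 < best[[pa]]) best[[pa]] <- best[[ch]] + 1
    }
  }
  best
}

# layer-scheme semantic similarity by explicit shared-node loop
bf_semantic_similarity <- function(a, b, delta = 0.5) {
  ca <- stats::setNames(delta ^ a$nodes$depth, a$nodes$term_id)
  cb <- stats::setNames(delta ^ b$nodes$depth, b$nodes$term_id)
  num <- 0
  for (t in intersect(names(ca), names(cb))) num <- num + ca[[t]] + cb[[t]]
  num / (sum(ca) + sum(cb))
}

# Mann-Whitney pair statistic, ties counted 1/2, by double loop
bf_auc_pairs <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# reference relevance scorer: every subscore computed by definition
bf_score <- function(u, d, ms, labels, fam, clus, alpha, beta, k) {
  others <- setdiff(rownames(ms), u)
  ord <- order(-ms[u, others], others, method = "radix")
  nb <- others[ord][seq_len(min(k, length(others)))]
  labeled <- unique(labels$mirna_id[labels$disease_id == d])
  total <- 0
  for (v in nb) {
    if (!(v %in% labeled)) next
    w <- 1
    fu <- fam$group_id[fam$mirna_id == u]
    fv <- fam$group_id[fam$mirna_id == v]
    if (length(fu) == 1 && length(fv) == 1 && identical(fu, fv)) {
      mem <- fam$mirna_id[fam$group_id == fu]
      w <- w * (1 + mean(mem %in% labeled) / alpha)
    }
    cu <- clus$group_id[clus$mirna_id == u]
    cv <- clus$group_id[clus$mirna_id == v]
    if (length(cu) == 1 && length(cv) == 1 && identical(cu, cv)) {
      mem <- clus$mirna_id[clus$group_id == cu]
      w <- w * (1 + mean(mem %in% labeled) / beta)
    }
    total <- total + ms[u, v] * w
  }
  total
}

# random small ontology; some terms carry a second tree number, creating
# genuine multi-path DAGs
random_ontology <- function(seed, n_grow = 8, n_extra = 2) {
  withr::with_seed(seed, {
    codes <- c("A", "B")
    owner <- c(1L, 2L)
    for (i in seq_len(n_grow)) {
      parent <- sample(codes, 1)
      codes <- c(codes, paste0(parent, ".", i))
      owner <- c(owner, length(owner) + 1L)
    }
    n_terms <- length(codes)
    tn <- split(codes, owner)
    code_owner <- stats::setNames(owner, codes)
    chain_owners <- function(code) {
      parts <- strsplit(code, ".", fixed = TRUE)[[1]]
      pre <- vapply(seq_along(parts), function(j) {
        paste(parts[seq_len(j)], collapse = ".")
      }, character(1))
      unique(unname(code_owner[pre]))
    }
    extras <- integer(0)
    for (j in seq_len(n_extra)) {
      # keep the hierarchy acyclic: the grafted position must not sit below
      # the receiving term or below any other term that carries an extra code
      for (attempt in 1:50) {
        k <- sample(setdiff(seq_len(n_terms), extras), 1)
        parent <- sample(codes, 1)
        anc <- chain_owners(parent)
        if (!k %in% anc && !any(extras %in% anc)) break
      }
      if (k %in% anc || any(extras %in% anc)) next
      new_code <- paste0(parent, ".x", j)
      tn[[k]] <- c(tn[[k]], new_code)
      codes <- c(codes, new_code)
      code_owner[new_code] <- k
      extras <- c(extras, k)
    }
    as_ontology(tibble::tibble(
      term_id = paste0("t", seq_len(n_terms)),
      name = paste0("term ", seq_len(n_terms)),
      tree_numbers = unname(tn)
    ))
  })
}

# random symmetric similarity matrix with unit diagonal
random_ms <- function(ids, seed) {
  withr::with_seed(seed, {
    n <- length(ids)
    m <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
}
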
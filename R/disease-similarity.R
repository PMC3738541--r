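#' Semantic similarity between two diseases
#'
#' Two diseases are compared through their ancestor DAGs: the similarity is
#' the total contribution of the shared nodes, evaluated in each DAG, over
#' the sum of the two semantic values,
#' \deqn{SS(A,B) = \frac{\sum_{t \in T_A \cap T_B} (D_A(t) + D_B(t))}{DV(A) + DV(B)}.}
#' It is symmetric, lies in \[0, 1\], equals 1 for identical diseases and 0
#' when the DAGs share no node.
#'
#' @param dag_a,dag_b [build_disease_dag()] results from the same ontology.
#' @inheritParams contribution_map
#' @return A scalar in \[0, 1\].
#' @examples
#' fx <- worked_example()
#' a <- build_disease_dag(fx$ontology, "liver neoplasms")
#' b <- build_disease_dag(fx$ontology, "pancreatic neoplasms")
#' semantic_similarity(a, b)  # 2.25 / 6 = 0.375
#' @export
semantic_similarity <- function(dag_a, dag_b, scheme = c("layer", "ic"),
                                delta = 0.5, ic = NULL) {
  stopifnot(inherits(dag_a, "disease_dag"), inherits(dag_b, "disease_dag"))
  if (!identical(attr(dag_a, "ontology_signature"),
                 attr(dag_b, "ontology_signature"))) {
    abort("DAGs were built from different ontologies",
          class = "hdmp_mixed_source_error")
  }
  scheme <- match.arg(scheme)
  ca <- contribution_map(dag_a, scheme, delta = delta, ic = ic)
  cb <- contribution_map(dag_b, scheme, delta = delta, ic = ic)
  shared <- intersect(ca$term_id, cb$term_id)
  if (length(shared) == 0) return(0)
  num <- sum(ca$contribution[match(shared, ca$term_id)]) +
    sum(cb$contribution[match(shared, cb$term_id)])
  num / (semantic_value(ca) + semantic_value(cb))
}

#' Phenotype similarity between two diseases
#'
#' Looks up text-mining phenotype similarity through a many-to-many mapping
#' from ontology terms to phenotype records. When both diseases map to at
#' least one phenotype the similarity is the maximum over all mapped pairs
#' (a shared phenotype id counts as 1); when either disease is unmapped the
#' value is absent (`NA`), which downstream fusion treats as "fall back to
#' semantic similarity", never as an error.
#'
#' @param a,b Ontology term ids.
#' @param phenotypes A [phenotype_table()] (symmetric pairwise similarities
#'   in \[0, 1\], implicit unit diagonal).
#' @param mapping A tibble with columns `term_id`, `phenotype_id`.
#' @return A scalar in \[0, 1\], or `NA_real_` when unmapped.
#' @export
phenotype_similarity <- function(a, b, phenotypes, mapping) {
  if (is.null(phenotypes) || is.null(mapping)) return(NA_real_)
  pa <- mapping$phenotype_id[mapping$term_id == a]
  pb <- mapping$phenotype_id[mapping$term_id == b]
  if (length(pa) == 0 || length(pb) == 0) return(NA_real_)
  best <- if (length(intersect(pa, pb)) > 0) 1 else 0
  if (best < 1 && nrow(phenotypes) > 0) {
    hit <- phenotypes[phenotypes$pheno_a %in% pa & phenotypes$pheno_b %in% pb, ]
    if (nrow(hit) > 0) best <- max(best, hit$similarity)
  }
  best
}

#' Make a symmetric phenotype-similarity table
#'
#' Validates pairwise phenotype similarities and applies symmetric closure,
#' so lookups never depend on pair orientation.
#'
#' @param x A data frame with columns `pheno_a`, `pheno_b`, `similarity`.
#' @return A tibble of class `hdmp_phenotypes` containing both orientations
#'   of every pair.
#' @export
phenotype_table <- function(x) {
  req <- c("pheno_a", "pheno_b", "similarity")
  if (!all(req %in% names(x))) {
    abort("phenotype table needs columns pheno_a, pheno_b, similarity")
  }
  x <- as_tibble(x)[req]
  bad <- which(x$similarity < 0 | x$similarity > 1 | is.na(x$similarity))
  if (length(bad) > 0) {
    abort(paste0("phenotype similarity outside [0, 1] for pair(s): ",
                 paste(paste0(x$pheno_a[bad], "~", x$pheno_b[bad]),
                       collapse = ", ")),
          class = "hdmp_validation_error")
  }
  out <- bind_rows(
    x,
    tibble(pheno_a = x$pheno_b, pheno_b = x$pheno_a, similarity = x$similarity)
  ) |> distinct()
  class(out) <- c("hdmp_phenotypes", class(out))
  out
}

#' Fused disease similarity
#'
#' Combines semantic and phenotype similarity as
#' `DS = lambda * SS + (1 - lambda) * PS` when a phenotype similarity is
#' available, and degrades to `DS = SS` when either disease has no
#' phenotype mapping. `DS(A, A) = 1` and the measure is symmetric.
#'
#' @inheritParams semantic_similarity
#' @inheritParams phenotype_similarity
#' @param lambda Fusion weight on the semantic part, in \[0, 1\]. Default 0.5.
#' @return A scalar in \[0, 1\].
#' @export
disease_similarity <- function(dag_a, dag_b, scheme = c("layer", "ic"),
                               delta = 0.5, ic = NULL, phenotypes = NULL,
                               mapping = NULL, lambda = 0.5) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1]")
  }
  ss <- semantic_similarity(dag_a, dag_b, scheme, delta = delta, ic = ic)
  if (identical(dag_a$disease, dag_b$disease)) return(1)
  ps <- phenotype_similarity(dag_a$disease, dag_b$disease, phenotypes, mapping)
  if (is.na(ps)) ss else lambda * ss + (1 - lambda) * ps
}

#' Similarity between a disease and a disease group
#'
#' The best-match rule: `S(d, DT) = max over d' in DT of DS(d, d')`. Equals
#' 1 whenever `d` itself belongs to the group.
#'
#' @param d An ontology term id.
#' @param dt Character vector of term ids (the group); must be non-empty.
#' @param ds Either a symmetric disease-similarity matrix with term ids as
#'   dimnames, or a function `f(a, b)` returning the pairwise similarity.
#' @return A scalar in \[0, 1\].
#' @export
group_similarity <- function(d, dt, ds) {
  if (length(dt) == 0) abort("empty disease group", class = "hdmp_empty_group_error")
  if (d %in% dt) return(1)
  if (is.function(ds)) {
    max(vapply(dt, function(x) ds(d, x), numeric(1)))
  } else {
    max(ds[d, dt])
  }
}

# Symmetric DS matrix over a set of term ids; the per-run cache behind
# miRNA similarity. DAGs are built once per disease.
disease_similarity_matrix <- function(ontology, diseases,
                                      scheme = "ic", delta = 0.5, ic = NULL,
                                      phenotypes = NULL, mapping = NULL,
                                      lambda = 0.5) {
  diseases <- sort(unique(diseases), method = "radix")
  dags <- lapply(diseases, function(d) build_disease_dag(ontology, d))
  names(dags) <- diseases
  n <- length(diseases)
  m <- diag(1, n)
  dimnames(m) <- list(diseases, diseases)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        v <- disease_similarity(dags[[i]], dags[[j]], scheme, delta = delta,
                                ic = ic, phenotypes = phenotypes,
                                mapping = mapping, lambda = lambda)
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}
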
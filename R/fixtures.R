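#' Worked-example fixture
#'
#' A small, fully deterministic bundle reproducing the method's standard
#' worked examples end to end without any external download:
#'
#' * `ontology`: a 14-term MeSH-style table whose liver-neoplasms DAG has
#'   6 nodes (depths 0,1,1,2,2,3) and whose pancreatic-neoplasms DAG has
#'   8 nodes (three at depth 1, three at depth 2, one at depth 3), plus
#'   breast neoplasms with its two standard chains.
#' * `ic_table`: the six published information-content values for the
#'   liver-neoplasms DAG terms. These are carried as literals (synthetic
#'   stand-ins for a full-vocabulary IC computation, which needs the
#'   complete 4577-term hierarchy): IC(liver neoplasms) = 10.160 etc.
#' * `associations`: the two-miRNA scenario `DT(u) = {liver neoplasms,
#'   breast neoplasms}`, `DT(v) = {pancreatic neoplasms, breast neoplasms}`.
#' * `family_example`: a 5-member family with the disease memberships of
#'   the standard weighting scenario (4 of 5 members labeled for `d2`).
#' * `neighborhood`: an [hdmp_data()] instance (10 miRNAs, precomputed
#'   similarity) in which the query `mir-1` has six nearest neighbors with
#'   labeled similarities 0.6, 0.7 and 0.6, the last sharing a family whose
#'   weight for the query disease works out to 1.15, so
#'   `relevance_score(mir-1) = 0.6 + 0.7 + 0.69 = 1.99`.
#'
#' @return A named list with elements `ontology`, `ic_table`,
#'   `associations`, `family_example`, `neighborhood`.
#' @examples
#' fx <- worked_example()
#' dag <- build_disease_dag(fx$ontology, "liver neoplasms")
#' semantic_value(contribution_map(dag, "layer"))  # 2.625
#' @export
worked_example <- function() {
  ontology <- as_ontology(tibble(
    term_id = c("D009369", "D009371", "D004067", "D008113", "D010190",
                "D004066", "D008107", "D010182", "D004700", "D004701",
                "D001943", "D017437", "D012871", "D001941"),
    name = c("neoplasms", "neoplasms by site", "digestive system neoplasms",
             "liver neoplasms", "pancreatic neoplasms",
             "digestive system diseases", "liver diseases",
             "pancreatic diseases", "endocrine system diseases",
             "endocrine gland neoplasms", "breast neoplasms",
             "skin and connective tissue diseases", "skin diseases",
             "breast diseases"),
    tree_numbers = list(
      "C04", "C04.588", "C04.588.274",
      c("C04.588.274.623", "C06.552.697"),
      c("C04.588.274.761", "C19.344.421", "C06.689.667"),
      "C06", "C06.552", "C06.689", "C19", "C19.344",
      c("C04.588.180", "C17.800.090.500"),
      "C17", "C17.800", "C17.800.090"
    )
  ))

  # published IC values for the liver-neoplasms DAG terms (synthetic table:
  # recomputing them requires the full disease vocabulary)
  ic_table <- tibble(
    term_id = c("D008113", "D004067", "D009371", "D009369", "D008107",
                "D004066"),
    ic = c(10.160, 6.838, 4.453, 2.785, 6.116, 3.961)
  )

  associations <- as_associations(tibble(
    mirna_id = c("mir-u", "mir-u", "mir-v", "mir-v"),
    disease_id = c("D008113", "D001943", "D010190", "D001943")
  ))

  family_example <- list(
    members = c("m1", "m2", "m3", "m4", "m5"),
    associations = as_associations(tibble(
      mirna_id = c("m1", "m3",
                   "m1", "m2", "m4", "m5",
                   "m2", "m3", "m4",
                   "m2", "m3",
                   "m3", "m5"),
      disease_id = c(rep("d1", 2), rep("d2", 4), rep("d3", 3),
                     rep("d4", 2), rep("d5", 2))
    ))
  )

  ids <- c("mir-1", "mir-2", "mir-5", "mir-8", "mir-10", "mir-16",
           "mir-20", "mir-21", "mir-22", "mir-23")
  ms <- matrix(0.2, nrow = 10, ncol = 10, dimnames = list(ids, ids))
  q <- c("mir-2" = 0.5, "mir-5" = 0.6, "mir-8" = 0.45, "mir-10" = 0.7,
         "mir-16" = 0.4, "mir-20" = 0.6, "mir-21" = 0.1, "mir-22" = 0.08,
         "mir-23" = 0.05)
  ms["mir-1", names(q)] <- q
  ms[names(q), "mir-1"] <- q
  diag(ms) <- 1

  neighborhood <- hdmp_data(
    associations = tibble(
      mirna_id = c("mir-5", "mir-10", "mir-20", "mir-21", "mir-22"),
      disease_id = "d"
    ),
    similarity = ms,
    families = tibble(group_id = "fam_i",
                      mirna_id = c("mir-1", "mir-20", "mir-21", "mir-22",
                                   "mir-23")),
    alpha = 4, k = 6
  )

  list(ontology = ontology, ic_table = ic_table, associations = associations,
       family_example = family_example, neighborhood = neighborhood)
}

#' Generate a synthetic planted-module corpus
#'
#' Emits a deterministic, self-contained corpus for end-to-end testing: a
#' tree-structured ontology whose leaves are diseases, miRNAs partitioned
#' into modules, and associations drawn so that each module's miRNAs share
#' a semantically close disease group (sibling leaves under one branch)
#' with probability `p_in`, against background probability `p_out` for all
#' other diseases. Families and genomic clusters are aligned with modules,
#' and a phenotype layer mirrors the module structure. With
#' `p_in > p_out` the corpus carries a planted signal that a working
#' prioritizer must recover; with `p_in = p_out` (see [null_corpus()])
#' associations are independent of the ontology and ranking is
#' uninformative by construction.
#'
#' @param n_mirnas Number of miRNAs, default 60.
#' @param n_modules Number of planted modules, default 4.
#' @param diseases_per_module Sibling-leaf diseases per module, default 5.
#' @param p_in Within-module association probability, default 0.8.
#' @param p_out Background association probability, default 0.05.
#' @param family_size,cluster_size Members per module-aligned family and
#'   cluster, defaults 5 and 4.
#' @param include_phenotypes Emit the phenotype layer? Default `TRUE`.
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   arguments.
#' @return A list of class `hdmp_corpus` with elements `ontology`,
#'   `associations`, `families`, `loci`, `phenotypes`, `phenotype_map`,
#'   `params`.
#' @export
generate_corpus <- function(n_mirnas = 60, n_modules = 4,
                            diseases_per_module = 5, p_in = 0.8,
                            p_out = 0.05, family_size = 5, cluster_size = 4,
                            include_phenotypes = TRUE, seed = 1) {
  stopifnot(n_mirnas >= 1, n_modules >= 1, diseases_per_module >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1, p_in >= p_out)

  ont_rows <- list()
  disease_ids <- list()
  for (i in seq_len(n_modules)) {
    root <- sprintf("C%02d", i)
    leaves <- sprintf("%s.500.%03d", root, seq_len(diseases_per_module))
    ids <- sprintf("disease_%02d_%02d", i, seq_len(diseases_per_module))
    ont_rows[[i]] <- tibble(
      term_id = c(sprintf("root_%02d", i), sprintf("branch_%02d", i), ids),
      name = c(sprintf("module %d root", i), sprintf("module %d branch", i),
               gsub("_", " ", ids)),
      tree_numbers = as.list(c(root, paste0(root, ".500"), leaves))
    )
    disease_ids[[i]] <- ids
  }
  ontology <- as_ontology(bind_rows(ont_rows))
  all_diseases <- unlist(disease_ids)

  mirnas <- sprintf("hsa-mir-%03d", seq_len(n_mirnas))
  module_of <- rep_len(seq_len(n_modules), n_mirnas)

  corpus <- withr::with_seed(seed, {
    rows <- list()
    for (j in seq_len(n_mirnas)) {
      own <- disease_ids[[module_of[j]]]
      others <- setdiff(all_diseases, own)
      hit <- c(own[stats::runif(length(own)) < p_in],
               others[stats::runif(length(others)) < p_out])
      if (length(hit) == 0) hit <- sample(own, 1)
      rows[[j]] <- tibble(mirna_id = mirnas[j], disease_id = hit)
    }
    associations <- bind_rows(rows)

    fam_rows <- clus_rows <- loci_rows <- list()
    for (i in seq_len(n_modules)) {
      members <- mirnas[module_of == i]
      fam <- head(members, family_size)
      if (length(fam) >= 2) {
        fam_rows[[i]] <- tibble(group_id = sprintf("fam_%02d", i),
                                mirna_id = fam)
      }
      clus <- head(setdiff(members, fam), cluster_size)
      if (length(clus) > 0) {
        clus_rows[[i]] <- tibble(mirna_id = clus, chrom = sprintf("chr%d", i),
                                 start = 1e6 + (seq_along(clus) - 1) * 5000,
                                 end = 1e6 + (seq_along(clus) - 1) * 5000 + 80,
                                 strand = "+")
      }
      rest <- setdiff(members, c(fam, clus))
      if (length(rest) > 0) {
        loci_rows[[i]] <- tibble(mirna_id = rest, chrom = sprintf("chr%d", i),
                                 start = 5e6 + (seq_along(rest) - 1) * 1e6,
                                 end = 5e6 + (seq_along(rest) - 1) * 1e6 + 80,
                                 strand = "-")
      }
    }
    loci <- bind_rows(c(clus_rows, loci_rows))

    phenotypes <- NULL
    phenotype_map <- NULL
    if (include_phenotypes) {
      phenotype_map <- tibble(
        term_id = all_diseases,
        phenotype_id = sprintf("MIM:%06d", 100000 + seq_along(all_diseases))
      )
      pm <- setNames(phenotype_map$phenotype_id, phenotype_map$term_id)
      pairs <- list()
      for (i in seq_len(n_modules)) {
        ids <- disease_ids[[i]]
        if (length(ids) < 2) next
        cmb <- utils::combn(ids, 2)
        pairs[[i]] <- tibble(
          pheno_a = unname(pm[cmb[1, ]]), pheno_b = unname(pm[cmb[2, ]]),
          similarity = round(stats::runif(ncol(cmb), 0.5, 0.9), 3)
        )
      }
      phenotypes <- phenotype_table(bind_rows(pairs))
    }

    list(associations = as_associations(associations),
         loci = loci,
         families = if (length(fam_rows) > 0) bind_rows(fam_rows) else NULL,
         phenotypes = phenotypes, phenotype_map = phenotype_map)
  })

  structure(
    c(list(ontology = ontology), corpus,
      list(params = list(n_mirnas = n_mirnas, n_modules = n_modules,
                         diseases_per_module = diseases_per_module,
                         p_in = p_in, p_out = p_out,
                         family_size = family_size,
                         cluster_size = cluster_size, seed = seed))),
    class = "hdmp_corpus"
  )
}

#' Generate a null corpus
#'
#' Associations are drawn independently of the ontology structure
#' (`p_in = p_out`), so disease labels carry no functional signal and
#' cross-validated AUC is expected to sit near 0.5.
#'
#' @inheritParams generate_corpus
#' @param p Uniform association probability, default 0.1.
#' @return See [generate_corpus()].
#' @export
null_corpus <- function(n_mirnas = 60, n_modules = 4,
                        diseases_per_module = 5, p = 0.1,
                        include_phenotypes = TRUE, seed = 1) {
  generate_corpus(n_mirnas = n_mirnas, n_modules = n_modules,
                  diseases_per_module = diseases_per_module,
                  p_in = p, p_out = p,
                  include_phenotypes = include_phenotypes, seed = seed)
}

#' Build an [hdmp_data()] object from a generated corpus
#'
#' @param corpus A [generate_corpus()] bundle.
#' @param ... Passed on to [hdmp_data()] (scheme, k, alpha, ...).
#' @return An `hdmp_data` object.
#' @export
corpus_data <- function(corpus, ...) {
  stopifnot(inherits(corpus, "hdmp_corpus"))
  hdmp_data(associations = corpus$associations, ontology = corpus$ontology,
            families = corpus$families, loci = corpus$loci,
            phenotypes = corpus$phenotypes,
            phenotype_map = corpus$phenotype_map, ...)
}
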
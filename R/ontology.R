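#' Construct and validate a disease ontology table
#'
#' An ontology is a tibble with one row per disease term and three columns:
#' `term_id` (unique key), `name` (display name, matched case- and
#' whitespace-insensitively) and `tree_numbers` (a list column of
#' dot-separated position codes, MeSH-style, e.g. `"C06.552.697"`). A term
#' may occupy several tree positions; each position implies one chain of
#' ancestors obtained by repeatedly stripping the last dotted component.
#' Terms whose codes have a single component are hierarchy roots.
#'
#' @param x A data frame with columns `term_id`, `name` and `tree_numbers`.
#'   `tree_numbers` may be a list of character vectors or a character column
#'   with semicolon-separated codes.
#' @return A validated ontology tibble of class `hdmp_ontology`.
#' @examples
#' ont <- as_ontology(data.frame(
#'   term_id = c("D1", "D2"),
#'   name = c("neoplasms", "liver neoplasms"),
#'   tree_numbers = c("C04", "C04.588")
#' ))
#' @export
as_ontology <- function(x) {
  req <- c("term_id", "name", "tree_numbers")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("ontology table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(x)[req]
  out$term_id <- as.character(out$term_id)
  out$name <- normalize_name(out$name)
  if (!is.list(out$tree_numbers)) {
    out$tree_numbers <- strsplit(as.character(out$tree_numbers), ";", fixed = TRUE)
  }
  out$tree_numbers <- map(out$tree_numbers, function(tn) {
    tn <- trimws(tn)
    unique(tn[nzchar(tn)])
  })
  validate_ontology(out)
  class(out) <- c("hdmp_ontology", class(out))
  out
}

validate_ontology <- function(ont) {
  if (nrow(ont) == 0) abort("ontology is empty")
  dup <- ont$term_id[duplicated(ont$term_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate term_id in ontology: ",
                 paste(unique(dup), collapse = ", ")))
  }
  n_tn <- lengths(ont$tree_numbers)
  if (any(n_tn == 0)) {
    abort(paste0("terms without tree numbers: ",
                 paste(ont$term_id[n_tn == 0], collapse = ", ")))
  }
  all_tn <- unlist(ont$tree_numbers, use.names = FALSE)
  if (anyDuplicated(all_tn)) {
    abort(paste0("tree number assigned to more than one term: ",
                 paste(unique(all_tn[duplicated(all_tn)]), collapse = ", ")))
  }
  # every multi-component code must have a resolvable parent prefix
  parents <- parent_code(all_tn)
  dangling <- setdiff(parents[!is.na(parents)], all_tn)
  if (length(dangling) > 0) {
    abort(paste0("dangling tree-number prefix(es) not assigned to any term: ",
                 paste(sort(dangling), collapse = ", ")))
  }
  invisible(ont)
}

# "C06.552.697" -> "C06.552"; single-component codes (roots) -> NA
parent_code <- function(code) {
  has_parent <- grepl(".", code, fixed = TRUE)
  out <- rep(NA_character_, length(code))
  out[has_parent] <- sub("\\.[^.]+$", "", code[has_parent])
  out
}

normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# map every tree number -> owning term_id (named character vector)
tree_number_index <- function(ontology) {
  tn <- unlist(ontology$tree_numbers, use.names = FALSE)
  owner <- rep(ontology$term_id, lengths(ontology$tree_numbers))
  setNames(owner, tn)
}

ontology_signature <- function(ontology) {
  rlang::hash(list(ontology$term_id, ontology$tree_numbers))
}

# resolve a disease given as term_id or (normalized) name
resolve_term <- function(ontology, disease) {
  disease <- as.character(disease)
  if (disease %in% ontology$term_id) return(disease)
  hit <- ontology$term_id[ontology$name == normalize_name(disease)]
  if (length(hit) == 1) return(hit)
  abort(paste0("unknown disease term: '", disease, "'"),
        class = "hdmp_lookup_error")
}

#' Build the ancestor DAG of one disease term
#'
#' The DAG of a disease is the union of all ancestor chains implied by each
#' of its tree numbers: for a code `C06.552.697`, the chain is the terms
#' holding `C06.552.697`, `C06.552` and `C06`. Nodes are deduplicated by
#' term and each node is labelled with its minimum depth, i.e. the smallest
#' number of child-to-parent steps from the disease node (the disease itself
#' has depth 0).
#'
#' @param ontology An [as_ontology()] table.
#' @param disease A `term_id` present in the ontology, or a term name
#'   (matched case-insensitively).
#' @return An object of class `disease_dag`: a list with elements `disease`
#'   (the resolved term_id), `nodes` (tibble `term_id`, `name`, `depth`)
#'   and `edges` (tibble `child`, `parent` of term ids).
#' @examples
#' ont <- worked_example()$ontology
#' dag <- build_disease_dag(ont, "liver neoplasms")
#' dag$nodes
#' @export
build_disease_dag <- function(ontology, disease) {
  ontology <- as_ontology(ontology)
  id <- resolve_term(ontology, disease)
  idx <- tree_number_index(ontology)
  codes <- ontology$tree_numbers[[match(id, ontology$term_id)]]

  all_terms <- character(0)
  edges <- character(0)
  for (code in codes) {
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    chain_codes <- vapply(seq_along(parts), function(j) {
      paste(parts[seq_len(j)], collapse = ".")
    }, character(1))
    chain_terms <- unname(idx[chain_codes])
    if (anyNA(chain_terms)) {
      abort(paste0("tree number '", code, "' has unresolvable prefix(es)"),
            class = "hdmp_ontology_integrity_error")
    }
    all_terms <- c(all_terms, chain_terms)
    if (length(chain_terms) > 1) {
      # chain runs root..disease; edges point child -> parent
      for (j in seq.int(2, length(chain_terms))) {
        edges <- c(edges, paste0(chain_terms[j], "\r", chain_terms[j - 1]))
      }
    }
  }
  all_terms <- unique(all_terms)
  edges <- unique(edges)
  edge_mat <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
  edges_tbl <- if (length(edges) == 0) {
    tibble(child = character(), parent = character())
  } else {
    tibble(child = edge_mat[, 1], parent = edge_mat[, 2])
  }

  # depth = shortest child-to-parent path from the disease node, so a term
  # reachable at several levels takes its minimum (the recursive
  # max-contribution rule with delta < 1 picks exactly this distance)
  node_depth <- setNames(rep(Inf, length(all_terms)), all_terms)
  node_depth[id] <- 0L
  frontier <- id
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(edges_tbl$parent[edges_tbl$child %in% frontier])
    nxt <- nxt[node_depth[nxt] > d]
    node_depth[nxt] <- d
    frontier <- nxt
  }

  ord <- order(node_depth, names(node_depth), method = "radix")
  nodes <- tibble(
    term_id = names(node_depth)[ord],
    name = ontology$name[match(names(node_depth)[ord], ontology$term_id)],
    depth = as.integer(node_depth[ord])
  )

  structure(
    list(disease = id, nodes = nodes, edges = edges_tbl),
    class = "disease_dag",
    ontology_signature = ontology_signature(ontology)
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("<disease_dag> ", x$disease, ": ", nrow(x$nodes), " node(s), max depth ",
      max(x$nodes$depth), "\n", sep = "")
  print(x$nodes, ...)
  invisible(x)
}

#' Per-node semantic contributions of a disease DAG
#'
#' Under the layer scheme a node at depth `k` contributes `delta^k`, so the
#' disease itself contributes 1 and ever more general ancestors contribute
#' geometrically less. Under the information-content (IC) scheme each node
#' contributes its IC, so rare (specific) terms contribute more than common
#' ones regardless of layer.
#'
#' @param dag A [build_disease_dag()] result.
#' @param scheme `"layer"` or `"ic"`.
#' @param delta Semantic contribution factor in (0, 1], layer scheme only.
#'   Default 0.5.
#' @param ic An [compute_information_content()] table (or any tibble with
#'   columns `term_id`, `ic`); required for the IC scheme and must cover
#'   every DAG node.
#' @return A tibble `term_id`, `depth`, `contribution` with attributes
#'   `scheme` and (layer only) `delta`.
#' @examples
#' fx <- worked_example()
#' dag <- build_disease_dag(fx$ontology, "liver neoplasms")
#' contribution_map(dag, "layer", delta = 0.5)
#' @export
contribution_map <- function(dag, scheme = c("layer", "ic"), delta = 0.5,
                             ic = NULL) {
  stopifnot(inherits(dag, "disease_dag"))
  scheme <- match.arg(scheme)
  nodes <- dag$nodes
  if (scheme == "layer") {
    if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
      abort("`delta` must be a single number in (0, 1]")
    }
    out <- tibble(term_id = nodes$term_id, depth = nodes$depth,
                  contribution = delta ^ nodes$depth)
    attr(out, "delta") <- delta
  } else {
    if (is.null(ic)) abort("IC scheme requires an `ic` table")
    pos <- match(nodes$term_id, ic$term_id)
    if (anyNA(pos)) {
      abort(paste0("IC table does not cover DAG node(s): ",
                   paste(nodes$term_id[is.na(pos)], collapse = ", ")),
            class = "hdmp_coverage_error")
    }
    out <- tibble(term_id = nodes$term_id, depth = nodes$depth,
                  contribution = ic$ic[pos])
  }
  attr(out, "scheme") <- scheme
  out
}

#' Semantic value of a disease
#'
#' The semantic value DV of a disease is the sum of the semantic
#' contributions of every node in its ancestor DAG. It normalizes the
#' pairwise semantic similarity.
#'
#' @param contributions A [contribution_map()] tibble.
#' @return A positive scalar.
#' @examples
#' fx <- worked_example()
#' dag <- build_disease_dag(fx$ontology, "liver neoplasms")
#' semantic_value(contribution_map(dag, "layer"))  # 2.625
#' @export
semantic_value <- function(contributions) {
  if (is.null(contributions) || nrow(contributions) == 0) {
    abort("empty contribution map", class = "hdmp_empty_input_error")
  }
  sum(contributions$contribution)
}

#' Information content of every ontology term
#'
#' Each of the N ontology terms induces one disease DAG. A term `t`
#' contained in `n_t` of those DAGs (every term contains itself, so
#' `n_t >= 1`) has information content `IC(t) = -log(n_t / N)`; terms shared
#' by all DAGs have IC 0, and the rarer a term is the larger its IC.
#'
#' @param ontology An [as_ontology()] table.
#' @param base Logarithm base; default 2.
#' @return A tibble `term_id`, `n_dags`, `ic` with attribute `total_dags`.
#' @examples
#' ont <- as_ontology(data.frame(
#'   term_id = c("a", "b", "c"), name = c("a", "b", "c"),
#'   tree_numbers = c("R.1.1", "R.1", "R")
#' ))
#' compute_information_content(ont)  # IC = log2(3), log2(1.5), 0
#' @export
compute_information_content <- function(ontology, base = 2) {
  ontology <- as_ontology(ontology)
  idx <- tree_number_index(ontology)
  n <- integer(nrow(ontology))
  names(n) <- ontology$term_id
  for (i in seq_len(nrow(ontology))) {
    anc <- character(0)
    for (code in ontology$tree_numbers[[i]]) {
      parts <- strsplit(code, ".", fixed = TRUE)[[1]]
      chain <- vapply(seq_along(parts), function(j) {
        paste(parts[seq_len(j)], collapse = ".")
      }, character(1))
      anc <- c(anc, unname(idx[chain]))
    }
    anc <- unique(anc)
    n[anc] <- n[anc] + 1L
  }
  total <- nrow(ontology)
  out <- tibble(
    term_id = ontology$term_id,
    n_dags = as.integer(n[ontology$term_id]),
    ic = unname(-log(n[ontology$term_id] / total, base = base))
  )
  attr(out, "total_dags") <- total
  out
}
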
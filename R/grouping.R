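#' Build genomic miRNA clusters from precursor coordinates
#'
#' miRNAs transcribed from the same genomic neighbourhood are often
#' co-regulated, so precursors lying close together on a chromosome are
#' grouped into one cluster. Per chromosome, loci are sorted by start and
#' chained single-linkage: a locus joins the running cluster when the gap
#' to the previous interval (`next start - previous end - 1`, floored at 0
#' for overlaps) is at most `max_gap`. Clustering ignores strand. A miRNA
#' with several loci joins every cluster any locus falls in, and clusters
#' sharing a miRNA are then unioned. Singleton clusters are discarded: a
#' lone miRNA can never share its cluster with a neighbour, so it is
#' weight-neutral.
#'
#' @param loci A tibble with columns `mirna_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `strand`.
#' @param max_gap Maximum inter-interval gap in bp; default 20000 (20 kb).
#' @return A group catalog: tibble `group_id`, `mirna_id` with attribute
#'   `kind = "cluster"`.
#' @export
build_clusters <- function(loci, max_gap = 20000) {
  req <- c("mirna_id", "chrom", "start", "end")
  if (!all(req %in% names(loci))) {
    abort("loci need columns mirna_id, chrom, start, end")
  }
  loci <- as_tibble(loci)
  bad <- which(!nzchar(as.character(loci$chrom)) | is.na(loci$start) |
                 is.na(loci$end) | loci$start > loci$end)
  if (length(bad) > 0) {
    abort(paste0("malformed locus at row(s): ", paste(bad, collapse = ", ")),
          class = "hdmp_parse_error")
  }
  loci$mirna_id <- normalize_mirna_id(loci$mirna_id)
  loci <- arrange(loci, chrom, start, end, mirna_id)

  # chained intervals per chromosome
  raw <- list()
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, ]
    cur <- sub$mirna_id[1]
    cur_end <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      gap <- max(0, sub$start[i] - cur_end - 1)
      if (gap <= max_gap) {
        cur <- c(cur, sub$mirna_id[i])
      } else {
        raw[[length(raw) + 1]] <- unique(cur)
        cur <- sub$mirna_id[i]
      }
      cur_end <- max(cur_end, sub$end[i])
    }
    raw[[length(raw) + 1]] <- unique(cur)
  }

  # union clusters sharing a miRNA (multi-locus precursors)
  merged <- list()
  for (cl in raw) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      merged[[length(merged) + 1]] <- cl
    } else {
      pooled <- unique(c(unlist(merged[hit]), cl))
      merged <- merged[-hit]
      merged[[length(merged) + 1]] <- pooled
    }
  }
  merged <- keep(merged, ~ length(.x) >= 2)
  merged <- lapply(merged, function(m) sort(m, method = "radix"))
  merged <- merged[order(map_chr(merged, 1), method = "radix")]

  out <- tibble(
    group_id = rep(sprintf("cluster_%d", seq_along(merged)), lengths(merged)),
    mirna_id = unlist(merged) %||% character(0)
  )
  attr(out, "kind") <- "cluster"
  out
}

#' Rate of disease-labeled miRNAs in a group
#'
#' For a family or cluster, the fraction of its members experimentally
#' associated with disease `d`. A high rate means most of the group is
#' already implicated, making the remaining members stronger candidates.
#'
#' @param group Character vector of miRNA ids (non-empty).
#' @param disease An ontology term id.
#' @param associations An [as_associations()] table (the current labels).
#' @return A scalar in \[0, 1\].
#' @examples
#' labels <- data.frame(mirna_id = c("m1", "m2", "m4", "m5"), disease_id = "d2")
#' group_rate(c("m1", "m2", "m3", "m4", "m5"), "d2", labels)  # 0.8
#' @export
group_rate <- function(group, disease, associations) {
  group <- unique(normalize_mirna_id(group))
  if (length(group) == 0) abort("empty group", class = "hdmp_empty_group_error")
  associations <- as_associations(associations)
  labeled <- unique(associations$mirna_id[associations$disease_id == disease])
  sum(group %in% labeled) / length(group)
}

#' Group weight from a labeling rate
#'
#' `w = 1 + rate / factor`, so the weight is 1 when no member is labeled
#' and at most `1 + 1/factor` when all are. The adjustment factor (alpha
#' for families, beta for clusters) damps the boost; its default 4 caps
#' the boost at 25%.
#'
#' @param rate Labeling rate in \[0, 1\].
#' @param factor Positive adjustment factor; default 4.
#' @return A weight in \[1, 1 + 1/factor\].
#' @examples
#' group_weight(0.8, 4)  # 1.2
#' @export
group_weight <- function(rate, factor = 4) {
  if (!is.numeric(factor) || any(factor <= 0)) {
    abort("`factor` must be > 0", class = "hdmp_parameter_error")
  }
  if (any(rate < 0 | rate > 1)) abort("`rate` must lie in [0, 1]")
  1 + rate / factor
}

#' Per-disease weights for every group in a catalog
#'
#' @param catalog A group catalog (tibble `group_id`, `mirna_id`).
#' @param disease An ontology term id.
#' @param associations Current labels, see [group_rate()].
#' @param factor Adjustment factor passed to [group_weight()].
#' @return A tibble `group_id`, `rate`, `weight`.
#' @export
group_weight_table <- function(catalog, disease, associations, factor = 4) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    return(tibble(group_id = character(), rate = numeric(), weight = numeric()))
  }
  associations <- as_associations(associations)
  groups <- split(catalog$mirna_id, catalog$group_id)
  r <- map_dbl(groups, group_rate, disease = disease,
               associations = associations)
  tibble(group_id = names(groups), rate = unname(r),
         weight = group_weight(unname(r), factor))
}

# restrict a catalog to miRNAs present in the dataset; group sizes are
# measured against dataset members only
restrict_catalog <- function(catalog, universe) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    return(tibble(group_id = character(), mirna_id = character()))
  }
  catalog <- as_tibble(catalog)
  catalog$mirna_id <- normalize_mirna_id(catalog$mirna_id)
  out <- distinct(catalog[catalog$mirna_id %in% universe,
                          c("group_id", "mirna_id")])
  out[order(out$group_id, out$mirna_id, method = "radix"), ]
}
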
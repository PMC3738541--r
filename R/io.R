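#' Read a disease ontology file
#'
#' Auto-detects the dialect from the first non-blank line: either a TSV
#' with header `term_id  name  tree_numbers` (tree numbers
#' semicolon-separated) or MeSH-style ASCII descriptor records
#' (`*NEWRECORD` blocks with `MH = `, `UI = ` and `MN = ` lines). Tree
#' number integrity (every multi-component code has a resolvable parent)
#' is validated on load.
#'
#' @param path Path to the ontology file.
#' @return An [as_ontology()] table.
#' @export
read_ontology <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("empty ontology file", class = "hdmp_parse_error")
  }
  first <- lines[1]
  if (grepl("^\\*NEWRECORD", first) || grepl("^(MH|UI|MN) = ", first)) {
    parse_mesh_ascii(lines)
  } else {
    parse_ontology_tsv(lines)
  }
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

parse_ontology_tsv <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!all(c("term_id", "name", "tree_numbers") %in% header)) {
    abort("ontology TSV needs header columns term_id, name, tree_numbers",
          class = "hdmp_parse_error")
  }
  body <- fields[-1]
  bad <- which(lengths(body) != length(header))
  if (length(bad) > 0) {
    abort(paste0("malformed ontology line ", bad[1] + 1),
          class = "hdmp_parse_error")
  }
  m <- do.call(rbind, body)
  colnames(m) <- header
  as_ontology(tibble(term_id = m[, "term_id"], name = m[, "name"],
                     tree_numbers = m[, "tree_numbers"]))
}

parse_mesh_ascii <- function(lines) {
  recs <- list()
  cur <- list()
  flush <- function(cur, recs) {
    if (length(cur) == 0) return(recs)
    recs[[length(recs) + 1]] <- cur
    recs
  }
  for (ln in lines) {
    if (grepl("^\\*NEWRECORD", ln)) {
      recs <- flush(cur, recs)
      cur <- list()
    } else if (grepl("^MH = ", ln)) {
      cur$name <- sub("^MH = ", "", ln)
    } else if (grepl("^UI = ", ln)) {
      cur$term_id <- sub("^UI = ", "", ln)
    } else if (grepl("^MN = ", ln)) {
      cur$tn <- c(cur$tn, sub("^MN = ", "", ln))
    }
  }
  recs <- flush(cur, recs)
  recs <- keep(recs, ~ !is.null(.x$name) && length(.x$tn) > 0)
  if (length(recs) == 0) {
    abort("no usable MeSH records found", class = "hdmp_parse_error")
  }
  as_ontology(tibble(
    term_id = map_chr(recs, ~ .x$term_id %||% .x$name),
    name = map_chr(recs, "name"),
    tree_numbers = map(recs, "tn")
  ))
}

#' Read a miRNA-disease association file
#'
#' Two tab-separated columns, `mirna_id` then disease (term id or name);
#' `#` lines are comments and a header row is detected and skipped. Names
#' are normalized, pairs with diseases absent from the ontology are
#' dropped with a message, and duplicates collapse to one pair.
#'
#' @param path Path to the TSV file.
#' @param ontology Optional [as_ontology()] table for resolution/filtering.
#' @return An [as_associations()] table.
#' @export
read_associations <- function(path, ontology = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    abort("no associations in file", class = "hdmp_empty_associations_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed association line ", bad[1]),
          class = "hdmp_parse_error")
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:2]))
  if (identical(tolower(m[1, 1]), "mirna_id")) m <- m[-1, , drop = FALSE]
  as_associations(tibble(mirna_id = m[, 1], disease_id = m[, 2]),
                  ontology = ontology)
}

#' Read a miRNA family file
#'
#' Accepts either miFam-style stanzas (`AC`/`ID` header lines, one `MI`
#' line per member whose last field is the miRNA name, records separated
#' by `//`) or a two-column TSV `family_id  mirna_id`.
#'
#' @param path Path to the family file.
#' @return A group catalog tibble `group_id`, `mirna_id`.
#' @export
read_family <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(group_id = character(),
                                        mirna_id = character()))
  if (any(grepl("^(AC|ID|MI)\\s", lines))) {
    parse_mifam(lines)
  } else {
    lines <- lines[!grepl("^#", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) {
      abort(paste0("malformed family line ", bad[1]),
            class = "hdmp_parse_error")
    }
    m <- do.call(rbind, lapply(fields, function(f) f[1:2]))
    if (identical(tolower(m[1, 1]), "family_id")) m <- m[-1, , drop = FALSE]
    distinct(tibble(group_id = m[, 1],
                    mirna_id = normalize_mirna_id(m[, 2])))
  }
}

parse_mifam <- function(lines) {
  out <- list()
  fam <- NULL
  members <- character(0)
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) {
      fam <- trimws(sub("^ID\\s+", "", ln))
    } else if (grepl("^AC\\s", ln) && is.null(fam)) {
      fam <- trimws(sub("^AC\\s+", "", ln))
    } else if (grepl("^MI\\s", ln)) {
      parts <- strsplit(trimws(sub("^MI\\s+", "", ln)), "\\s+")[[1]]
      members <- c(members, parts[length(parts)])
    } else if (grepl("^//", ln)) {
      if (!is.null(fam) && length(members) > 0) {
        out[[length(out) + 1]] <- tibble(group_id = fam,
                                         mirna_id = members)
      }
      fam <- NULL
      members <- character(0)
    }
  }
  if (!is.null(fam) && length(members) > 0) {
    out[[length(out) + 1]] <- tibble(group_id = fam, mirna_id = members)
  }
  res <- bind_rows(out)
  res$mirna_id <- normalize_mirna_id(res$mirna_id)
  distinct(res)
}

#' Read miRNA precursor coordinates from GFF3
#'
#' Keeps `miRNA_primary_transcript` features (all features when the file
#' carries no type column matches) and takes the miRNA id from the `Name=`
#' attribute. Coordinates are 1-based inclusive, GFF3 convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble `mirna_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_loci_gff3 <- function(path) {
  lines <- read_text_lines(path)
  keep_idx <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  rows <- list()
  for (i in keep_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      abort(paste0("malformed GFF3 line ", i), class = "hdmp_parse_error")
    }
    if (f[3] != "miRNA_primary_transcript") next
    name <- sub(".*Name=([^;]+).*", "\\1", f[9])
    if (identical(name, f[9]) && !grepl("Name=", f[9])) {
      abort(paste0("GFF3 line ", i, " lacks a Name= attribute"),
            class = "hdmp_parse_error")
    }
    rows[[length(rows) + 1]] <- tibble(
      mirna_id = normalize_mirna_id(name), chrom = f[1],
      start = as.numeric(f[4]), end = as.numeric(f[5]), strand = f[7]
    )
  }
  if (length(rows) == 0) {
    return(tibble(mirna_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character()))
  }
  bind_rows(rows)
}

#' Read phenotype similarity and term mapping files
#'
#' The matrix file is a sparse three-column TSV `pheno_a  pheno_b
#' similarity`; symmetric closure is applied and similarities outside
#' \[0, 1\] are rejected. The mapping file is a two-column TSV
#' `term_id  phenotype_id`. Both present enables phenotype fusion; both
#' absent (`NULL`) selects semantic-only similarity.
#'
#' @param matrix_path,mapping_path File paths, or `NULL` for semantic-only
#'   mode.
#' @return A list with elements `phenotypes` and `mapping` (both `NULL` in
#'   semantic-only mode).
#' @export
read_phenotype_inputs <- function(matrix_path = NULL, mapping_path = NULL) {
  if (is.null(matrix_path) != is.null(mapping_path)) {
    abort("supply both phenotype files, or neither")
  }
  if (is.null(matrix_path)) return(list(phenotypes = NULL, mapping = NULL))
  tab <- read_tsv_cols(matrix_path, c("pheno_a", "pheno_b", "similarity"))
  tab$similarity <- as.numeric(tab$similarity)
  phen <- phenotype_table(tab)
  map <- read_tsv_cols(mapping_path, c("term_id", "phenotype_id"))
  list(phenotypes = phen, mapping = map)
}

read_tsv_cols <- function(path, cols) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < length(cols))
  if (length(bad) > 0) {
    abort(paste0("malformed line ", bad[1], " in ", basename(path)),
          class = "hdmp_parse_error")
  }
  m <- do.call(rbind, lapply(fields, function(f) f[seq_along(cols)]))
  if (identical(tolower(m[1, 1]), cols[1])) m <- m[-1, , drop = FALSE]
  out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(out) <- cols
  out
}

#' Write a generated corpus to disk
#'
#' Emits every bundle component in the exact dialect its reader accepts:
#' `ontology.tsv`, `associations.tsv`, `families.tsv`, `loci.gff3`, and
#' (when present) `phenotypes.tsv` plus `phenotype_map.tsv`.
#'
#' @param corpus A [generate_corpus()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "hdmp_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  p <- file.path(dir, "ontology.tsv")
  ont <- corpus$ontology
  writeLines(c("term_id\tname\ttree_numbers",
               paste(ont$term_id, ont$name,
                     map_chr(ont$tree_numbers, paste, collapse = ";"),
                     sep = "\t")), p)
  files <- c(files, p)

  p <- file.path(dir, "associations.tsv")
  writeLines(c("mirna_id\tdisease_id",
               paste(corpus$associations$mirna_id,
                     corpus$associations$disease_id, sep = "\t")), p)
  files <- c(files, p)

  if (!is.null(corpus$families)) {
    p <- file.path(dir, "families.tsv")
    writeLines(c("family_id\tmirna_id",
                 paste(corpus$families$group_id, corpus$families$mirna_id,
                       sep = "\t")), p)
    files <- c(files, p)
  }

  if (!is.null(corpus$loci) && nrow(corpus$loci) > 0) {
    p <- file.path(dir, "loci.gff3")
    l <- corpus$loci
    writeLines(c("##gff-version 3",
                 paste(l$chrom, "hdmp", "miRNA_primary_transcript",
                       format(l$start, scientific = FALSE, trim = TRUE),
                       format(l$end, scientific = FALSE, trim = TRUE),
                       ".", l$strand, ".",
                       paste0("ID=", l$mirna_id, ";Name=", l$mirna_id),
                       sep = "\t")), p)
    files <- c(files, p)
  }

  if (!is.null(corpus$phenotypes)) {
    p <- file.path(dir, "phenotypes.tsv")
    ph <- corpus$phenotypes
    keep_rows <- ph$pheno_a < ph$pheno_b  # one orientation per pair
    writeLines(c("pheno_a\tpheno_b\tsimilarity",
                 paste(ph$pheno_a[keep_rows], ph$pheno_b[keep_rows],
                       ph$similarity[keep_rows], sep = "\t")), p)
    files <- c(files, p)

    p <- file.path(dir, "phenotype_map.tsv")
    writeLines(c("term_id\tphenotype_id",
                 paste(corpus$phenotype_map$term_id,
                       corpus$phenotype_map$phenotype_id, sep = "\t")), p)
    files <- c(files, p)
  }
  invisible(files)
}

#' Read a corpus directory back into a bundle
#'
#' Counterpart of [write_corpus()]; file contents round-trip losslessly.
#'
#' @param dir Directory written by [write_corpus()].
#' @return A list with elements `ontology`, `associations`, `families`,
#'   `loci`, `phenotypes`, `phenotype_map`.
#' @export
read_corpus <- function(dir) {
  ontology <- read_ontology(file.path(dir, "ontology.tsv"))
  associations <- read_associations(file.path(dir, "associations.tsv"),
                                    ontology = ontology)
  fam_path <- file.path(dir, "families.tsv")
  families <- if (file.exists(fam_path)) read_family(fam_path) else NULL
  gff_path <- file.path(dir, "loci.gff3")
  loci <- if (file.exists(gff_path)) read_loci_gff3(gff_path) else NULL
  ph_path <- file.path(dir, "phenotypes.tsv")
  map_path <- file.path(dir, "phenotype_map.tsv")
  ph <- if (file.exists(ph_path) && file.exists(map_path)) {
    read_phenotype_inputs(ph_path, map_path)
  } else {
    list(phenotypes = NULL, mapping = NULL)
  }
  list(ontology = ontology, associations = associations, families = families,
       loci = loci, phenotypes = ph$phenotypes, phenotype_map = ph$mapping)
}
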
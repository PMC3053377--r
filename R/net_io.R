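#' Read a weighted protein interaction edge list
#'
#' Reads a whitespace- or tab-delimited edge list (STRING-style: two protein
#' identifiers and an integer association confidence on the 0-999 scale) and
#' applies the standard cleaning rules: rows with score below `min_weight`
#' are discarded, self-loop rows are dropped, and duplicate or reciprocal
#' rows for the same unordered pair are collapsed keeping the maximum
#' weight. The node set of the result is exactly the set of endpoints of the
#' retained edges.
#'
#' Weights are kept on the raw 0-999 integer confidence scale; the default
#' cutoff 900 is the "highest confidence" filter (score >= 900, inclusive).
#' A header line is auto-detected by a non-numeric score field. An input
#' that retains no edges yields an empty network with a warning, not an
#' error.
#'
#' @param path Path to the edge-list file.
#' @param min_weight Minimum confidence score to retain an edge (inclusive).
#' @param columns Integer vector of length 3 naming which columns hold
#'   protein A, protein B and the score (default `c(1, 2, 3)`).
#' @return A tibble with columns `protein_a`, `protein_b`, `weight`, one row
#'   per unordered protein pair, with `protein_a < protein_b`.
#' @seealso [network_nodes()], [write_edge_list()], [seed_set()]
#' @examples
#' f <- tempfile()
#' writeLines(c("A B 950", "B A 940", "C C 999", "A C 850"), f)
#' read_edge_list(f, min_weight = 900)
#' @export
read_edge_list <- function(path, min_weight = 900, columns = c(1L, 2L, 3L)) {
  stopifnot(length(columns) == 3, min_weight >= 0)
  if (!file.exists(path)) abort(sprintf("Edge-list file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")

  if (length(fields) == 0) {
    warn("Edge list is empty; returning a network with 0 nodes and 0 edges.")
    return(empty_network())
  }

  short <- lengths(fields) < max(columns)
  # a header row is tolerated only as the first line, detected below
  if (any(short[-1])) {
    abort(sprintf(
      "Malformed edge row (fewer than %d columns) at line %d of %s",
      max(columns), line_no[which(short[-1])[1] + 1L], path
    ))
  }

  first_score <- if (!short[1]) fields[[1]][columns[3]] else NA_character_
  has_header <- short[1] || is.na(suppressWarnings(as.numeric(first_score)))
  if (has_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  } else if (short[1]) {
    abort(sprintf("Malformed edge row (fewer than %d columns) at line %d of %s",
                  max(columns), line_no[1], path))
  }
  if (length(fields) == 0) {
    warn("Edge list is empty; returning a network with 0 nodes and 0 edges.")
    return(empty_network())
  }

  a <- vapply(fields, `[[`, "", columns[1])
  b <- vapply(fields, `[[`, "", columns[2])
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", columns[3])))
  if (anyNA(score)) {
    abort(sprintf("Non-numeric confidence score at line %d of %s",
                  line_no[which(is.na(score))[1]], path))
  }

  edges <- tibble(
    protein_a = pmin(a, b),
    protein_b = pmax(a, b),
    weight = as.integer(round(score))
  ) %>%
    filter(.data$protein_a != .data$protein_b) %>%
    group_by(.data$protein_a, .data$protein_b) %>%
    summarise(weight = max(.data$weight), .groups = "drop") %>%
    filter(.data$weight >= min_weight) %>%
    arrange(.data$protein_a, .data$protein_b)

  if (nrow(edges) == 0) {
    warn(sprintf(
      "No edges with confidence >= %s; returning an empty network.", min_weight
    ))
  }
  edges
}

empty_network <- function() {
  tibble(protein_a = character(), protein_b = character(), weight = integer())
}

#' Nodes of an interaction network
#'
#' @param network Edge tibble as returned by [read_edge_list()].
#' @return Sorted character vector of protein identifiers.
#' @export
network_nodes <- function(network) {
  check_network(network)
  sort(unique(c(network$protein_a, network$protein_b)))
}

#' Write a weighted edge list
#'
#' Inverse of [read_edge_list()]: writes a tab-separated file with a header
#' `protein_a protein_b combined_score` that [read_edge_list()] re-reads
#' identically (at `min_weight = 0`).
#'
#' @param network Edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  check_network(network)
  out <- network %>% rename(combined_score = "weight")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read protein phenotype annotations
#'
#' Reads a tab-separated table whose first column is a protein identifier
#' and whose second column holds one or more comma-separated phenotype
#' category indices (1..K of `scheme`). Repeated indices within a row are
#' collapsed (set semantics); duplicate protein rows are merged by union of
#' their label sets with a warning.
#'
#' @param path Path to the annotation file.
#' @param scheme Phenotype scheme tibble (see [phenotype_scheme()]).
#' @return A long tibble with columns `protein` and `category` (integer),
#'   one row per (protein, category) pair; every annotated protein has at
#'   least one row.
#' @examples
#' f <- tempfile()
#' writeLines(c("PX\t3,3,5", "PY\t1"), f)
#' read_annotations(f, phenotype_scheme(letters[1:5]))
#' @export
read_annotations <- function(path, scheme) {
  check_scheme(scheme)
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("protein", "categories"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#"
  )
  if (any(duplicated(raw$protein))) {
    warn("Duplicate protein rows in annotation file; label sets merged by union.")
  }
  ann <- raw %>%
    mutate(category = strsplit(.data$categories, "[,;] *")) %>%
    select("protein", "category") %>%
    tidyr::unnest("category") %>%
    mutate(category = suppressWarnings(as.integer(.data$category))) %>%
    distinct()
  if (anyNA(ann$category)) {
    abort("Non-integer category index in annotation file.")
  }
  check_annotations(ann, scheme)
  arrange(ann, .data$protein, .data$category)
}

#' Write protein phenotype annotations
#'
#' @param annotations Long tibble with columns `protein`, `category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  check_annotations(annotations)
  out <- annotations %>%
    group_by(.data$protein) %>%
    summarise(categories = paste(sort(.data$category), collapse = ","))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Build the seed set
#'
#' The seed set is the voter population of the predictor: annotated proteins
#' that are also nodes of the interaction network, in deterministic
#' lexicographic order.
#'
#' @param annotations Long annotation tibble.
#' @param network Edge tibble.
#' @return Sorted character vector of seed protein identifiers.
#' @export
seed_set <- function(annotations, network) {
  check_annotations(annotations)
  sort(intersect(unique(annotations$protein), network_nodes(network)))
}

#' Read a complex or pathway membership table
#'
#' Reads a tab-separated table whose first column is a protein identifier
#' and whose second column holds comma- or semicolon-separated feature
#' identifiers (complex or pathway IDs). The literal token `no annotation`
#' marks a protein explicitly lacking membership; such proteins are kept
#' with `feature = NA`.
#'
#' @param path Path to the membership file.
#' @return A long tibble with columns `protein` and `feature` (`NA` for the
#'   explicit no-annotation flag).
#' @seealso [feature_universe()]
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) abort(sprintf("Membership file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("protein", "features"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#"
  )
  if (nrow(raw) == 0) {
    warn("Membership file is empty.")
    return(tibble(protein = character(), feature = character()))
  }
  raw %>%
    mutate(feature = strsplit(.data$features, "[,;] *")) %>%
    select("protein", "feature") %>%
    tidyr::unnest("feature") %>%
    mutate(feature = ifelse(trimws(.data$feature) == "no annotation",
                            NA_character_, trimws(.data$feature))) %>%
    distinct() %>%
    arrange(.data$protein, .data$feature)
}

#' Write a membership table
#'
#' @param membership Long tibble with columns `protein`, `feature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path) {
  out <- membership %>%
    group_by(.data$protein) %>%
    summarise(features = if (all(is.na(.data$feature))) "no annotation" else
      paste(sort(.data$feature[!is.na(.data$feature)]), collapse = ","))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Feature universe of a membership table
#'
#' @param membership Long membership tibble.
#' @return Sorted character vector of distinct feature identifiers
#'   (complexes or pathways), excluding the no-annotation flag.
#' @export
feature_universe <- function(membership) {
  sort(unique(membership$feature[!is.na(membership$feature)]))
}
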
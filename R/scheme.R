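#' Define a phenotype scheme
#'
#' A phenotype scheme is the ordered registry of the K phenotype categories
#' a study distinguishes. It is an ordinary tibble with integer column
#' `index` (contiguous 1..K) and character column `label` (unique), so it
#' pipes through dplyr like any other table.
#'
#' @param labels Character vector of category labels, in category order.
#' @return A tibble with columns `index` (1..K) and `label`.
#' @examples
#' phenotype_scheme(c("slow growth", "heat sensitive", "cold sensitive"))
#' @export
phenotype_scheme <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    abort("A phenotype scheme needs at least 2 categories.")
  }
  if (anyDuplicated(labels)) {
    abort("Phenotype category labels must be unique.")
  }
  tibble(index = seq_along(labels), label = labels)
}

#' The budding-yeast phenotype scheme
#'
#' The 11 phenotypic categories used for Saccharomyces cerevisiae
#' (CYGD/MIPS phenotype classification), in their conventional order.
#'
#' @return A tibble with columns `index` and `label`, 11 rows.
#' @examples
#' yeast_phenotype_scheme()
#' @export
yeast_phenotype_scheme <- function() {
  phenotype_scheme(c(
    "Conditional phenotypes",
    "Cell cycle defects",
    "Mating and sporulation defects",
    "Auxotrophies, carbon and nitrogen utilization defects",
    "Cell morphology and organelle mutants",
    "Stress response defects",
    "Carbohydrate and lipid biosynthesis defects",
    "Nucleic acid metabolism defects",
    "Sensitivity to amino acid analogs and other drugs",
    "Sensitivity to antibiotics",
    "Sensitivity to immunosuppressants"
  ))
}

# Validate a scheme tibble; returns it invisibly.
check_scheme <- function(scheme) {
  if (!is.data.frame(scheme) || !all(c("index", "label") %in% names(scheme))) {
    abort("`scheme` must be a data frame with columns `index` and `label`.")
  }
  k <- nrow(scheme)
  if (k < 2 || !identical(as.integer(scheme$index), seq_len(k))) {
    abort("`scheme$index` must be the contiguous sequence 1..K with K >= 2.")
  }
  if (anyDuplicated(scheme$label)) {
    abort("`scheme$label` must be unique.")
  }
  invisible(scheme)
}

# Validate a long annotation table (protein, category) against a scheme.
check_annotations <- function(annotations, scheme = NULL) {
  if (!is.data.frame(annotations) ||
      !all(c("protein", "category") %in% names(annotations))) {
    abort("`annotations` must have columns `protein` and `category`.")
  }
  if (!is.null(scheme)) {
    bad <- setdiff(unique(annotations$category), scheme$index)
    if (length(bad) > 0) {
      abort(sprintf(
        "Annotation uses category indices outside 1..%d: %s",
        nrow(scheme), paste(sort(bad), collapse = ", ")
      ))
    }
  }
  invisible(annotations)
}

# Validate an edge table (protein_a, protein_b, weight).
check_network <- function(network) {
  if (!is.data.frame(network) ||
      !all(c("protein_a", "protein_b", "weight") %in% names(network))) {
    abort("`network` must have columns `protein_a`, `protein_b`, `weight`.")
  }
  if (any(network$protein_a == network$protein_b)) {
    abort("`network` must not contain self-loops.")
  }
  invisible(network)
}
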
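#' Proteins carrying exactly one phenotype
#'
#' The separability analysis is built from unambiguous examples: proteins
#' annotated with a single phenotype category.
#'
#' @param annotations Long annotation tibble.
#' @return Sorted character vector of single-phenotype proteins.
#' @export
single_phenotype_proteins <- function(annotations) {
  check_annotations(annotations)
  annotations %>%
    count(.data$protein) %>%
    filter(.data$n == 1) %>%
    pull("protein") %>%
    sort()
}

#' Phenotype membership vector over a feature universe
#'
#' Represents one phenotype category as a count vector over the feature
#' universe (complexes or pathways): the component-wise sum of the binary
#' membership indicator vectors of the category's (single-phenotype)
#' proteins. Proteins flagged "no annotation" contribute a zero vector.
#' Because cosine similarity is invariant to positive rescaling, summing
#' indicators is equivalent to averaging them.
#'
#' @param annotations Long annotation tibble.
#' @param membership Long membership tibble ([read_membership()]).
#' @param category Category index.
#' @param proteins Proteins to aggregate over (typically
#'   [single_phenotype_proteins()] output).
#' @return A tibble with columns `feature` (the full universe, sorted) and
#'   `count`.
#' @export
phenotype_vector <- function(annotations, membership, category, proteins) {
  universe <- feature_universe(membership)
  members <- annotations %>%
    filter(.data$category == !!category, .data$protein %in% proteins) %>%
    pull("protein")
  counts <- membership %>%
    filter(.data$protein %in% members, !is.na(.data$feature)) %>%
    count(.data$feature)
  tibble(feature = universe) %>%
    left_join(counts, by = "feature") %>%
    mutate(count = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    select("feature", "count")
}

#' Cosine similarity of two non-negative vectors
#'
#' Inner product divided by the product of Euclidean norms; lies in [0, 1]
#' for non-negative vectors, and is invariant to positive rescaling of
#' either argument.
#'
#' @param u,v Numeric vectors of equal length; a zero vector has undefined
#'   similarity and yields `NA` with a warning.
#' @return A single number in [0, 1], or `NA`.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warn("Cosine similarity of a zero vector is undefined.")
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Phenotype separability profile
#'
#' Quantifies how well complex or pathway membership separates the
#' phenotype categories. Each category is represented by the summed
#' membership-indicator vector of its single-phenotype proteins; all
#' pairwise cosine similarities are computed among categories with nonzero
#' vectors (categories with no membership information are dropped, not
#' given NA rows). Two phenotypes are considered hard to discriminate when
#' their similarity exceeds `threshold`.
#'
#' @param annotations Long annotation tibble.
#' @param membership Long membership tibble.
#' @param scheme Phenotype scheme tibble.
#' @param threshold Discriminability threshold (default 0.5).
#' @param bin_width Histogram bin width for the distribution summary
#'   (default 0.1).
#' @param proteins Optional protein subset to restrict the analysis to
#'   (e.g. the seed set); default: all single-phenotype proteins of
#'   `annotations`.
#' @return An object of class `pheno_similarity`: list with `matrix`
#'   (symmetric K' x K' similarity matrix, unit diagonal), `pairs` (tibble
#'   of the K'(K'-1)/2 category pairs and similarities), `histogram`
#'   (tibble bin_lower/count), `categories` (the K' retained indices),
#'   `n_below` (pairs below `threshold`) and `threshold`. Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
similarity_profile <- function(annotations, membership, scheme,
                               threshold = 0.5, bin_width = 0.1,
                               proteins = NULL) {
  check_scheme(scheme)
  check_annotations(annotations, scheme)
  singles <- single_phenotype_proteins(annotations)
  if (!is.null(proteins)) singles <- intersect(singles, proteins)
  universe <- feature_universe(membership)
  vecs <- matrix(vapply(scheme$index, function(j) {
    phenotype_vector(annotations, membership, j, singles)$count
  }, numeric(length(universe))), nrow = length(universe))
  nonzero <- which(colSums(vecs^2) > 0)
  if (length(nonzero) < 2) {
    abort("Fewer than 2 categories have nonzero membership vectors.")
  }
  v <- vecs[, nonzero, drop = FALSE]
  norms <- sqrt(colSums(v^2))
  sim <- crossprod(v) / tcrossprod(norms)
  dimnames(sim) <- list(scheme$label[nonzero], scheme$label[nonzero])

  idx <- which(upper.tri(sim), arr.ind = TRUE)
  pairs <- tibble(
    category_a = scheme$index[nonzero][idx[, 1]],
    category_b = scheme$index[nonzero][idx[, 2]],
    label_a = scheme$label[nonzero][idx[, 1]],
    label_b = scheme$label[nonzero][idx[, 2]],
    similarity = sim[idx]
  )
  breaks <- seq(0, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  h <- hist(pairs$similarity, breaks = breaks, plot = FALSE)
  structure(list(
    matrix = sim,
    pairs = pairs,
    histogram = tibble(bin_lower = h$breaks[-length(h$breaks)],
                       count = h$counts),
    categories = scheme$index[nonzero],
    n_below = sum(pairs$similarity < threshold),
    threshold = threshold
  ), class = "pheno_similarity")
}

#' @method print pheno_similarity
#' @export
print.pheno_similarity <- function(x, ...) {
  np <- nrow(x$pairs)
  cat(sprintf(
    "Phenotype separability: %d categories, %d pairwise similarities\n",
    length(x$categories), np
  ))
  cat(sprintf("  %d of %d pairs below the %.2g discriminability threshold\n",
              x$n_below, np, x$threshold))
  cat(sprintf("  similarity range: [%.3g, %.3g]\n",
              min(x$pairs$similarity), max(x$pairs$similarity)))
  invisible(x)
}

#' @rdname similarity_profile
#' @param x A `pheno_similarity` object.
#' @param ... Unused.
#' @export
tidy.pheno_similarity <- function(x, ...) {
  x$pairs
}

#' @rdname similarity_profile
#' @export
glance.pheno_similarity <- function(x, ...) {
  tibble(
    n_categories = length(x$categories),
    n_pairs = nrow(x$pairs),
    n_below_threshold = x$n_below,
    threshold = x$threshold,
    max_similarity = max(x$pairs$similarity)
  )
}

#' @rdname similarity_profile
#' @param object A `pheno_similarity` object.
#' @export
autoplot.pheno_similarity <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0, closed = "left",
                            colour = "grey30", fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "pairwise phenotype similarity",
      y = "number of category pairs",
      title = "Distribution of phenotype similarities",
      subtitle = "dashed line: discriminability threshold"
    )
}

#' Write a similarity profile to disk
#'
#' Emits the similarity matrix and the histogram (bin lower edge, count)
#' as TSV files.
#'
#' @param profile A `pheno_similarity` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_similarity <- function(profile, dir) {
  stopifnot(inherits(profile, "pheno_similarity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- as_tibble(profile$matrix, rownames = "category")
  readr::write_tsv(mat, file.path(dir, "similarity_matrix.tsv"))
  readr::write_tsv(profile$histogram, file.path(dir, "similarity_histogram.tsv"))
  invisible(dir)
}
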
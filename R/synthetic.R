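#' Simulate a phenotype-assortative interaction network
#'
#' Planted-label generator producing the three tables the predictor
#' consumes: a weighted undirected network, a multi-label phenotype
#' annotation table, and a block-structured complex membership table. Each
#' node gets a primary category (equal-sized blocks) and, with probability
#' `multi_label_rate`, one additional random category (pleiotropy). Every
#' unordered node pair is connected with probability `p_in` when the two
#' nodes share at least one label and `p_out` otherwise, so the ratio
#' p_in/p_out controls phenotype assortativity — the structural assumption
#' (interacting proteins tend to share phenotypes) that makes
#' guilt-by-association work. Edge confidences are drawn uniformly from
#' `weight_range`. A fraction of nodes is stripped of its labels to serve
#' as prediction targets; their latent labels still drive edge placement.
#'
#' The defaults emulate the study conditions of the yeast analysis at a
#' size that runs in seconds: K = 11 categories, mean phenotypes per
#' protein 1 + `multi_label_rate` = 1.7, and confidences on the
#' highest-confidence 900-999 band.
#'
#' @param K Number of phenotype categories.
#' @param n_per_category Nodes per primary-category block (>= 2).
#' @param p_in Edge probability for label-sharing pairs.
#' @param p_out Edge probability for non-sharing pairs (p_out <= p_in).
#' @param weight_range Integer confidence interval, within 0-999.
#' @param multi_label_rate Probability a node gains a second random label.
#' @param unlabeled_fraction Fraction of nodes left unannotated.
#' @param complexes_per_category Synthetic complexes per category block.
#' @param membership_overlap Probability a protein additionally joins a
#'   complex of another category (inter-category overlap).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with elements `network`, `annotations`, `membership`
#'   (tibbles in the package's standard layouts), `scheme`, and
#'   `latent_labels` (the true labels of all nodes, including the
#'   unannotated ones).
#' @examples
#' sim <- simulate_phenotype_network(K = 3, n_per_category = 5, seed = 1)
#' sim$network
#' @export
simulate_phenotype_network <- function(K = 11, n_per_category = 30,
                                       p_in = 0.3, p_out = 0.01,
                                       weight_range = c(900L, 999L),
                                       multi_label_rate = 0.7,
                                       unlabeled_fraction = 0.1,
                                       complexes_per_category = 3,
                                       membership_overlap = 0.1,
                                       seed = NULL) {
  stopifnot(
    K >= 2, n_per_category >= 2,
    p_out >= 0, p_out <= p_in, p_in <= 1,
    weight_range[1] >= 0, weight_range[2] <= 999,
    weight_range[1] <= weight_range[2],
    multi_label_rate >= 0, multi_label_rate <= 1,
    unlabeled_fraction >= 0, unlabeled_fraction < 1
  )
  scheme <- if (K == 11) yeast_phenotype_scheme() else {
    phenotype_scheme(sprintf("synthetic phenotype %d", seq_len(K)))
  }
  with_rng(seed, {
    n <- K * n_per_category
    ids <- sprintf("SYN%04d", seq_len(n))
    primary <- rep(seq_len(K), each = n_per_category)
    gains <- runif(n) < multi_label_rate
    second <- ifelse(
      gains,
      # uniform over the K-1 categories other than the primary one
      (primary + sample.int(K - 1, n, replace = TRUE) - 1L) %% K + 1L,
      NA_integer_
    )
    labels <- lapply(seq_len(n), function(i) {
      sort(unique(c(primary[i], second[i][!is.na(second[i])])))
    })

    x <- matrix(0L, n, K)
    for (i in seq_len(n)) x[i, labels[[i]]] <- 1L
    shared <- tcrossprod(x) > 0

    ut <- which(upper.tri(shared), arr.ind = TRUE)
    p <- ifelse(shared[ut], p_in, p_out)
    on <- runif(nrow(ut)) < p
    ia <- ut[on, 1]
    ib <- ut[on, 2]
    network <- tibble(
      protein_a = ids[ia],
      protein_b = ids[ib],
      weight = as.integer(sample(weight_range[1]:weight_range[2],
                                 sum(on), replace = TRUE))
    ) %>% arrange(.data$protein_a, .data$protein_b)

    hidden <- sample(ids, floor(unlabeled_fraction * n))
    annotations <- tibble(
      protein = rep(ids, lengths(labels)),
      category = unlist(labels)
    ) %>%
      filter(!.data$protein %in% hidden) %>%
      arrange(.data$protein, .data$category)

    cpx <- function(cat, slot) sprintf("CPX%02d_%d", cat, slot)
    membership <- purrr::map(seq_len(n), function(i) {
      own <- vapply(labels[[i]], function(cat) {
        cpx(cat, sample.int(complexes_per_category, 1))
      }, character(1))
      if (runif(1) < membership_overlap) {
        other <- sample(setdiff(seq_len(K), labels[[i]]), 1)
        own <- c(own, cpx(other, sample.int(complexes_per_category, 1)))
      }
      tibble(protein = ids[i], feature = sort(unique(own)))
    }) %>% bind_rows()

    list(
      network = network,
      annotations = annotations,
      membership = membership,
      scheme = scheme,
      latent_labels = tibble(
        protein = rep(ids, lengths(labels)),
        category = unlist(labels)
      )
    )
  })
}

#' Write a simulated data set in the package's file dialects
#'
#' Emits `network.tsv`, `annotations.tsv` and `membership.tsv` in exactly
#' the formats [read_edge_list()], [read_annotations()] and
#' [read_membership()] consume, so simulated data exercises the full I/O
#' path.
#'
#' @param sim Output of [simulate_phenotype_network()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(sim$network, file.path(dir, "network.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_membership(sim$membership, file.path(dir, "membership.tsv"))
  invisible(dir)
}
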
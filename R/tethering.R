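#' Interaction weights of a query protein with the seed set
#'
#' For a query protein and an ordered list of seed proteins, returns the
#' edge confidence between the query and each seed: 0 when no edge exists,
#' and 0 for the seed equal to the query itself (self-interactions are never
#' counted). A query absent from the network yields an all-zero column.
#'
#' @param network Edge tibble (see [read_edge_list()]).
#' @param query Protein identifier.
#' @param seeds Ordered character vector of seed proteins (nonempty).
#' @return A tibble with columns `seed` (in the given order) and `weight`.
#' @export
interaction_weights <- function(network, query, seeds) {
  check_network(network)
  stopifnot(length(seeds) > 0, length(query) == 1)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(query, seeds), key(network$protein_a, network$protein_b))
  w <- ifelse(is.na(idx), 0L, network$weight[idx])
  w[seeds == query] <- 0L
  tibble(seed = seeds, weight = as.integer(w))
}

# Dense queries x K matrix of tethering potentials, computed in one sparse
# product: W[queries, seeds] %*% X[seeds, categories]. Because networks
# carry no self-loops, w(q, q) = 0, so a query that is itself a seed never
# votes for itself -- the leave-one-out condition comes for free.
score_matrix <- function(network, queries, annotations, seeds, k) {
  nodes <- sort(unique(c(network_nodes(network), queries, seeds)))
  ia <- match(network$protein_a, nodes)
  ib <- match(network$protein_b, nodes)
  w <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = rep(as.numeric(network$weight), 2),
    dims = c(length(nodes), length(nodes))
  )
  ann <- annotations %>% filter(.data$protein %in% seeds)
  x <- Matrix::sparseMatrix(
    i = match(ann$protein, nodes), j = ann$category, x = 1,
    dims = c(length(nodes), k)
  )
  f <- as.matrix(w[match(queries, nodes), , drop = FALSE] %*% x)
  dimnames(f) <- list(queries, NULL)
  f
}

#' Tethering potential of a query protein to every phenotype category
#'
#' The tethering potential of a query protein to category j is the sum of
#' its interaction confidences to the seed proteins annotated with j: a
#' weighted neighbour vote in which seeds without an edge to the query
#' contribute nothing, and a seed carrying several phenotype labels votes
#' its full edge weight for each of them. Scores are exact integer sums of
#' the 0-999 confidences.
#'
#' @inheritParams interaction_weights
#' @param annotations Long annotation tibble covering at least the seeds.
#' @param seeds Character vector of seed (voter) proteins; must all be
#'   annotated.
#' @param scheme Phenotype scheme tibble.
#' @return A tibble with one row per category: `protein`, `category_index`,
#'   `category_label`, `score`.
#' @examples
#' net <- tibble::tibble(
#'   protein_a = c("Q", "Q"), protein_b = c("S1", "S2"),
#'   weight = c(900L, 950L)
#' )
#' ann <- tibble::tibble(protein = c("S1", "S2"), category = c(1L, 2L))
#' tethering_potential(net, "Q", ann, c("S1", "S2"),
#'                     phenotype_scheme(c("a", "b")))
#' @export
tethering_potential <- function(network, query, annotations, seeds, scheme) {
  check_network(network)
  check_scheme(scheme)
  check_annotations(annotations, scheme)
  unannotated <- setdiff(seeds, annotations$protein)
  if (length(unannotated) > 0) {
    abort(sprintf("Seeds without annotation: %s",
                  paste(head(unannotated, 5), collapse = ", ")))
  }
  k <- nrow(scheme)
  s <- if (length(seeds) == 0) {
    rep(0, k)
  } else {
    drop(score_matrix(network, query, annotations, seeds, k))
  }
  tibble(
    protein = query,
    category_index = scheme$index,
    category_label = scheme$label,
    score = as.numeric(s)
  )
}

#' Most likely phenotype category of a score vector
#'
#' @param scores Score tibble from [tethering_potential()] (columns
#'   `category_index`, `score`).
#' @return The category index with the maximal tethering potential. When
#'   several categories tie at the maximum, one of them is returned
#'   uniformly at random (the first element of a random tie-sorted
#'   ranking); when every score is zero the protein is unpredictable and
#'   `NA` is returned with a warning.
#' @param seed Optional integer seed for the tie-breaking draw.
#' @export
top_category <- function(scores, seed = NULL) {
  if (all(scores$score == 0)) {
    warn("All tethering potentials are zero; the phenotype is unpredictable.")
    return(NA_integer_)
  }
  ranked <- rank_prediction(scores, seed = seed)
  ranked$category_index[ranked$rank == 1]
}

# Rank one score vector descendingly with uniform random tie-sorting.
# Returns integer order (category indices ranked 1..K) and tie groups.
rank_one <- function(s) {
  k <- length(s)
  ord <- order(-s, sample.int(k))
  sorted <- s[ord]
  list(order = ord, tie_group = cumsum(c(TRUE, diff(sorted) != 0)))
}

#' Rank all phenotype categories of a query protein
#'
#' Sorts the K tethering potentials in descending order; runs of equal
#' scores are permuted uniformly at random, so ties carry no systematic
#' ordering. A protein whose scores are all zero (no annotated neighbour)
#' is flagged `all_zero` and receives a uniformly random full permutation;
#' such proteins stay in every evaluation denominator.
#'
#' @param scores Score tibble from [tethering_potential()].
#' @param seed Optional integer seed for reproducible tie-sorting; `NULL`
#'   uses (and advances) the current RNG stream.
#' @return A tibble with one row per rank 1..K: `protein`, `rank`,
#'   `category_index`, `category_label`, `score`, `tie_group` (maximal runs
#'   of equal score), `all_zero`.
#' @export
rank_prediction <- function(scores, seed = NULL) {
  stopifnot(all(c("category_index", "score") %in% names(scores)))
  s <- scores$score[order(scores$category_index)]
  r <- with_rng(seed, rank_one(s))
  base <- scores[order(scores$category_index), ]
  out <- base[r$order, ]
  out$rank <- seq_along(s)
  out$tie_group <- r$tie_group
  out$all_zero <- all(s == 0)
  cols <- intersect(
    c("protein", "rank", "category_index", "category_label", "score",
      "tie_group", "all_zero"),
    names(out)
  )
  as_tibble(out[, cols])
}

# Score and rank many queries against one voter set; long tibble output.
rank_many <- function(network, queries, annotations, seeds, scheme, seed) {
  k <- nrow(scheme)
  if (length(queries) == 0) {
    return(tibble(
      protein = character(), rank = integer(), category_index = integer(),
      category_label = character(), score = numeric(), tie_group = integer(),
      all_zero = logical()
    ))
  }
  f <- score_matrix(network, queries, annotations, seeds, k)
  blocks <- with_rng(seed, lapply(seq_along(queries), function(i) {
    r <- rank_one(f[i, ])
    tibble(
      protein = queries[i],
      rank = seq_len(k),
      category_index = r$order,
      category_label = scheme$label[r$order],
      score = f[i, r$order],
      tie_group = r$tie_group,
      all_zero = all(f[i, ] == 0)
    )
  }))
  bind_rows(blocks)
}

#' Predict phenotypes for every unlabeled network protein
#'
#' Scores each network node outside the seed set against the full seed set
#' and ranks all categories per protein.
#'
#' @param network Edge tibble.
#' @param annotations Long annotation tibble.
#' @param scheme Phenotype scheme tibble.
#' @param seed Integer seed for tie-sorting (default 1 for reproducibility).
#' @return A long tibble of ranked predictions, one K-row block per
#'   unlabeled protein (see [rank_prediction()] for columns).
#' @export
predict_unlabeled <- function(network, annotations, scheme, seed = 1L) {
  check_network(network)
  check_scheme(scheme)
  check_annotations(annotations, scheme)
  seeds <- seed_set(annotations, network)
  queries <- setdiff(network_nodes(network), seeds)
  rank_many(network, queries, annotations, seeds, scheme, seed)
}
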
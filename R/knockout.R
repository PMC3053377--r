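#' Re-predict a protein's phenotypes after inactivating an interactor
#'
#' Compares two ranked predictions for a query protein: the baseline on the
#' intact network, and the knockout condition in which one protein is
#' removed from the network together with all its incident edges. In both
#' conditions the query's own annotation is withheld from the voters
#' (the jackknife condition), so an annotated query is scored exactly as
#' during cross-validation.
#'
#' @inheritParams predict_unlabeled
#' @param query Query protein identifier (must differ from `removed`).
#' @param removed Protein to inactivate; must be a network node.
#' @param seed Integer seed for tie-sorting.
#' @return An object of class `knockout_result`: list with `query`,
#'   `removed`, `baseline_top`, `knockout_top` (category indices, `NA`
#'   when unpredictable) and `ranking` (long tibble of both full rankings,
#'   distinguished by a `condition` column). Supports [tidy()],
#'   [glance()] and `print()`.
#' @export
inactivate_and_predict <- function(network, annotations, scheme,
                                   query, removed, seed = 1L) {
  check_network(network)
  check_scheme(scheme)
  check_annotations(annotations, scheme)
  stopifnot(length(query) == 1, length(removed) == 1)
  if (query == removed) abort("`query` and `removed` must differ.")
  if (!removed %in% network_nodes(network)) {
    abort(sprintf("`removed` protein %s is not a network node.", removed))
  }

  broken <- network %>%
    filter(.data$protein_a != removed, .data$protein_b != removed)

  rank_for <- function(net, cond, s) {
    seeds <- setdiff(seed_set(annotations, net), query)
    scores <- tethering_potential(net, query, annotations, seeds, scheme)
    rank_prediction(scores, seed = s) %>%
      mutate(condition = cond, .before = 1)
  }
  base <- rank_for(network, "baseline", seed)
  ko <- rank_for(broken, "knockout", seed + 1L)

  top_of <- function(r) {
    if (r$all_zero[1]) NA_integer_ else r$category_index[r$rank == 1]
  }
  structure(list(
    query = query,
    removed = removed,
    baseline_top = top_of(base),
    knockout_top = top_of(ko),
    ranking = bind_rows(base, ko)
  ), class = "knockout_result")
}

#' @method print knockout_result
#' @export
print.knockout_result <- function(x, ...) {
  lab <- function(j, cond) {
    if (is.na(j)) return("(unpredictable: no annotated neighbour)")
    x$ranking$category_label[x$ranking$condition == cond &
                               x$ranking$category_index == j]
  }
  cat(sprintf("Knockout analysis: query %s, removed %s\n", x$query, x$removed))
  cat(sprintf("  baseline top phenotype: %s\n", lab(x$baseline_top, "baseline")))
  cat(sprintf("  knockout top phenotype: %s\n", lab(x$knockout_top, "knockout")))
  invisible(x)
}

#' @rdname inactivate_and_predict
#' @param x A `knockout_result` object.
#' @param ... Unused.
#' @export
tidy.knockout_result <- function(x, ...) {
  x$ranking
}

#' @rdname inactivate_and_predict
#' @export
glance.knockout_result <- function(x, ...) {
  tibble(
    query = x$query,
    removed = x$removed,
    baseline_top = x$baseline_top,
    knockout_top = x$knockout_top,
    changed = !identical(x$baseline_top, x$knockout_top)
  )
}

#' Run the knockout analysis over a table of (query, removed) pairs
#'
#' @inheritParams predict_unlabeled
#' @param pairs Tibble with columns `query` and `removed`.
#' @param seed Integer seed.
#' @return A tibble with one row per pair ([glance()] of each result).
#' @export
knockout_batch <- function(network, annotations, scheme, pairs, seed = 1L) {
  stopifnot(all(c("query", "removed") %in% names(pairs)))
  purrr::map2(pairs$query, pairs$removed, function(q, r) {
    glance(inactivate_and_predict(network, annotations, scheme, q, r,
                                  seed = seed))
  }) %>% bind_rows()
}
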
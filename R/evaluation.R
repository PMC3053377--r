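#' Jackknife (leave-one-out) predictions over the seed set
#'
#' Each seed protein is in turn treated as the query: its own annotation is
#' withheld and the remaining seed proteins vote. The protein's node and
#' edges stay in the network; since self-interactions carry weight zero,
#' withholding the query from the voter set is exactly the leave-one-out
#' condition.
#'
#' @inheritParams predict_unlabeled
#' @return A long tibble of ranked predictions, one K-row block per seed
#'   protein.
#' @export
jackknife <- function(network, annotations, scheme, seed = 1L) {
  check_network(network)
  check_scheme(scheme)
  check_annotations(annotations, scheme)
  seeds <- seed_set(annotations, network)
  if (length(seeds) == 0) abort("The seed set is empty; nothing to jackknife.")
  rank_many(network, seeds, annotations, seeds, scheme, seed)
}

# protein -> label set, as a list keyed by protein.
label_sets <- function(annotations) {
  split(annotations$category, annotations$protein)
}

#' Order prediction accuracies
#'
#' The i-th order accuracy A_i is the percentage of proteins whose i-th
#' ranked category belongs to their true label set. Because every true
#' label occupies exactly one rank, the A_i sum to 100 times the mean
#' phenotype count.
#'
#' @param predictions Long ranked-prediction tibble ([jackknife()] output).
#' @param annotations Long annotation tibble covering every predicted
#'   protein.
#' @return A tibble with columns `rank` (1..K) and `accuracy` (percent).
#' @export
order_accuracies <- function(predictions, annotations) {
  if (nrow(predictions) == 0) abort("Empty prediction table.")
  check_annotations(annotations)
  truth <- label_sets(annotations)
  missing <- setdiff(unique(predictions$protein), names(truth))
  if (length(missing) > 0) {
    abort(sprintf("Predicted proteins without annotation: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  predictions %>%
    mutate(hit = purrr::map2_lgl(
      .data$protein, .data$category_index,
      function(p, j) j %in% truth[[p]]
    )) %>%
    group_by(rank = .data$rank) %>%
    summarise(accuracy = 100 * mean(.data$hit)) %>%
    arrange(.data$rank)
}

#' Mean number of phenotypes per protein
#'
#' @param annotations Long annotation tibble.
#' @param proteins Character vector of proteins to average over (all must
#'   be annotated).
#' @return Arithmetic mean of the label-set sizes.
#' @export
mean_phenotype_count <- function(annotations, proteins) {
  if (length(proteins) == 0) abort("Empty protein list.")
  check_annotations(annotations)
  sizes <- lengths(label_sets(annotations)[proteins])
  if (anyNA(names(sizes)) || length(sizes) < length(proteins)) {
    abort("Some proteins in `proteins` are not annotated.")
  }
  mean(sizes)
}

#' Random-guess baseline accuracy
#'
#' The chance that a uniformly random category guess hits one of a
#' protein's phenotypes, averaged over proteins: 100 * mean phenotype
#' count / K percent.
#'
#' @param mean_count Mean phenotypes per protein (0 < mean_count <= K).
#' @param k Number of phenotype categories.
#' @return Percentage.
#' @examples
#' random_baseline(1.7, 11) # 15.45..., i.e. 15.5 at 3 significant figures
#' @export
random_baseline <- function(mean_count, k) {
  stopifnot(mean_count > 0, mean_count <= k)
  100 * mean_count / k
}

#' Top-r inclusion likelihood
#'
#' L(r) is the percentage of proteins whose entire true label set is
#' contained in their top-r ranked categories. L is non-decreasing in r and
#' L(K) = 100.
#'
#' @inheritParams order_accuracies
#' @param r Rank cutoff, 1 <= r <= K.
#' @return Percentage.
#' @export
inclusion_likelihood <- function(predictions, annotations, r) {
  if (nrow(predictions) == 0) abort("Empty prediction table.")
  k <- max(predictions$rank)
  if (r < 1 || r > k) abort(sprintf("`r` must be in 1..%d.", k))
  truth <- label_sets(annotations)
  covered <- predictions %>%
    filter(.data$rank <= r) %>%
    group_by(.data$protein) %>%
    summarise(ok = all(truth[[.data$protein[1]]] %in% .data$category_index))
  100 * mean(covered$ok)
}

#' Jackknife evaluation of the network-based predictor
#'
#' Runs a single leave-one-out jackknife over the seed set and derives all
#' evaluation statistics from the same prediction map: the K order
#' accuracies, the mean phenotype count, the random-guess baseline, and the
#' top-r inclusion likelihoods.
#'
#' @inheritParams predict_unlabeled
#' @param r_values Integer vector of rank cutoffs for the inclusion
#'   likelihood (default 1:3).
#' @return An object of class `pheno_eval`: a list with elements
#'   `order_accuracy` (tibble rank/accuracy), `inclusion` (tibble
#'   r/likelihood), `mean_phenotypes`, `random_baseline`, `n_proteins`,
#'   `k`, `seed`, and the full `predictions` tibble. Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' sim <- simulate_phenotype_network(K = 4, n_per_category = 10, seed = 7)
#' ev <- evaluate_predictor(sim$network, sim$annotations, sim$scheme, seed = 7)
#' glance(ev)
#' @export
evaluate_predictor <- function(network, annotations, scheme, seed = 1L,
                               r_values = 1:3) {
  check_scheme(scheme)
  preds <- jackknife(network, annotations, scheme, seed = seed)
  seeds <- seed_set(annotations, network)
  ann_seeds <- annotations %>% filter(.data$protein %in% seeds)
  mbar <- mean_phenotype_count(ann_seeds, seeds)
  k <- nrow(scheme)
  out <- list(
    order_accuracy = order_accuracies(preds, ann_seeds),
    inclusion = tibble(
      r = as.integer(r_values),
      likelihood = vapply(r_values, function(r) {
        inclusion_likelihood(preds, ann_seeds, r)
      }, numeric(1))
    ),
    mean_phenotypes = mbar,
    random_baseline = random_baseline(mbar, k),
    n_proteins = length(seeds),
    k = k,
    seed = seed,
    predictions = preds
  )
  structure(out, class = "pheno_eval")
}

#' @method print pheno_eval
#' @export
print.pheno_eval <- function(x, ...) {
  cat(sprintf(
    "Jackknife evaluation of %d seed proteins (K = %d categories)\n",
    x$n_proteins, x$k
  ))
  cat(sprintf("  mean phenotypes per protein: %s\n",
              signif(x$mean_phenotypes, 3)))
  cat(sprintf("  random-guess baseline:       %s%%\n",
              signif(x$random_baseline, 3)))
  acc <- signif(x$order_accuracy$accuracy, 3)
  cat("  order accuracies (%):        ",
      paste(acc, collapse = " "), "\n", sep = "")
  for (i in seq_len(nrow(x$inclusion))) {
    cat(sprintf("  L(%d) = %s%%\n", x$inclusion$r[i],
                signif(x$inclusion$likelihood[i], 3)))
  }
  invisible(x)
}

#' @rdname evaluate_predictor
#' @param x A `pheno_eval` object.
#' @param ... Unused.
#' @export
tidy.pheno_eval <- function(x, ...) {
  x$order_accuracy
}

#' @rdname evaluate_predictor
#' @export
glance.pheno_eval <- function(x, ...) {
  tibble(
    n_proteins = x$n_proteins,
    k = x$k,
    mean_phenotypes = x$mean_phenotypes,
    random_baseline = x$random_baseline,
    accuracy_1 = x$order_accuracy$accuracy[1],
    inclusion_3 = if (3 %in% x$inclusion$r) {
      x$inclusion$likelihood[x$inclusion$r == 3]
    } else NA_real_
  )
}

#' @rdname evaluate_predictor
#' @param object A `pheno_eval` object.
#' @export
autoplot.pheno_eval <- function(object, ...) {
  df <- object$order_accuracy
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$random_baseline,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$rank) +
    ggplot2::labs(
      x = "prediction order i",
      y = "order accuracy A_i (%)",
      title = "Jackknife order-accuracy profile",
      subtitle = "dashed line: random-guess baseline"
    )
}

#' Write a jackknife evaluation report to disk
#'
#' Emits the order-accuracy table as TSV plus a key-value summary file
#' (mean phenotype count, baseline, inclusion likelihoods, N, seed).
#'
#' @param eval A `pheno_eval` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(eval, dir) {
  stopifnot(inherits(eval, "pheno_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(eval$order_accuracy, file.path(dir, "order_accuracy.tsv"))
  summary_lines <- c(
    sprintf("n_proteins\t%d", eval$n_proteins),
    sprintf("k\t%d", eval$k),
    sprintf("mean_phenotypes\t%.6g", eval$mean_phenotypes),
    sprintf("random_baseline\t%.6g", eval$random_baseline),
    sprintf("inclusion_L%d\t%.6g", eval$inclusion$r, eval$inclusion$likelihood),
    sprintf("seed\t%d", eval$seed)
  )
  writeLines(summary_lines, file.path(dir, "summary.tsv"))
  invisible(dir)
}
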
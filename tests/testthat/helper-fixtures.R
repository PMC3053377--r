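# Shared fixtures and independent oracles for the test suite.

yeast_scheme <- phenotether::yeast_phenotype_scheme()

example_path <- function(...) {
  system.file("extdata", "worked_examples", ..., package = "phenotether",
              mustWork = TRUE)
}

# The two in-paper worked examples: a query protein, its neighbour edges,
# and the neighbours' annotations, loaded through the package's own I/O.
load_example <- function(which = c("ybr039w", "ydl028c")) {
  which <- match.arg(which)
  query <- toupper(which)
  net <- read_edge_list(example_path(paste0(which, "_network.tsv")),
                        min_weight = 900)
  ann <- read_annotations(example_path(paste0(which, "_annotations.tsv")),
                          yeast_scheme)
  list(
    query = query,
    network = net,
    annotations = ann,
    seeds = setdiff(seed_set(ann, net), query)
  )
}

# Independent brute-force oracle for the tethering potential: scans the
# edge table row by row and sums confidences per category, never touching
# the package's sparse-matrix path.
brute_tethering <- function(network, query, annotations, seeds, k) {
  vapply(seq_len(k), function(j) {
    total <- 0
    for (s in setdiff(seeds, query)) {
      if (!j %in% annotations$category[annotations$protein == s]) next
      hit <- (network$protein_a == query & network$protein_b == s) |
        (network$protein_b == query & network$protein_a == s)
      total <- total + sum(network$weight[hit])
    }
    total
  }, numeric(1))
}

# Random test instance: an Erdos-Renyi-ish weighted network on n nodes plus
# random multi-label annotations, built directly (independent of the
# package's planted-label generator).
random_instance <- function(n, k, p_edge = 0.3) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  on <- runif(nrow(pairs)) < p_edge
  network <- tibble::tibble(
    protein_a = ids[pairs[on, 1]],
    protein_b = ids[pairs[on, 2]],
    weight = sample(1:999, sum(on), replace = TRUE)
  )
  n_labels <- sample(seq_len(min(3, k)), n, replace = TRUE)
  annotations <- tibble::tibble(
    protein = rep(ids, n_labels),
    category = unlist(lapply(n_labels, function(m) sample.int(k, m)))
  )
  list(ids = ids, network = network, annotations = annotations,
       scheme = phenotype_scheme(sprintf("cat%d", seq_len(k))))
}
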
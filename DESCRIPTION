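Package: phenotether
Title: Network-Based Protein Phenotype Prediction by Tethering Potential
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guilt-by-association prediction of protein phenotypes from a
    weighted protein-protein interaction network. For each query protein the
    tethering potential to every phenotype category is computed as the sum of
    interaction confidences to annotated neighbour proteins, and all
    categories are ranked by descending score with random tie-sorting.
    Includes leave-one-out jackknife evaluation (order accuracies, mean
    phenotype count, top-r inclusion likelihood, random-guess baseline),
    phenotype separability analysis via cosine similarity of complex and
    pathway membership vectors, single-node inactivation (knockout)
    re-prediction, and a planted-label synthetic data generator with
    controlled phenotype assortativity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
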
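test_that("interaction weights reproduce the YBR039W neighbour confidences", {
  ex <- load_example("ybr039w")
  w <- interaction_weights(ex$network, ex$query, ex$seeds)
  expect_equal(w$weight[match(
    c("YBL099W", "YDL004W", "YDR298C", "YLR295C", "YML081C-A",
      "YPL078C", "YPL271W", "YPR024W"), w$seed
  )], c(999L, 999L, 999L, 917L, 934L, 999L, 997L, 986L))
})

test_that("self-interactions and absent queries score zero", {
  ex <- load_example("ybr039w")
  w <- interaction_weights(ex$network, "YBL099W", c("YBL099W", "YDL004W"))
  expect_equal(w$weight[w$seed == "YBL099W"], 0L)
  iso <- interaction_weights(ex$network, "NOT_A_NODE", ex$seeds)
  expect_true(all(iso$weight == 0))
})

test_that("tethering potentials equal the hand-summed worked-example values", {
  ex <- load_example("ybr039w")
  tp <- tethering_potential(ex$network, ex$query, ex$annotations,
                            ex$seeds, yeast_scheme)
  expect_identical(tp$score[4], 7830) # Auxotrophies...
  expect_identical(tp$score[5], 1920) # Cell morphology...
  expect_identical(tp$score[1], 986)  # Conditional phenotypes
  expect_true(all(tp$score[-c(1, 4, 5)] == 0))

  ex2 <- load_example("ydl028c")
  tp2 <- tethering_potential(ex2$network, ex2$query, ex2$annotations,
                             ex2$seeds, yeast_scheme)
  expect_identical(tp2$score[2], 9736) # Cell cycle defects
  expect_identical(tp2$score[5], 3970) # Cell morphology...
  expect_identical(tp2$score[1], 2891) # Conditional phenotypes
  expect_identical(tp2$score[8], 929)  # Nucleic acid metabolism defects
  expect_true(all(tp2$score[-c(1, 2, 5, 8)] == 0))
})

test_that("empty seed sets give an all-zero score vector", {
  ex <- load_example("ybr039w")
  tp <- tethering_potential(ex$network, ex$query, ex$annotations,
                            character(0), yeast_scheme)
  expect_true(all(tp$score == 0))
})

test_that("tethering potentials match a brute-force oracle on random graphs", {
  set.seed(101)
  for (case in 1:60) {
    k <- sample(2:6, 1)
    inst <- random_instance(sample(5:30, 1), k)
    seeds <- sort(sample(inst$ids, sample(2:length(inst$ids), 1)))
    query <- sample(inst$ids, 1)
    tp <- tethering_potential(inst$network, query, inst$annotations,
                              seeds, inst$scheme)
    expect_equal(tp$score,
                 brute_tethering(inst$network, query, inst$annotations,
                                 seeds, k))
  }
})

test_that("score mass is conserved: sum of potentials = sum of weight x labels", {
  set.seed(202)
  for (case in 1:20) {
    inst <- random_instance(sample(5:30, 1), 4)
    seeds <- inst$ids
    query <- sample(inst$ids, 1)
    tp <- tethering_potential(inst$network, query, inst$annotations,
                              seeds, inst$scheme)
    w <- interaction_weights(inst$network, query, seeds)
    nlab <- lengths(split(inst$annotations$category,
                          inst$annotations$protein))[seeds]
    expect_equal(sum(tp$score), sum(w$weight * nlab))
  }
})

test_that("adding an edge to a seed raises exactly that seed's categories", {
  set.seed(303)
  inst <- random_instance(10, 4, p_edge = 0.2)
  query <- "N01"
  target <- "N09"
  base <- tethering_potential(inst$network, query, inst$annotations,
                              inst$ids, inst$scheme)
  boosted_net <- dplyr::bind_rows(
    dplyr::filter(inst$network,
                  !(protein_a == query & protein_b == target),
                  !(protein_a == target & protein_b == query)),
    tibble::tibble(protein_a = query, protein_b = target, weight = 500L)
  )
  boosted <- tethering_potential(boosted_net, query, inst$annotations,
                                 inst$ids, inst$scheme)
  target_cats <- inst$annotations$category[inst$annotations$protein == target]
  delta <- boosted$score - base$score
  old_w <- sum(interaction_weights(inst$network, query, target)$weight)
  expect_true(all(delta[target_cats] == 500 - old_w))
  expect_true(all(delta[-target_cats] == 0))
})

test_that("relabeling categories permutes the score vector identically", {
  set.seed(404)
  inst <- random_instance(15, 5)
  query <- "N03"
  perm <- sample(5)
  tp <- tethering_potential(inst$network, query, inst$annotations,
                            inst$ids, inst$scheme)
  relabeled <- dplyr::mutate(inst$annotations, category = perm[category])
  tp2 <- tethering_potential(inst$network, query, relabeled,
                             inst$ids, inst$scheme)
  expect_equal(tp2$score[perm], tp$score)
})

test_that("ranking sorts descendingly and is rng-independent without ties", {
  scores <- tibble::tibble(protein = "Q", category_index = 1:5,
                           category_label = letters[1:5],
                           score = c(10, 50, 0, 30, 20))
  r1 <- rank_prediction(scores, seed = 1)
  r2 <- rank_prediction(scores, seed = 999)
  expect_equal(r1$category_index, c(2L, 4L, 5L, 1L, 3L))
  expect_equal(r1, r2)
  expect_true(all(diff(r1$score) <= 0))
  expect_setequal(r1$category_index, 1:5)
})

test_that("ties are permuted uniformly and tie groups are bookkept", {
  scores <- tibble::tibble(protein = "Q", category_index = 1:4,
                           category_label = letters[1:4],
                           score = c(9, 9, 1, 0))
  first <- withr::with_seed(7, vapply(1:10000, function(i) {
    rank_prediction(scores)$category_index[1]
  }, integer(1)))
  frac1 <- mean(first == 1)
  expect_gt(frac1, 0.48)
  expect_lt(frac1, 0.52)

  r <- rank_prediction(scores, seed = 5)
  expect_equal(r$tie_group, c(1L, 1L, 2L, 3L))
  expect_false(r$all_zero[1])

  zero <- dplyr::mutate(scores, score = 0)
  rz1 <- rank_prediction(zero, seed = 42)
  rz2 <- rank_prediction(zero, seed = 42)
  expect_true(all(rz1$all_zero))
  expect_equal(rz1$tie_group, rep(1L, 4))
  expect_equal(rz1, rz2) # reproducible permutation under a fixed seed
})

test_that("top_category returns the argmax and flags all-zero queries", {
  scores <- tibble::tibble(protein = "Q", category_index = 1:3,
                           category_label = letters[1:3],
                           score = c(5, 0, 0))
  expect_equal(top_category(scores), 1L)
  zero <- dplyr::mutate(scores, score = 0)
  expect_warning(res <- top_category(zero), "unpredictable")
  expect_true(is.na(res))
})

test_that("worked-example top categories match the published candidate order", {
  ex <- load_example("ybr039w")
  tp <- tethering_potential(ex$network, ex$query, ex$annotations,
                            ex$seeds, yeast_scheme)
  expect_equal(
    yeast_scheme$label[top_category(tp)],
    "Auxotrophies, carbon and nitrogen utilization defects"
  )
  ex2 <- load_example("ydl028c")
  tp2 <- tethering_potential(ex2$network, ex2$query, ex2$annotations,
                             ex2$seeds, yeast_scheme)
  ranked <- rank_prediction(tp2, seed = 1)
  expect_equal(ranked$category_label[1:2],
               c("Cell cycle defects", "Cell morphology and organelle mutants"))
})

test_that("predict_unlabeled covers exactly the non-seed network nodes", {
  sim <- simulate_phenotype_network(K = 4, n_per_category = 10,
                                    unlabeled_fraction = 0.25, seed = 9)
  preds <- predict_unlabeled(sim$network, sim$annotations, sim$scheme,
                             seed = 9)
  seeds <- seed_set(sim$annotations, sim$network)
  expect_setequal(unique(preds$protein),
                  setdiff(network_nodes(sim$network), seeds))
  expect_equal(nrow(preds), length(unique(preds$protein)) * 4)

  # a single voter of category 3 puts category 3 first
  net <- tibble::tibble(protein_a = "Q", protein_b = "S", weight = 950L)
  ann <- tibble::tibble(protein = "S", category = 3L)
  sch <- phenotype_scheme(letters[1:4])
  p <- predict_unlabeled(net, ann, sch, seed = 1)
  expect_equal(p$category_index[p$rank == 1], 3L)

  # network fully annotated -> nothing to predict
  ann_all <- tibble::tibble(protein = c("Q", "S"), category = c(1L, 3L))
  expect_equal(nrow(predict_unlabeled(net, ann_all, sch)), 0)
})
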
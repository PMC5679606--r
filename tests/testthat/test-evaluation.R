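test_that("label_nodes marks exactly the listed genes as essential", {
  g <- graph_from_pairs("A", "B", "B", "C", "C", "D", "D", "E")
  lab <- label_nodes(g, essential_set(c("b", "D")))
  expect_equal(sum(lab$essential), 2L)
  expect_equal(lab$essential[lab$node %in% c("B", "D")], c(1L, 1L))

  all_on <- label_nodes(g, essential_set(c("A", "B", "C", "D", "E")))
  expect_true(all(all_on$essential == 1))
  none <- label_nodes(g, essential_set(character()))
  expect_true(all(none$essential == 0))

  translated <- label_nodes(g, essential_set("G1"),
                            node_to_gene = c(A = "G1"))
  expect_equal(translated$essential[translated$node == "A"], 1L)
  expect_equal(sum(translated$essential), 1L)
})

test_that("confusion matrices count the top-k slice correctly", {
  sc <- scores_of(c("A", "B", "C", "D"), c(4, 3, 2, 1))
  lab <- labels_of(c("A", "B", "C", "D"), c(1, 0, 1, 0))
  expect_equal(confusion_at_top_k(sc, lab, 0)[, c("tp", "fp")],
               tibble::tibble(tp = 0L, fp = 0L))
  expect_equal(confusion_at_top_k(sc, lab, 4)[, c("fn", "tn")],
               tibble::tibble(fn = 0L, tn = 0L))
  cm <- confusion_at_top_k(sc, lab, 2)
  expect_equal(unlist(cm[, c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(confusion_at_top_k(sc, lab, 5), "k must be")

  # row/column sums tie out for random labelings
  set.seed(14)
  for (rep in 1:10) {
    n <- 30
    sc <- scores_of(sprintf("n%02d", 1:n), stats::rnorm(n))
    lab <- labels_of(sc$node, stats::rbinom(n, 1, 0.4))
    k <- sample(0:n, 1)
    cm <- confusion_at_top_k(sc, lab, k)
    expect_equal(cm$tp + cm$fn, sum(lab$essential))
    expect_equal(cm$fp + cm$tn, n - sum(lab$essential))
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, n)
  }
})

test_that("ROC curves have the right endpoints, AUC and error cases", {
  nodes <- c("A", "B", "C", "D")
  perfect <- roc_curve(scores_of(nodes, c(4, 3, 2, 1)),
                       labels_of(nodes, c(1, 1, 0, 0)))
  expect_equal(curve_auc(perfect), 1)
  inverted <- roc_curve(scores_of(nodes, c(4, 3, 2, 1)),
                        labels_of(nodes, c(0, 0, 1, 1)))
  expect_equal(curve_auc(inverted), 0)
  mixed <- roc_curve(scores_of(nodes, c(0.9, 0.8, 0.7, 0.6)),
                     labels_of(nodes, c(1, 0, 1, 0)))
  expect_equal(curve_auc(mixed), 0.75)
  expect_equal(as.numeric(mixed[1, ]), c(0, 0))
  expect_equal(as.numeric(mixed[nrow(mixed), ]), c(1, 1))
  expect_true(all(diff(mixed$fpr) >= 0) && all(diff(mixed$tpr) >= 0))

  expect_error(roc_curve(scores_of(nodes, 1:4), labels_of(nodes, c(1, 1, 1, 1))),
               "non-essential")
})

test_that("trapezoid AUC equals Mann-Whitney pair counting with ties at 1/2", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    score <- sample(stats::rnorm(ceiling(n / 2)), n, replace = TRUE)  # force ties
    label <- stats::rbinom(n, 1, 0.4)
    if (sum(label) == 0 || sum(label) == n) next
    sc <- scores_of(sprintf("n%02d", 1:n), score)
    lab <- labels_of(sc$node, label)
    expect_equal(curve_auc(roc_curve(sc, lab)), oracle_auc(score, label),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms of scores", {
  set.seed(12)
  n <- 80
  score <- stats::rnorm(n)
  lab <- labels_of(sprintf("n%02d", 1:n), stats::rbinom(n, 1, 0.3))
  base <- curve_auc(roc_curve(scores_of(lab$node, score), lab))
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) rank(x, ties.method = "average"))) {
    expect_equal(curve_auc(roc_curve(scores_of(lab$node, f(score)), lab)), base,
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent ROC implementation", {
  set.seed(44)
  n <- 200
  score <- stats::rnorm(n)
  label <- stats::rbinom(n, 1, 0.35)
  mine <- curve_auc(roc_curve(scores_of(sprintf("n%03d", 1:n), score),
                              labels_of(sprintf("n%03d", 1:n), label)))
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("precision-recall curves match hand-computed points", {
  nodes <- c("A", "B", "C", "D")
  pr <- pr_curve(scores_of(nodes, c(0.9, 0.8, 0.7, 0.6)),
                 labels_of(nodes, c(1, 0, 1, 0)))
  expect_equal(pr$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pr$precision, c(1, 0.5, 2 / 3, 0.5))

  perfect <- pr_curve(scores_of(nodes, c(4, 3, 2, 1)),
                      labels_of(nodes, c(1, 1, 0, 0)))
  expect_true(all(perfect$precision[perfect$recall <= 1 &
                                      seq_along(perfect$recall) <= 2] == 1))
  all_pos <- pr_curve(scores_of(nodes, c(4, 3, 2, 1)),
                      labels_of(nodes, c(1, 1, 1, 1)))
  expect_true(all(all_pos$precision == 1))
  expect_error(pr_curve(scores_of(nodes, 1:4), labels_of(nodes, c(0, 0, 0, 0))),
               "essential")
})

test_that("top-percent hit counts and unique counts match set arithmetic", {
  nodes <- sprintf("n%d", 1:6)
  lab <- labels_of(nodes, c(1, 1, 1, 0, 0, 0))  # n1..n3 essential
  a <- scores_of(nodes, c(6, 5, 1, 4, 3, 2))    # top3: n1 n2 n4
  b <- scores_of(nodes, c(6, 1, 5, 4, 3, 2))    # top3: n1 n3 n4
  tab <- top_percent_hits(list(a = a, b = b), lab, percents = 50)
  expect_equal(tab$hits, c(2L, 2L))
  expect_equal(tab$unique_hits, c(1L, 1L))  # a alone finds n2; b alone n3

  same <- top_percent_hits(list(x = a, y = a), lab, percents = c(50, 100))
  expect_true(all(same$unique_hits == 0))
  expect_equal(same$hits[same$percent == 100], c(3L, 3L))

  expect_error(top_percent_hits(list(a, b), lab, 50), "named")
  expect_error(top_percent_hits(list(a = a), lab, 0), "percents")
})

test_that("ranking overlap partitions essentials found by two top slices", {
  nodes <- sprintf("n%d", 1:6)
  lab <- labels_of(nodes, c(1, 1, 1, 0, 0, 0))
  a <- scores_of(nodes, c(6, 5, 1, 4, 3, 2))
  b <- scores_of(nodes, c(6, 1, 5, 4, 3, 2))
  ov <- ranking_overlap(a, b, lab, percent = 50)
  expect_equal(ov$shared, 1L)   # n1
  expect_equal(ov$only_a, 1L)   # n2
  expect_equal(ov$only_b, 1L)   # n3

  expect_equal(ranking_overlap(a, a, lab, 50)$only_a, 0L)
  disjoint_b <- scores_of(nodes, c(1, 2, 3, 6, 5, 4))
  ov2 <- ranking_overlap(a, disjoint_b, lab, percent = 50)
  expect_equal(ov2$shared, 0L)
})

test_that("parameter sweep cells equal independent diffslc evaluations", {
  g <- random_gnp(30, 0.2, 23)
  set.seed(3)
  w <- all_edge_weights(g)
  w$coexpr <- stats::runif(nrow(w))
  lab <- labels_of(igraph::V(g)$name,
                   stats::rbinom(igraph::vcount(g), 1, 0.4))
  one <- parameter_sweep(g, w, lab, beta_grid = 0.8, omega_grid = 0.1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$auc, curve_auc(roc_curve(diffslc(g, w, 0.8, 0.1), lab)))

  grid <- parameter_sweep(g, w, lab, beta_grid = c(0.2, 0.5, 0.9),
                          omega_grid = c(0, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    direct <- curve_auc(roc_curve(
      diffslc(g, w, beta = grid$beta[i], omega = grid$omega[i]), lab))
    expect_identical(grid$auc[i], direct)
  }
  # beta is irrelevant when omega = 1 (pure eigenvector score)
  at1 <- grid$auc[grid$omega == 1]
  expect_true(all(at1 == at1[1]))
  expect_error(parameter_sweep(g, w, lab, beta_grid = numeric()), "grids")
})

test_that("bootstrap AUC interval brackets the point estimate", {
  set.seed(10)
  n <- 60
  sc <- scores_of(sprintf("n%02d", 1:n), stats::rnorm(n))
  lab <- labels_of(sc$node, stats::rbinom(n, 1, 0.5))
  ci <- bootstrap_auc_ci(sc, lab, n_boot = 200)
  expect_lte(ci$lower, ci$auc)
  expect_gte(ci$upper, ci$auc)
})
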
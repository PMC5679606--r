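get_score <- function(sc, node) sc$score[sc$node == node]

test_that("degree centrality counts incident edges, zero for isolates", {
  rec <- data.frame(a = c("P1", "P1", "P20"), b = c("P2", "P3", "P20"))
  net <- build_network(rec)  # P20 self-interaction only -> isolated node
  dc <- degree_centrality(net)
  expect_equal(get_score(dc, "P20"), 0)
  expect_equal(get_score(dc, "P1"), 2)

  k <- degree_centrality(k4())
  expect_true(all(k$score == 3))
  s <- degree_centrality(star4())
  expect_equal(get_score(s, "C0"), 4)
  expect_true(all(s$score[s$node != "C0"] == 1))
})

test_that("harmonic closeness sums reciprocal distances; classic mode inverts farness", {
  cc <- closeness_centrality(path3())
  expect_equal(get_score(cc, "B"), 2.0)
  expect_equal(get_score(cc, "A"), 1.5)

  lonely <- build_network(data.frame(a = c("X", "Y"), b = c("Y", "X")))
  lonely <- igraph::add_vertices(lonely, 1, name = "Z")
  expect_equal(get_score(closeness_centrality(lonely), "Z"), 0)

  classic <- closeness_centrality(path3(), mode = "classic")
  expect_equal(get_score(classic, "B"), 1 / 2)
  expect_equal(get_score(classic, "A"), 1 / 3)
})

test_that("betweenness matches hand values and the path-enumeration oracle", {
  bc <- betweenness_centrality(star4())
  expect_equal(get_score(bc, "C0"), 6)  # choose(4, 2)
  expect_true(all(bc$score[bc$node != "C0"] == 0))
  expect_equal(get_score(betweenness_centrality(path3()), "B"), 1)

  tree <- build_network(data.frame(a = c("A", "A", "B", "B"),
                                   b = c("B", "C", "D", "E")))
  bt <- betweenness_centrality(tree)
  for (leaf in c("C", "D", "E")) expect_equal(get_score(bt, leaf), 0)

  for (seed in 1:5) {
    g <- random_gnp(18, 0.2, seed)
    got <- betweenness_centrality(g)
    want <- oracle_betweenness(g)
    expect_equal(stats::setNames(got$score, got$node), want[got$node],
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality matches dense eigensolver and satisfies Ax = lambda x", {
  ec_path <- eigenvector_centrality(path3())
  expect_equal(get_score(ec_path, "B"), 1.0)
  expect_equal(get_score(ec_path, "A"), 1 / sqrt(2), tolerance = 1e-10)

  ec_star <- eigenvector_centrality(star4())
  expect_equal(get_score(ec_star, "L1"), 0.5, tolerance = 1e-10)
  expect_equal(attr(ec_star, "lambda"), 2, tolerance = 1e-10)

  expect_true(all(eigenvector_centrality(k4())$score == 1))

  for (seed in c(2, 8)) {
    g <- random_gnp(40, 0.15, seed)
    got <- eigenvector_centrality(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    e <- eigen(A, symmetric = TRUE)
    ref <- abs(e$vectors[, which.max(e$values)])
    ref <- ref / max(ref)
    expect_equal(got$score, ref, tolerance = 1e-8)
    # residual on the unit-scale vector
    x <- got$score / sqrt(sum(got$score^2))
    lambda <- as.numeric(x %*% A %*% x)
    expect_lt(sqrt(sum((A %*% x - lambda * x)^2)), 1e-10)
  }
})

test_that("subgraph centrality equals closed forms and the matrix-exponential diagonal", {
  single_edge <- build_network(data.frame(a = "A", b = "B"))
  expect_equal(subgraph_centrality(single_edge)$score, rep(cosh(1), 2),
               tolerance = 1e-12)
  tri <- subgraph_centrality(triangle3())
  expect_equal(tri$score, rep(exp(2) / 3 + 2 * exp(-1) / 3, 3),
               tolerance = 1e-12)
  iso <- build_network(data.frame(a = "A", b = "B"))
  iso <- igraph::add_vertices(iso, 1, name = "Z")
  expect_equal(get_score(subgraph_centrality(iso), "Z"), 1.0)

  for (seed in c(1, 7)) {
    g <- random_gnp(30, 0.15, seed)
    got <- subgraph_centrality(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(got$score, oracle_expm_diag(A), tolerance = 1e-8)
  }
  expect_error(subgraph_centrality(random_gnp(30, 0.1, 1), max_nodes = 10),
               "max_nodes")
  small <- random_gnp(15, 0.2, 3)
  expect_equal(subgraph_centrality(small, max_nodes = 5, fallback = "expm")$score,
               subgraph_centrality(small)$score, tolerance = 1e-10)
})

test_that("BDC mixes incident coexpression and ECC and reduces at beta extremes", {
  g <- path3()  # edges A-B, B-C
  w <- all_edge_weights(g, tibble::tibble(
    node_a = c("A", "B"), node_b = c("B", "C"), coexpr = c(0.5, 1.0)
  ))
  # hand-set ecc to the worked example (0 is what path edges give anyway)
  w$ecc <- c(2.0, 0.0)
  bdc <- biased_degree_centrality(g, w, beta = 0.8)
  expect_equal(get_score(bdc, "B"), (0.8 * 0.5 + 0.2 * 2.0) + (0.8 * 1.0 + 0.2 * 0))
  expect_equal(get_score(bdc, "A"), 0.8 * 0.5 + 0.2 * 2.0)

  b0 <- biased_degree_centrality(g, w, beta = 0)
  expect_equal(get_score(b0, "B"), sum(w$ecc))
  b1 <- biased_degree_centrality(g, w, beta = 1)
  expect_equal(get_score(b1, "B"), sum(w$coexpr))

  expect_error(biased_degree_centrality(g, w, beta = 1.2), "beta")
  expect_error(biased_degree_centrality(g, w[1, ], beta = 0.5), "missing")
})

test_that("with zero coexpression and constant ECC, BDC is rank-equal to degree", {
  g <- random_gnp(25, 0.2, 13)
  w <- all_edge_weights(g)
  w$ecc <- rep(0.37, nrow(w))
  bdc <- biased_degree_centrality(g, w, beta = 0.25)
  dc <- degree_centrality(g)
  expect_equal(bdc$score, 0.75 * 0.37 * dc$score, tolerance = 1e-12)
})

test_that("DiffSLC combines EC and BDC and reduces at omega extremes", {
  g <- random_gnp(20, 0.25, 5)
  set.seed(6)
  cx <- edge_table_weights <- all_edge_weights(g)
  cx$coexpr <- stats::runif(nrow(cx))
  ec <- eigenvector_centrality(g)
  bdc <- biased_degree_centrality(g, cx, beta = 0.8)

  ds <- diffslc(g, cx, beta = 0.8, omega = 0.1)
  expect_equal(ds$score, 0.1 * ec$score + 0.9 * bdc$score, tolerance = 1e-12)

  expect_equal(diffslc(g, cx, omega = 1)$score, ec$score, tolerance = 1e-12)
  expect_equal(diffslc(g, cx, omega = 0)$score, bdc$score, tolerance = 1e-12)
  expect_error(diffslc(g, cx, omega = -0.1), "omega")

  # affine in omega: the midpoint mix equals the mean of the extremes
  mid <- diffslc(g, cx, omega = 0.5)$score
  expect_equal(mid, (diffslc(g, cx, omega = 0)$score +
                       diffslc(g, cx, omega = 1)$score) / 2, tolerance = 1e-12)

  mm <- diffslc(g, cx, omega = 0.3, normalization = "minmax")
  expect_true(all(mm$score >= 0 & mm$score <= 1 + 1e-12))
  params <- attr(ds, "params")
  expect_equal(params$beta, 0.8)
  expect_equal(params$omega, 0.1)
})

test_that("all centralities are invariant under node relabeling", {
  g <- random_gnp(22, 0.2, 77)
  set.seed(2)
  perm <- sample(igraph::V(g)$name)
  relabel <- stats::setNames(perm, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  g2 <- build_network(data.frame(a = unname(relabel[el[, 1]]),
                                 b = unname(relabel[el[, 2]])))
  w1 <- all_edge_weights(g)
  w2 <- all_edge_weights(g2)
  for (m in c("degree", "closeness", "betweenness", "eigenvector", "subgraph")) {
    s1 <- centrality(g, m)
    s2 <- centrality(g2, m)
    expect_equal(stats::setNames(s2$score, s2$node)[unname(relabel[s1$node])],
                 stats::setNames(s1$score, unname(relabel[s1$node])),
                 tolerance = 1e-8)
  }
  s1 <- diffslc(g, w1)
  s2 <- diffslc(g2, w2)
  expect_equal(stats::setNames(s2$score, s2$node)[unname(relabel[s1$node])],
               stats::setNames(s1$score, unname(relabel[s1$node])),
               tolerance = 1e-8)
})

test_that("the centrality dispatcher validates method names", {
  g <- path3()
  expect_equal(centrality(g, "degree")$score, degree_centrality(g)$score)
  expect_error(centrality(g, "pagerank"), "unknown centrality")
  expect_error(centrality(g, "diffslc"), "requires `weights`")
})

test_that("tidy and glance summarize centrality score tables", {
  sc <- degree_centrality(star4())
  td <- generics::tidy(sc)
  expect_equal(td$rank, 1:5)
  expect_equal(td$node[1], "C0")
  gl <- generics::glance(diffslc(star4(), all_edge_weights(star4())))
  expect_equal(gl$method, "diffslc")
  expect_equal(gl$beta, 0.8)
  expect_equal(gl$n_nodes, 5L)
})
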
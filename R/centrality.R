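#' @title Centrality score tables
#' @description All centrality functions return a `centrality_scores` object:
#'   a tibble with columns `node` and `score` (one row per network node, all
#'   scores finite), carrying the method name and its parameters as
#'   attributes. [ranked()] adds the deterministic rank (descending score,
#'   ties broken by ascending node identifier); [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @param x,scores A `centrality_scores` object.
#' @name centrality_scores
NULL

new_centrality_scores <- function(nodes, score, method, params = list()) {
  stopifnot(length(nodes) == length(score))
  if (length(score) && !all(is.finite(score))) {
    abort(sprintf("non-finite %s score", method))
  }
  structure(
    tibble(node = as.character(nodes), score = as.numeric(score)),
    method = method, params = params,
    class = c("centrality_scores", class(tibble()))
  )
}

#' @rdname centrality_scores
#' @return `ranked()`: the score tibble with a `rank` column, sorted; rank 1
#'   is the highest score.
#' @export
ranked <- function(scores) {
  as_tibble(scores) |>
    arrange(desc(.data$score), .data$node) |>
    mutate(rank = row_number()) |>
    select("node", "score", "rank")
}

#' @rdname centrality_scores
#' @param ... Unused.
#' @export
tidy.centrality_scores <- function(x, ...) ranked(x)

#' @rdname centrality_scores
#' @export
glance.centrality_scores <- function(x, ...) {
  params <- attr(x, "params") %||% list()
  out <- tibble(method = attr(x, "method") %||% NA_character_,
                n_nodes = nrow(x))
  for (k in names(params)) out[[k]] <- params[[k]]
  out
}

#' Degree centrality
#'
#' DC(u): the number of edges incident to u. Under the centrality-lethality
#' hypothesis, high-degree (hub) proteins are more likely to be essential.
#'
#' @param net An igraph network.
#' @return A [centrality_scores] tibble.
#' @export
degree_centrality <- function(net) {
  d <- igraph::degree(net)
  new_centrality_scores(node_names(net), as.numeric(d), "degree")
}

#' Closeness centrality (harmonic form)
#'
#' CC(u) = sum over v != u of 1/d(u, v), with 1/Inf = 0 for unreachable
#' pairs. This harmonic form is well defined on disconnected networks. The
#' `"classic"` mode instead returns 1 / sum of distances to the nodes
#' reachable from u (0 for an isolated node).
#'
#' @param net An igraph network.
#' @param mode `"harmonic"` (default) or `"classic"`.
#' @return A [centrality_scores] tibble.
#' @export
closeness_centrality <- function(net, mode = c("harmonic", "classic")) {
  mode <- match.arg(mode)
  if (mode == "harmonic") {
    s <- igraph::harmonic_centrality(net, mode = "all")
  } else {
    d <- igraph::distances(net)
    diag(d) <- NA
    s <- apply(d, 1, function(row) {
      fin <- row[is.finite(row) & !is.na(row)]
      if (!length(fin)) 0 else 1 / sum(fin)
    })
  }
  new_centrality_scores(node_names(net), as.numeric(s), "closeness",
                        list(mode = mode))
}

#' Betweenness centrality
#'
#' BC(u) = sum over unordered pairs i != u != j of sigma_ij(u) / sigma_ij,
#' the fraction of shortest i-j paths passing through u. Unnormalized;
#' endpoint pairs involving u are excluded.
#'
#' @param net An igraph network.
#' @return A [centrality_scores] tibble.
#' @export
betweenness_centrality <- function(net) {
  s <- igraph::betweenness(net, directed = FALSE, weights = NA)
  new_centrality_scores(node_names(net), as.numeric(s), "betweenness")
}

#' Eigenvector centrality
#'
#' The entries of the principal eigenvector of the adjacency matrix: a
#' node's score is proportional to the sum of its neighbors' scores, so the
#' measure rewards connection to other well-connected nodes. Computed by
#' deterministic power iteration on the (optionally weighted) adjacency
#' matrix with a +1 diagonal shift — the shift leaves eigenvectors unchanged
#' but guarantees convergence on bipartite graphs — from a uniform start
#' vector, so results are fully reproducible. Scores are non-negative and
#' rescaled so the maximum entry is 1; nodes outside the dominant component
#' converge to ~0.
#'
#' @param net An igraph network (non-empty).
#' @param weights Optional per-edge weights as a data frame with columns
#'   `node_a`, `node_b` and a weight column (named by `weight_col`); when
#'   given the weighted adjacency matrix is used.
#' @param weight_col Name of the weight column in `weights`.
#' @param tol Convergence tolerance on the max-norm change of the
#'   unit-scaled score vector.
#' @param max_iter Iteration budget; exceeding it is an error reporting the
#'   residual.
#' @return A [centrality_scores] tibble; attribute `lambda` holds the
#'   dominant eigenvalue estimate.
#' @export
eigenvector_centrality <- function(net, weights = NULL, weight_col = "coexpr",
                                   tol = 1e-12, max_iter = 1e6) {
  n <- igraph::vcount(net)
  if (n == 0L) abort("eigenvector centrality of an empty network is undefined")
  A <- adjacency_sparse(net, weights, weight_col)
  if (all(A@x == 0) || length(A@x) == 0L) {
    out <- new_centrality_scores(node_names(net), rep(0, n), "eigenvector")
    attr(out, "lambda") <- 0
    return(out)
  }
  x <- rep(1 / sqrt(n), n)
  iter <- 0L
  repeat {
    y <- as.numeric(A %*% x) + x  # +1 spectral shift
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    x <- y
    iter <- iter + 1L
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf(
        "eigenvector centrality did not converge in %d iterations (residual %.3e)",
        as.integer(max_iter), delta
      ))
    }
  }
  x <- pmax(x, 0)
  lambda <- as.numeric(x %*% (A %*% x)) / sum(x^2)
  out <- new_centrality_scores(node_names(net), x / max(x), "eigenvector")
  attr(out, "lambda") <- lambda
  out
}

adjacency_sparse <- function(net, weights = NULL, weight_col = "coexpr") {
  if (is.null(weights)) {
    return(igraph::as_adjacency_matrix(net, sparse = TRUE))
  }
  nm <- node_names(net)
  w <- as_tibble(weights)
  p <- normalize_pairs(w$node_a, w$node_b)
  i <- match(p$node_a, nm)
  j <- match(p$node_b, nm)
  if (anyNA(i) || anyNA(j)) abort("weights reference nodes absent from the network")
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(as.numeric(w[[weight_col]]), 2),
                       dims = c(length(nm), length(nm)),
                       dimnames = list(nm, nm))
}

#' Subgraph centrality
#'
#' SC(u) = sum_j (v_j[u])^2 exp(lambda_j) over the eigenpairs of the
#' adjacency matrix — equivalently the u-th diagonal entry of expm(A). The
#' score counts closed walks starting and ending at u, weighting short walks
#' (small subgraphs, e.g. triangles) most. Computed by full symmetric
#' eigendecomposition up to `max_nodes` nodes; for larger networks the
#' sparse matrix exponential fallback (`fallback = "expm"`,
#' [Matrix::expm()]) must be enabled explicitly.
#'
#' @param net An igraph network.
#' @param max_nodes Size threshold for the dense eigendecomposition.
#' @param fallback `"none"` (default: error above the threshold) or
#'   `"expm"`.
#' @return A [centrality_scores] tibble.
#' @export
subgraph_centrality <- function(net, max_nodes = 5000,
                                fallback = c("none", "expm")) {
  fallback <- match.arg(fallback)
  n <- igraph::vcount(net)
  if (n == 0L) return(new_centrality_scores(character(), numeric(), "subgraph"))
  if (n > max_nodes) {
    if (fallback == "none") {
      abort(sprintf(
        "network has %d nodes (> max_nodes = %d); enable fallback = \"expm\" or raise max_nodes",
        n, max_nodes
      ))
    }
    A <- adjacency_sparse(net)
    s <- Matrix::diag(Matrix::expm(A))
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
    e <- eigen(A, symmetric = TRUE)
    s <- as.numeric((e$vectors^2) %*% exp(e$values))
  }
  new_centrality_scores(node_names(net), s, "subgraph")
}

#' Coexpression- and clustering-biased degree centrality (BDC)
#'
#' BDC(u) = sum over the edges incident to u of
#' beta * coexpr(e) + (1 - beta) * ecc(e):
#' a degree centrality in which each incident edge contributes a beta-mix of
#' its gene-coexpression weight and its edge clustering coefficient instead
#' of 1. beta = 1 reduces to the coexpression-weighted degree, beta = 0 to
#' the ECC-weighted degree.
#'
#' @param net An igraph network.
#' @param weights An `edge_weights` tibble ([all_edge_weights()]) covering
#'   every edge of `net`.
#' @param beta Mixing weight in \[0, 1\] for the coexpression term
#'   (default 0.8).
#' @return A [centrality_scores] tibble.
#' @export
biased_degree_centrality <- function(net, weights, beta = 0.8) {
  assert_scalar_number(beta, "beta", 0, 1)
  w <- check_weight_cover(net, weights)
  ew <- beta * w$coexpr + (1 - beta) * w$ecc
  nm <- node_names(net)
  s <- numeric(length(nm))
  names(s) <- nm
  inc <- tapply(c(ew, ew), c(w$node_a, w$node_b), sum)
  s[names(inc)] <- inc
  new_centrality_scores(nm, unname(s), "bdc", list(beta = beta))
}

check_weight_cover <- function(net, weights) {
  w <- as_tibble(weights)
  need <- c("node_a", "node_b", "ecc", "coexpr")
  if (!all(need %in% names(w))) {
    abort("`weights` must have columns node_a, node_b, ecc, coexpr (see all_edge_weights())")
  }
  et <- edge_table(net)
  hit <- match(edge_key(et$node_a, et$node_b), edge_key(w$node_a, w$node_b))
  if (anyNA(hit)) {
    abort(sprintf("%d network edge(s) missing from `weights`", sum(is.na(hit))))
  }
  w[hit, , drop = FALSE]
}

#' DiffSLC: differential-expression and structure biased centrality
#'
#' DiffSLC(u) = omega * EC(u) + (1 - omega) * BDC(u): a weighted combination
#' of eigenvector centrality — which ranks low-degree nodes attached to
#' important neighbors highly — and the coexpression/ECC biased degree
#' centrality ([biased_degree_centrality()]). omega = 1 reduces to EC,
#' omega = 0 to BDC. Defaults beta = 0.8, omega = 0.1.
#'
#' EC is computed on the unweighted adjacency matrix by default
#' (`ec_mode = "weighted"` uses the coexpression-weighted matrix) and is
#' scaled to max 1 by construction; BDC is used raw under the default
#' `normalization = "ec_max"`, while `"minmax"` rescales both terms to
#' \[0, 1\] before mixing (used by sensitivity analyses).
#'
#' @inheritParams biased_degree_centrality
#' @param omega Mixing weight in \[0, 1\] for the eigenvector term
#'   (default 0.1).
#' @param normalization `"ec_max"` (default) or `"minmax"`.
#' @param ec_mode `"unweighted"` (default) or `"weighted"`.
#' @return A [centrality_scores] tibble with `beta`, `omega`,
#'   `normalization` and `ec_mode` recorded in its parameters.
#' @export
diffslc <- function(net, weights, beta = 0.8, omega = 0.1,
                    normalization = c("ec_max", "minmax"),
                    ec_mode = c("unweighted", "weighted")) {
  assert_scalar_number(beta, "beta", 0, 1)
  assert_scalar_number(omega, "omega", 0, 1)
  normalization <- match.arg(normalization)
  ec_mode <- match.arg(ec_mode)
  ec <- if (ec_mode == "unweighted") {
    eigenvector_centrality(net)
  } else {
    eigenvector_centrality(net, weights = weights)
  }
  bdc <- biased_degree_centrality(net, weights, beta = beta)
  ecs <- ec$score
  bds <- bdc$score
  if (normalization == "minmax") {
    ecs <- minmax(ecs)
    bds <- minmax(bds)
  }
  new_centrality_scores(
    ec$node, omega * ecs + (1 - omega) * bds, "diffslc",
    list(beta = beta, omega = omega, normalization = normalization,
         ec_mode = ec_mode)
  )
}

minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Compute any supported centrality by name
#'
#' One dispatcher over the reference centralities (`"degree"`,
#' `"closeness"`, `"betweenness"`, `"eigenvector"`, `"subgraph"`) and the
#' biased scores (`"bdc"`, `"diffslc"`, which require `weights`).
#'
#' @param net An igraph network.
#' @param method Method name (see Description).
#' @param weights `edge_weights` tibble, required for `"bdc"`/`"diffslc"`.
#' @param ... Passed to the underlying centrality function.
#' @return A [centrality_scores] tibble.
#' @export
centrality <- function(net, method, weights = NULL, ...) {
  methods <- c("degree", "closeness", "betweenness", "eigenvector",
               "subgraph", "bdc", "diffslc")
  if (!is.character(method) || length(method) != 1L || !method %in% methods) {
    abort(sprintf("unknown centrality method %s; valid: %s",
                  deparse(method), paste(methods, collapse = ", ")))
  }
  switch(method,
    degree = degree_centrality(net),
    closeness = closeness_centrality(net, ...),
    betweenness = betweenness_centrality(net),
    eigenvector = eigenvector_centrality(net, ...),
    subgraph = subgraph_centrality(net, ...),
    bdc = {
      if (is.null(weights)) abort("method \"bdc\" requires `weights`")
      biased_degree_centrality(net, weights, ...)
    },
    diffslc = {
      if (is.null(weights)) abort("method \"diffslc\" requires `weights`")
      diffslc(net, weights, ...)
    }
  )
}
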
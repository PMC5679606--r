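# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and igraph where the package uses igraph for the same quantity)
# so agreement is evidence, not tautology.

# adjacency list from an explicit edge data frame
oracle_adjacency <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1]][i]
    b <- edges[[2]][i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

net_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
}

# triangle count for one edge by scanning every third node
oracle_edge_triangles <- function(net, u, v) {
  adj <- oracle_adjacency(net_edges(net), igraph::V(net)$name)
  sum(vapply(setdiff(names(adj), c(u, v)),
             function(w) (u %in% adj[[w]]) && (v %in% adj[[w]]), logical(1)))
}

# all shortest paths between two nodes by BFS layering + recursive expansion
oracle_shortest_paths <- function(adj, s, t) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        nxt <- c(nxt, v)
      }
    }
    frontier <- unique(nxt)
  }
  if (is.infinite(dist[t])) return(list())
  expand <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
    unlist(lapply(preds, function(p) {
      lapply(expand(p), function(path) c(path, v))
    }), recursive = FALSE)
  }
  expand(t)
}

# unnormalized betweenness over unordered pairs, by full path enumeration
oracle_betweenness <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- oracle_adjacency(net_edges(net), nodes)
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(pairs))) {
    paths <- oracle_shortest_paths(adj, pairs[1, k], pairs[2, k])
    if (!length(paths)) next
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      tab <- table(interior)
      bc[names(tab)] <- bc[names(tab)] + as.numeric(tab) / length(paths)
    }
  }
  bc
}

# O(m^2) distance correlation with explicit loops and elementwise centering
oracle_dcor <- function(x, y) {
  m <- length(x)
  dx <- matrix(0, m, m)
  dy <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    dx[i, j] <- abs(x[i] - x[j])
    dy[i, j] <- abs(y[i] - y[j])
  }
  center <- function(d) {
    A <- matrix(0, m, m)
    for (i in 1:m) for (j in 1:m) {
      A[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
    }
    A
  }
  A <- center(dx)
  B <- center(dy)
  dvx <- sum(A * A) / m^2
  dvy <- sum(B * B) / m^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(sum(A * B) / m^2, 0) / sqrt(dvx * dvy))
}

# Mann-Whitney AUC by explicit pair counting, ties scored 1/2
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# diagonal of expm(A) by truncated Taylor series on the dense matrix
oracle_expm_diag <- function(A, order = 60) {
  n <- nrow(A)
  acc <- diag(n)
  term <- diag(n)
  for (k in 1:order) {
    term <- term %*% A / k
    acc <- acc + term
  }
  diag(acc)
}
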
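#' Build an undirected simple PPI network from interaction records
#'
#' Nodes are all interactor identifiers seen in the records; edges are the
#' interactions with self-interactions removed and redundant (duplicate or
#' reversed) pairs collapsed to a single undirected edge.
#'
#' @param records Tibble of interaction records ([read_mitab()]), or any data
#'   frame whose first two columns are interactor identifiers.
#' @return An undirected simple [igraph::igraph] graph with named vertices.
#' @export
build_network <- function(records) {
  a <- as.character(records[[1]])
  b <- as.character(records[[2]])
  nodes <- sort(unique(c(a, b)))
  keep <- a != b
  pairs <- normalize_pairs(a[keep], b[keep]) |> distinct()
  igraph::graph_from_data_frame(pairs, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Drop small disconnected components
#'
#' Removes every connected component of `max_size` or fewer nodes. Isolated
#' proteins and tiny satellite clusters disconnected from the main network
#' carry no information usable by neighborhood-based centralities, so the
#' default removes components of one to three proteins. Idempotent.
#'
#' @param net An igraph network.
#' @param max_size Components of this size or smaller are removed (>= 1).
#' @return The filtered network.
#' @export
filter_small_components <- function(net, max_size = 3) {
  stopifnot(max_size >= 1)
  comp <- igraph::components(net)
  drop <- which(comp$csize[comp$membership] <= max_size)
  igraph::delete_vertices(net, drop)
}

node_names <- function(net) igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))

# tibble(node_a, node_b) of all edges in canonical pair order
edge_table <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (!nrow(el)) return(tibble(node_a = character(), node_b = character()))
  normalize_pairs(el[, 1], el[, 2])
}

# adjacency sets as a named list of character vectors
adjacency_sets <- function(net) {
  adj <- igraph::as_adj_list(net, mode = "all")
  nm <- node_names(net)
  stats::setNames(lapply(adj, function(v) nm[as.integer(v)]), nm)
}

check_edge <- function(net, edge) {
  edge <- as.character(edge)
  if (length(edge) != 2L) abort("`edge` must be a pair of node identifiers")
  if (!all(edge %in% node_names(net)) ||
      !igraph::are_adjacent(net, edge[1], edge[2])) {
    abort(sprintf("edge (%s, %s) is not in the network", edge[1], edge[2]))
  }
  edge
}

#' Number of triangles through an edge
#'
#' For edge (u, v), the count of common neighbors of u and v — each common
#' neighbor closes one triangle over the edge.
#'
#' @param net An igraph network.
#' @param edge Length-2 character vector `c(u, v)`; must be an edge of `net`.
#' @return Integer triangle count.
#' @export
count_edge_triangles <- function(net, edge) {
  edge <- check_edge(net, edge)
  nu <- igraph::neighbors(net, edge[1])$name
  nv <- igraph::neighbors(net, edge[2])$name
  length(intersect(nu, nv))
}

# per-edge triangle counts and endpoint degrees for all edges at once
edge_topology <- function(net) {
  et <- edge_table(net)
  if (!nrow(et)) return(mutate(et, z = integer(), deg_a = integer(), deg_b = integer()))
  adj <- adjacency_sets(net)
  deg <- igraph::degree(net)
  et |>
    mutate(
      z = map2_int(.data$node_a, .data$node_b,
                   function(u, v) length(intersect(adj[[u]], adj[[v]]))),
      deg_a = unname(deg[.data$node_a]),
      deg_b = unname(deg[.data$node_b])
    )
}

#' Edge clustering coefficient
#'
#' ECC of edge (u, v) is (z + 1) / min(k_u - 1, k_v - 1), where z is the
#' number of triangles through the edge. With `denominator = "degree"`
#' (default) k is the node degree, so the denominator is the maximum number
#' of triangles the edge could participate in; the `"triangles"` mode
#' instead uses the number of triangles each endpoint participates in.
#' When the denominator is not positive (a pendant edge) the formula is
#' undefined; such edges return 0 by default (`pendant = "zero"`) — a
#' pendant edge can close no triangle and should carry no clustering bias —
#' or (z + 1)/1 with `pendant = "unit"`.
#'
#' @param net An igraph network.
#' @param edge Optional pair `c(u, v)`. When omitted, all edges are scored.
#' @param denominator `"degree"` (default) or `"triangles"`; see Details.
#' @param pendant Degenerate-denominator convention: `"zero"` or `"unit"`.
#' @return A single number when `edge` is given, otherwise a tibble with
#'   columns `node_a`, `node_b`, `ecc` covering every edge.
#' @export
edge_clustering_coefficient <- function(net, edge = NULL,
                                        denominator = c("degree", "triangles"),
                                        pendant = c("zero", "unit")) {
  denominator <- match.arg(denominator)
  pendant <- match.arg(pendant)
  tab <- edge_topology(net)
  if (denominator == "degree") {
    kx <- tab$deg_a
    ky <- tab$deg_b
  } else {
    tri <- igraph::count_triangles(net)
    names(tri) <- node_names(net)
    kx <- unname(tri[tab$node_a])
    ky <- unname(tri[tab$node_b])
  }
  den <- pmin(kx - 1, ky - 1)
  ecc <- ifelse(den <= 0,
                if (pendant == "zero") 0 else tab$z + 1,
                (tab$z + 1) / den)
  out <- tibble(node_a = tab$node_a, node_b = tab$node_b, ecc = as.numeric(ecc))
  if (is.null(edge)) return(out)
  edge <- check_edge(net, edge)
  p <- normalize_pairs(edge[1], edge[2])
  out$ecc[out$node_a == p$node_a & out$node_b == p$node_b]
}

#' Assemble per-edge weights for biased centralities
#'
#' Computes the edge clustering coefficient for every edge and merges in the
#' supplied coexpression values. Edges absent from the coexpression map get
#' the missing-data default of 0 — the ECC term still contributes for those
#' edges — and the number of such edges is recorded in the `n_missing_coexpr`
#' attribute.
#'
#' @param net An igraph network.
#' @param coexpr Optional data frame with columns `node_a`, `node_b`,
#'   `coexpr` (any pair order), e.g. from [edge_coexpression()].
#' @param ... Passed on to [edge_clustering_coefficient()] (`denominator`,
#'   `pendant`).
#' @return An `edge_weights` tibble with columns `node_a`, `node_b`, `ecc`,
#'   `coexpr`, one row per network edge in canonical pair order.
#' @export
all_edge_weights <- function(net, coexpr = NULL, ...) {
  out <- edge_clustering_coefficient(net, ...)
  if (is.null(coexpr)) {
    out$coexpr <- 0
    n_missing <- nrow(out)
  } else {
    cx <- as_tibble(coexpr)
    key <- edge_key(cx$node_a, cx$node_b)
    hit <- match(edge_key(out$node_a, out$node_b), key)
    out$coexpr <- ifelse(is.na(hit), 0, cx$coexpr[hit])
    n_missing <- sum(is.na(hit))
  }
  structure(out, n_missing_coexpr = n_missing,
            class = c("edge_weights", class(out)))
}

#' Export the annotated edge list as TSV
#'
#' Writes `node_a`, `node_b`, `ecc`, `coexpr` with a provenance header, for
#' interoperability with generic graph tools.
#'
#' @param weights An `edge_weights` tibble from [all_edge_weights()].
#' @param path Output path.
#' @param extra_params Extra provenance key/value pairs.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(weights, path, extra_params = list()) {
  write_tsv_with_header(
    as_tibble(weights)[, c("node_a", "node_b", "ecc", "coexpr")],
    path, extra_params
  )
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to the TSV.
#' @return An `edge_weights` tibble.
#' @export
read_edge_list <- function(path) {
  tab <- as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                                     check.names = FALSE)) |>
    mutate(node_a = as.character(.data$node_a),
           node_b = as.character(.data$node_b))
  structure(tab, class = c("edge_weights", class(tab)))
}

#' @importFrom purrr map2_int
NULL
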
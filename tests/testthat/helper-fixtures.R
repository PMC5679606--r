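# small graphs and files built in code at test time

graph_from_pairs <- function(...) {
  pairs <- matrix(c(...), ncol = 2, byrow = TRUE)
  build_network(data.frame(a = pairs[, 1], b = pairs[, 2]))
}

path3 <- function() graph_from_pairs("A", "B", "B", "C")
star4 <- function() graph_from_pairs("C0", "L1", "C0", "L2", "C0", "L3", "C0", "L4")
triangle3 <- function() graph_from_pairs("A", "B", "B", "C", "A", "C")
k4 <- function() {
  nodes <- c("A", "B", "C", "D")
  pr <- t(utils::combn(nodes, 2))
  build_network(data.frame(a = pr[, 1], b = pr[, 2]))
}

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# uniform edge weights for tests that need a full cover
unit_weights <- function(net, coexpr = NULL) {
  all_edge_weights(net, coexpr)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal hand-rolled MITAB line (15 columns)
mitab_line <- function(a, b, taxa = 4932, taxb = 4932,
                       xa = "-", xb = "-") {
  fields <- rep("-", 15)
  fields[1] <- paste0("dip:", a)
  fields[2] <- paste0("dip:", b)
  fields[3] <- xa
  fields[4] <- xb
  fields[10] <- if (is.na(taxa)) "unknown" else sprintf("taxid:%d(yeast)", taxa)
  fields[11] <- if (is.na(taxb)) "unknown" else sprintf("taxid:%d(yeast)", taxb)
  paste(fields, collapse = "\t")
}

mitab_header <- function() paste(rep("#header", 15), collapse = "\t")

scores_of <- function(nodes, values, method = "test") {
  diffslc:::new_centrality_scores(nodes, values, method)
}

labels_of <- function(nodes, essential) {
  tibble::tibble(node = nodes, essential = as.integer(essential))
}
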
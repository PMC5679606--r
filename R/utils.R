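#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange desc mutate filter select left_join anti_join
#'   distinct group_by summarise ungroup bind_rows row_number n
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap
NULL

# canonical unordered-pair order: node_a <= node_b lexicographically
normalize_pairs <- function(a, b) {
  swap <- a > b
  tibble(node_a = ifelse(swap, b, a), node_b = ifelse(swap, a, b))
}

edge_key <- function(a, b) {
  p <- normalize_pairs(a, b)
  paste(p$node_a, p$node_b, sep = "\r")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# provenance header for all on-disk tables: tool version + run parameters
provenance_header <- function(params = list()) {
  ver <- as.character(utils::packageVersion("diffslc"))
  lines <- sprintf("# diffslc %s", ver)
  if (length(params)) {
    kv <- vapply(names(params), function(k) {
      sprintf("# %s=%s", k, paste(format(params[[k]], digits = 15), collapse = ","))
    }, character(1))
    lines <- c(lines, kv)
  }
  lines
}

write_tsv_with_header <- function(x, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(
    as.data.frame(lapply(x, function(col) {
      if (is.double(col)) format(col, digits = 15, trim = TRUE) else col
    })),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
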
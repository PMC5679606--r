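#' Read a PSI-MI MITAB 2.5 interaction file
#'
#' Parses a tab-delimited MITAB 2.5 file into one interaction record per data
#' line. The first two columns are taken as the interactor identifiers (a
#' leading `db:` prefix such as `dip:` is stripped); columns 3 and 4 supply
#' `database:accession` cross-references used later for probeset mapping;
#' columns 10 and 11 carry `taxid:NNNN` organism tags. Lines starting with
#' `#` (including the usual MITAB header) are skipped. Both the 15-column
#' MITAB 2.5 layout and wider variants are accepted.
#'
#' Records whose taxon field cannot be parsed are dropped with a warning.
#' Self-interactions are retained here; they are removed when the graph is
#' built by [build_network()].
#'
#' @param path Path to a MITAB file.
#' @param taxon_filter Optional NCBI taxon id (integer). When given, records
#'   where either interactor belongs to a different taxon are excluded —
#'   e.g. `taxon_filter = 4932` keeps only yeast–yeast interactions.
#' @return A tibble with one row per retained record and columns
#'   `interactor_a`, `interactor_b` (character), `taxon_a`, `taxon_b`
#'   (integer), and list-columns `xrefs_a`, `xrefs_b`, each element a tibble
#'   with columns `database` and `accession`.
#' @seealso [build_network()], [write_mitab()]
#' @export
read_mitab <- function(path, taxon_filter = NULL) {
  if (!file.exists(path)) abort(sprintf("MITAB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(tibble(
      interactor_a = character(), interactor_b = character(),
      taxon_a = integer(), taxon_b = integer(),
      xrefs_a = list(), xrefs_b = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    bad <- which(nf < 15L)[1L]
    abort(sprintf(
      "malformed MITAB line %d: expected >= 15 tab-separated columns, found %d",
      lineno[bad], nf[bad]
    ))
  }
  strip_db <- function(x) sub("^[A-Za-z0-9_.-]+:", "", sub("\\|.*$", "", x))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  taxon_one <- function(x) {
    m <- regmatches(x, regexpr("taxid:-?[0-9]+", x))
    if (!length(m)) return(NA_integer_)
    suppressWarnings(as.integer(sub("taxid:", "", m)))
  }
  parse_xrefs <- function(x) {
    toks <- strsplit(x, "|", fixed = TRUE)[[1]]
    toks <- toks[toks != "-" & nzchar(toks) & grepl(":", toks, fixed = TRUE)]
    tibble(
      database = tolower(sub(":.*$", "", toks)),
      accession = sub("^[^:]*:", "", toks)
    )
  }
  rec <- tibble(
    interactor_a = strip_db(col(1)),
    interactor_b = strip_db(col(2)),
    taxon_a = vapply(col(10), taxon_one, integer(1), USE.NAMES = FALSE),
    taxon_b = vapply(col(11), taxon_one, integer(1), USE.NAMES = FALSE),
    xrefs_a = map(col(3), parse_xrefs),
    xrefs_b = map(col(4), parse_xrefs)
  )
  if (any(!nzchar(rec$interactor_a) | !nzchar(rec$interactor_b))) {
    abort("MITAB record with empty interactor identifier")
  }
  bad_taxon <- is.na(rec$taxon_a) | is.na(rec$taxon_b)
  if (any(bad_taxon)) {
    warn(sprintf(
      "%d MITAB record(s) dropped: unparseable taxid token", sum(bad_taxon)
    ))
    rec <- rec[!bad_taxon, ]
  }
  if (!is.null(taxon_filter)) {
    taxon_filter <- as.integer(taxon_filter)
    rec <- rec[rec$taxon_a == taxon_filter & rec$taxon_b == taxon_filter, ]
  }
  rec
}

#' Write interaction records as a minimal MITAB 2.5 file
#'
#' Emits valid 15-column records: unique identifiers in columns 1–2,
#' cross-references in columns 3–4, `taxid:` organism tags in columns 10–11,
#' `-` elsewhere. Reading the file back with [read_mitab()] is lossless for
#' identifiers, taxa and cross-references.
#'
#' @param records A tibble as returned by [read_mitab()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mitab <- function(records, path) {
  fmt_xrefs <- function(x) {
    if (is.null(x) || !nrow(x)) return("-")
    paste(paste0(x$database, ":", x$accession), collapse = "|")
  }
  n <- nrow(records)
  cols <- matrix("-", nrow = n, ncol = 15)
  cols[, 1] <- paste0("dip:", records$interactor_a)
  cols[, 2] <- paste0("dip:", records$interactor_b)
  cols[, 3] <- vapply(records$xrefs_a, fmt_xrefs, character(1))
  cols[, 4] <- vapply(records$xrefs_b, fmt_xrefs, character(1))
  cols[, 10] <- sprintf("taxid:%d", records$taxon_a)
  cols[, 11] <- sprintf("taxid:%d", records$taxon_b)
  header <- paste(c(
    "#ID interactor A", "ID interactor B", "Alt. ID A", "Alt. ID B",
    "Alias A", "Alias B", "Detection method", "First author", "Publication",
    "Taxid A", "Taxid B", "Interaction type", "Source database",
    "Interaction ID", "Confidence"
  ), collapse = "\t")
  writeLines(c(header, apply(cols, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a processed expression matrix
#'
#' Reads a tab-delimited matrix of (typically RMA-scale) expression values:
#' first column probeset identifiers, remaining columns numeric samples, with
#' a header row of sample names.
#'
#' @param path Path to the tab-delimited file.
#' @return A numeric matrix, probesets in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 3L) abort("expression matrix needs >= 2 sample columns")
  probesets <- raw[[1]]
  if (anyDuplicated(probesets)) {
    dup <- probesets[duplicated(probesets)][1]
    abort(sprintf("duplicate probeset row: %s", dup))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric expression value at row %d (probeset %s), sample column %d",
      bad[1], probesets[bad[1]], bad[2]
    ))
  }
  dimnames(num) <- list(probesets, colnames(raw)[-1])
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 15 significant digits so a write-then-read round
#' trip preserves them to well beyond 12 significant digits.
#'
#' @param expr Numeric matrix with probeset rownames and sample colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(
    probeset_id = rownames(expr),
    format(expr, digits = 15, trim = TRUE),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an essential-gene list
#'
#' Reads a plain-text list (one gene identifier per line, `#` comments
#' ignored) in the style of the DEG / yeast deletion-project exports.
#' Identifiers are trimmed and compared case-insensitively (uppercased), and
#' an optional synonym table collapses aliases onto canonical names. Genes
#' absent from the list are treated as non-essential by [label_nodes()],
#' giving a conservative estimate of prediction success.
#'
#' @param path Path to the gene list.
#' @param synonyms Optional path to a two-column tab-delimited table
#'   (`alias`, `canonical`) mapping gene synonyms to canonical identifiers.
#' @return An `essential_set`: see [essential_set()].
#' @export
read_essential_list <- function(path, synonyms = NULL) {
  if (!file.exists(path)) abort(sprintf("essential-gene list not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syn <- NULL
  if (!is.null(synonyms)) {
    tab <- utils::read.delim(synonyms, header = TRUE, sep = "\t",
                             colClasses = "character")
    syn <- stats::setNames(toupper(tab[[2]]), toupper(tab[[1]]))
  }
  if (!length(lines)) warn(sprintf("essential-gene list is empty: %s", path))
  essential_set(lines, synonym_map = syn)
}

#' Construct an essential-gene set
#'
#' Canonicalizes identifiers (trim + uppercase), applies the synonym map, and
#' deduplicates. Lookup through the synonym map is idempotent: canonical
#' identifiers map to themselves.
#'
#' @param genes Character vector of gene identifiers.
#' @param synonym_map Optional named character vector, `names` = alias,
#'   values = canonical identifier (both matched case-insensitively).
#' @return An object of class `essential_set`: a list with elements `genes`
#'   (sorted unique canonical identifiers) and `synonym_map`.
#' @export
essential_set <- function(genes, synonym_map = NULL) {
  canon <- canonical_gene(genes, synonym_map)
  structure(
    list(genes = sort(unique(canon)), synonym_map = synonym_map),
    class = "essential_set"
  )
}

#' Canonicalize gene identifiers
#'
#' @param genes Character vector.
#' @param synonym_map Named character vector (alias -> canonical) or an
#'   `essential_set` whose map should be used.
#' @return Uppercased, trimmed, synonym-collapsed identifiers.
#' @export
canonical_gene <- function(genes, synonym_map = NULL) {
  if (inherits(synonym_map, "essential_set")) synonym_map <- synonym_map$synonym_map
  x <- toupper(trimws(genes))
  if (!is.null(synonym_map)) {
    hit <- match(x, names(synonym_map))
    x[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  }
  x
}

#' @export
print.essential_set <- function(x, ...) {
  cat(sprintf("<essential_set> %d gene(s)\n", length(x$genes)))
  if (length(x$genes)) cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
                           if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Test membership in an essential set
#'
#' @param set An [essential_set()].
#' @param genes Character vector of identifiers (canonicalized before lookup).
#' @return Logical vector.
#' @export
is_essential <- function(set, genes) {
  stopifnot(inherits(set, "essential_set"))
  canonical_gene(genes, set$synonym_map) %in% set$genes
}

#' Map network interactors to expression probesets
#'
#' Each interactor is matched to array probesets through its UniProtKB
#' cross-references first and, only when that fails, through Ensembl — the
#' route actually taken is recorded in the `provenance` column. When several
#' probesets match one interactor, the probeset with the lowest aggregate
#' expression across samples is chosen (a conservative lower bound on the
#' transcription available to produce the protein); ties break
#' lexicographically on probeset id. Interactors with no usable match are
#' kept with provenance `"unmapped"`, never dropped silently.
#'
#' @param records Interaction records from [read_mitab()] (source of the
#'   per-interactor cross-references).
#' @param annotations Data frame with column `probeset_id` and at least one
#'   of `uniprot_acc`, `ensembl_id`.
#' @param expr Expression matrix from [read_expression_matrix()]; candidate
#'   probesets must be present among its rows.
#' @param aggregate How "lowest expression" is aggregated across samples:
#'   `"mean"` (default) or `"min"`.
#' @return A tibble with columns `interactor`, `probeset` (NA when
#'   unmapped) and `provenance` (`"uniprot"`, `"ensembl"` or `"unmapped"`),
#'   one row per distinct interactor.
#' @export
build_id_map <- function(records, annotations, expr,
                         aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  annotations <- as_tibble(annotations)
  if (!"probeset_id" %in% names(annotations)) {
    abort("annotation table must have a `probeset_id` column")
  }
  has_uni <- "uniprot_acc" %in% names(annotations)
  has_ens <- "ensembl_id" %in% names(annotations)
  if (!has_uni && !has_ens) {
    abort("annotation table must have `uniprot_acc` and/or `ensembl_id`")
  }
  agg_fun <- if (aggregate == "mean") rowMeans else function(m) apply(m, 1, min)
  expr_level <- stats::setNames(agg_fun(expr), rownames(expr))

  if (!nrow(records)) {
    return(tibble(interactor = character(), probeset = character(),
                  provenance = character()))
  }

  xref_tbl <- bind_rows(
    tibble(interactor = records$interactor_a, xrefs = records$xrefs_a),
    tibble(interactor = records$interactor_b, xrefs = records$xrefs_b)
  ) |>
    tidyr::unnest("xrefs") |>
    distinct(.data$interactor, .data$database, .data$accession)

  interactors <- sort(unique(c(records$interactor_a, records$interactor_b)))

  match_route <- function(dbs, ann_col) {
    if (!ann_col %in% names(annotations)) return(NULL)
    accs <- xref_tbl |> filter(.data$database %in% dbs)
    ann <- annotations |>
      filter(!is.na(.data[[ann_col]]), .data$probeset_id %in% rownames(expr)) |>
      select(probeset_id = "probeset_id", accession = dplyr::all_of(ann_col))
    dplyr::inner_join(accs, ann, by = "accession",
                      relationship = "many-to-many") |>
      distinct(.data$interactor, .data$probeset_id)
  }
  pick_lowest <- function(cand) {
    cand |>
      mutate(level = expr_level[.data$probeset_id]) |>
      arrange(.data$interactor, .data$level, .data$probeset_id) |>
      group_by(.data$interactor) |>
      dplyr::slice(1) |>
      ungroup()
  }

  uni <- match_route(c("uniprotkb", "uniprot", "uniprotkb/swiss-prot"), "uniprot_acc")
  uni <- if (is.null(uni) || !nrow(uni)) {
    tibble(interactor = character(), probeset_id = character())
  } else pick_lowest(uni)[, c("interactor", "probeset_id")]

  rest <- setdiff(interactors, uni$interactor)
  ens <- match_route(c("ensembl", "ensemblgenomes"), "ensembl_id")
  ens <- if (is.null(ens) || !nrow(ens)) {
    tibble(interactor = character(), probeset_id = character())
  } else {
    pick_lowest(filter(ens, .data$interactor %in% rest))[, c("interactor", "probeset_id")]
  }

  out <- tibble(interactor = interactors) |>
    left_join(mutate(uni, prov_u = "uniprot"), by = "interactor") |>
    left_join(mutate(ens, prov_e = "ensembl"), by = "interactor",
              suffix = c("_u", "_e")) |>
    mutate(
      probeset = dplyr::coalesce(.data$probeset_id_u, .data$probeset_id_e),
      provenance = dplyr::case_when(
        !is.na(.data$prov_u) ~ "uniprot",
        !is.na(.data$prov_e) ~ "ensembl",
        TRUE ~ "unmapped"
      )
    ) |>
    select("interactor", "probeset", "provenance")
  out
}

#' Write a centrality ranking as TSV
#'
#' Columns are `node`, `score`, `rank` and, when labels are supplied,
#' `essential` (0/1). Rank 1 is the highest score; ties order
#' lexicographically by node identifier so output is fully deterministic.
#' A commented header records the tool version and the method's parameters.
#'
#' @param scores A [centrality_scores] tibble.
#' @param path Output path.
#' @param essentials Optional [essential_set()] used to add the `essential`
#'   column.
#' @param extra_params Extra key/value pairs for the provenance header.
#' @return The path, invisibly.
#' @export
write_ranking <- function(scores, path, essentials = NULL, extra_params = list()) {
  if (!nrow(scores)) abort("cannot write an empty ranking")
  out <- ranked(scores)
  if (!is.null(essentials)) {
    out$essential <- as.integer(is_essential(essentials, out$node))
  }
  params <- c(
    list(method = attr(scores, "method") %||% "unknown"),
    attr(scores, "params") %||% list(),
    extra_params
  )
  write_tsv_with_header(out, path, params)
}

#' Read a ranking written by [write_ranking()]
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `node`, `score`, `rank` (and `essential`
#'   when present).
#' @export
read_ranking <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                              colClasses = NA, check.names = FALSE)) |>
    mutate(node = as.character(.data$node))
}
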
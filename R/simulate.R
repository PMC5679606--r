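#' Specification for a coupled synthetic fixture
#'
#' Describes one synthetic study condition: a scale-free-like PPI network
#' with degree-linked essentiality and an expression matrix whose profiles
#' are correlated along network edges. Defaults mirror the yeast setting the
#' package targets: ~2000 proteins at the density of the curated yeast
#' interactome (about 3 attachment edges per new node), an essential
#' fraction of 0.22 (the DEG essential share of the filtered DIP network),
#' and 36 expression samples (a typical metabolic-cycle time course).
#' The same seed always reproduces the same fixture byte for byte.
#'
#' @param n_nodes Number of proteins in the connected core (>= 1).
#' @param attachment_edges Preferential-attachment edges added per node
#'   (>= 0; 0 only with `n_nodes = 1`).
#' @param essential_fraction Target expected fraction of essential nodes,
#'   in (0, 1).
#' @param degree_bias Slope of the logistic essentiality model on
#'   log-degree (>= 0; 0 = essentiality independent of degree).
#' @param n_samples Expression samples per profile (>= 2).
#' @param edge_coexpr_boost Overall strength in \[0, 1\] of the shared
#'   per-edge latent factors; 0 means pure noise profiles. Loadings on edges
#'   incident to an essential node are twice those on other edges, so the
#'   boost also plants an essentiality signal in coexpression.
#' @param noise_sd Standard deviation of the per-profile Gaussian noise
#'   (> 0).
#' @param unmapped_fraction Fraction of nodes deliberately left without any
#'   annotation (provenance `"unmapped"`).
#' @param ensembl_fraction Fraction of nodes whose annotation lacks a
#'   UniProtKB accession so they exercise the Ensembl mapping route.
#' @param decoy_fraction Fraction of nodes given a second, higher-expressed
#'   decoy probeset to exercise the lowest-expression mapping rule.
#' @param n_satellites Number of 2–3-node satellite components appended to
#'   the interaction records (removed downstream by
#'   [filter_small_components()]).
#' @param n_foreign_records Cross-taxon interaction records appended so the
#'   taxon filter is exercised.
#' @param taxon Taxon id written for the in-taxon records.
#' @param seed Integer RNG seed.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_nodes = 2000, attachment_edges = 3,
                         essential_fraction = 0.22, degree_bias = 1,
                         n_samples = 36, edge_coexpr_boost = 0.6,
                         noise_sd = 1, unmapped_fraction = 0.01,
                         ensembl_fraction = 0.02, decoy_fraction = 0.02,
                         n_satellites = 3, n_foreign_records = 5,
                         taxon = 4932, seed = 1) {
  assert_scalar_number(n_nodes, "n_nodes", 1)
  assert_scalar_number(attachment_edges, "attachment_edges", 0)
  if (n_nodes > 1 && attachment_edges < 1) {
    abort("attachment_edges must be >= 1 when n_nodes > 1")
  }
  assert_scalar_number(essential_fraction, "essential_fraction", 1e-9, 1 - 1e-9)
  assert_scalar_number(degree_bias, "degree_bias", 0)
  assert_scalar_number(n_samples, "n_samples", 2)
  assert_scalar_number(edge_coexpr_boost, "edge_coexpr_boost", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", 1e-12)
  assert_scalar_number(unmapped_fraction, "unmapped_fraction", 0, 1)
  assert_scalar_number(ensembl_fraction, "ensembl_fraction", 0, 1)
  assert_scalar_number(decoy_fraction, "decoy_fraction", 0, 1)
  assert_scalar_number(n_satellites, "n_satellites", 0)
  assert_scalar_number(n_foreign_records, "n_foreign_records", 0)
  assert_scalar_number(seed, "seed")
  structure(
    list(n_nodes = as.integer(n_nodes),
         attachment_edges = as.integer(attachment_edges),
         essential_fraction = essential_fraction,
         degree_bias = degree_bias,
         n_samples = as.integer(n_samples),
         edge_coexpr_boost = edge_coexpr_boost,
         noise_sd = noise_sd,
         unmapped_fraction = unmapped_fraction,
         ensembl_fraction = ensembl_fraction,
         decoy_fraction = decoy_fraction,
         n_satellites = as.integer(n_satellites),
         n_foreign_records = as.integer(n_foreign_records),
         taxon = as.integer(taxon),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Simulate a scale-free-like PPI network
#'
#' Barabási–Albert preferential attachment: each new node attaches
#' `attachment_edges` edges to existing nodes with probability proportional
#' to their degree, producing the heavy-tailed degree distribution and hub
#' structure characteristic of PPI networks. The graph is connected, simple
#' and undirected, with nodes named `P0001`, `P0002`, ...
#'
#' @param spec A [fixture_spec()].
#' @return An igraph network.
#' @export
simulate_ppi <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  g <- if (n == 1L || spec$attachment_edges == 0L) {
    igraph::make_empty_graph(n, directed = FALSE)
  } else {
    igraph::simplify(igraph::sample_pa(n, m = spec$attachment_edges,
                                       directed = FALSE))
  }
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n))
  g
}

#' Plant degree-linked essentiality on a network
#'
#' Each node is essential independently with probability
#' plogis(a + degree_bias * log(degree)); the intercept a is solved
#' numerically so the expected essential fraction equals
#' `essential_fraction`. The logistic acts on log-degree because
#' preferential-attachment degrees are heavy-tailed — a raw-degree logistic
#' saturates at the hubs and leaves no gradient across the bulk of the
#' network. `degree_bias = 0` makes essentiality independent of topology
#' (the null condition).
#'
#' @param net An igraph network.
#' @param spec A [fixture_spec()].
#' @return An [essential_set()] of node names.
#' @export
plant_essentiality <- function(net, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  deg <- pmax(igraph::degree(net), 1)
  eta <- spec$degree_bias * log(deg)
  f <- spec$essential_fraction
  a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - f,
                      lower = -50, upper = 50, tol = 1e-10)$root
  ess <- stats::rbinom(length(deg), 1, stats::plogis(a + eta)) == 1
  essential_set(node_names(net)[ess])
}

#' Simulate expression profiles coupled to the network
#'
#' One probeset per node. Each edge carries a latent Gaussian factor shared
#' by its two endpoints; a node's profile mixes independent Gaussian noise
#' with the unit-variance weighted sum of its incident edge factors. The
#' shared component's variance share is `edge_coexpr_boost` times a fixed
#' ceiling of 0.8 — at boost 0 the profiles are pure noise, so edge pairs
#' are no more correlated than non-edges — and edges incident to an
#' essential node carry twice the factor weight of other edges, planting an
#' essentiality signal that coexpression-biased centralities can exploit.
#' Because a node's shared component is split across its incident edges,
#' per-edge correlation naturally declines with degree, as it must when one
#' hub profile is shared among many partners.
#'
#' The returned id map is a bijection from nodes to probesets except for the
#' planted complications: `unmapped_fraction` of nodes get no annotation,
#' `ensembl_fraction` are reachable only through the Ensembl route, and
#' `decoy_fraction` receive a second probeset with strictly higher mean
#' expression, which the lowest-expression rule must reject.
#'
#' @param net An igraph network.
#' @param essentials An [essential_set()] from [plant_essentiality()].
#' @param spec A [fixture_spec()].
#' @return A list with elements `expr` (matrix, probesets x samples),
#'   `annotations` (tibble: `probeset_id`, `uniprot_acc`, `ensembl_id`),
#'   `idmap` (the expected mapping: `interactor`, `probeset`, `provenance`)
#'   and `node_meta` (per-node accession bookkeeping used by the MITAB
#'   writer).
#' @export
simulate_expression <- function(net, essentials, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  nodes <- node_names(net)
  n <- length(nodes)
  m <- spec$n_samples
  ess <- is_essential(essentials, nodes)
  names(ess) <- nodes

  profiles <- matrix(stats::rnorm(n * m), nrow = n)
  el <- edge_table(net)
  if (nrow(el) && spec$edge_coexpr_boost > 0) {
    # shared-variance share of a coupled profile: boost * max_share, split
    # across incident edges with weight 1 vs 2 (essential-incident edges)
    max_share <- 0.8
    lam <- 0.5 + 0.5 * (ess[el$node_a] | ess[el$node_b])
    factors <- matrix(stats::rnorm(nrow(el) * m), nrow = nrow(el))
    ia <- match(el$node_a, nodes)
    ib <- match(el$node_b, nodes)
    contrib <- factors * lam
    g_a <- rowsum(contrib, group = ia)
    g_b <- rowsum(contrib, group = ib)
    g <- matrix(0, nrow = n, ncol = m)
    g[as.integer(rownames(g_a)), ] <- g[as.integer(rownames(g_a)), ] + g_a
    g[as.integer(rownames(g_b)), ] <- g[as.integer(rownames(g_b)), ] + g_b
    s <- as.vector(rowsum(c(lam^2, lam^2), group = c(ia, ib)))
    s_all <- numeric(n)
    s_all[sort(unique(c(ia, ib)))] <- s
    share <- spec$edge_coexpr_boost * max_share
    coupled <- s_all > 0
    profiles[coupled, ] <- sqrt(1 - share) * profiles[coupled, ] +
      sqrt(share) * g[coupled, ] / sqrt(s_all[coupled])
  }
  profiles <- spec$noise_sd * profiles

  probesets <- sprintf("%05d_at", seq_len(n))
  rownames(profiles) <- probesets
  colnames(profiles) <- sprintf("S%02d", seq_len(m))

  # disjoint complication sets
  n_unmapped <- floor(spec$unmapped_fraction * n)
  n_ensembl <- floor(spec$ensembl_fraction * n)
  n_decoy <- floor(spec$decoy_fraction * n)
  shuffled <- sample(nodes)
  unmapped <- shuffled[seq_len(n_unmapped)]
  ensembl_only <- shuffled[n_unmapped + seq_len(n_ensembl)]
  decoy <- shuffled[n_unmapped + n_ensembl + seq_len(n_decoy)]

  uniprot <- sprintf("U%05d", seq_len(n))
  ensembl <- sprintf("Y%04dC", seq_len(n))
  names(uniprot) <- names(ensembl) <- nodes

  ann <- tibble(
    probeset_id = probesets,
    uniprot_acc = ifelse(nodes %in% ensembl_only, NA_character_, uniprot),
    ensembl_id = ensembl
  )
  ann <- ann[!(nodes %in% unmapped), ]

  expr <- profiles
  if (length(decoy)) {
    di <- match(decoy, nodes)
    decoy_ids <- sprintf("%05d_x_at", di)
    decoy_profiles <- profiles[di, , drop = FALSE] +
      abs(stats::rnorm(length(di), mean = 2, sd = 0.5))
    rownames(decoy_profiles) <- decoy_ids
    expr <- rbind(expr, decoy_profiles)
    ann <- bind_rows(ann, tibble(
      probeset_id = decoy_ids,
      uniprot_acc = ifelse(decoy %in% ensembl_only, NA_character_, uniprot[decoy]),
      ensembl_id = ensembl[decoy]
    ))
  }

  idmap <- tibble(
    interactor = nodes,
    probeset = ifelse(nodes %in% unmapped, NA_character_, probesets),
    provenance = dplyr::case_when(
      nodes %in% unmapped ~ "unmapped",
      nodes %in% ensembl_only ~ "ensembl",
      TRUE ~ "uniprot"
    )
  )

  list(
    expr = expr,
    annotations = ann,
    idmap = idmap,
    node_meta = tibble(
      node = nodes,
      uniprot_acc = ifelse(nodes %in% unmapped, NA_character_, uniprot),
      ensembl_id = ifelse(nodes %in% unmapped, NA_character_, ensembl)
    )
  )
}

#' Generate a complete coupled fixture
#'
#' Runs [simulate_ppi()], [plant_essentiality()] and
#' [simulate_expression()], then assembles MITAB-style interaction records:
#' the core network's edges, `n_satellites` small satellite components
#' (paths of 2–3 extra nodes, there to exercise small-component filtering)
#' and `n_foreign_records` cross-taxon records (filtered out by the taxon
#' filter). A manifest records the spec and the stage counts the pipeline
#' should reproduce.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `spec`, `records`, `net`, `essentials`,
#'   `expr`, `annotations`, `idmap`, `manifest`.
#' @export
simulate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  net <- simulate_ppi(spec)
  essentials <- plant_essentiality(net, spec)
  xp <- simulate_expression(net, essentials, spec)

  set.seed(spec$seed + 3L)
  el <- edge_table(net)
  meta <- xp$node_meta
  node_xrefs <- lapply(seq_len(nrow(meta)), function(i) {
    dbs <- c(if (!is.na(meta$uniprot_acc[i])) "uniprotkb",
             if (!is.na(meta$ensembl_id[i])) "ensembl")
    accs <- c(if (!is.na(meta$uniprot_acc[i])) meta$uniprot_acc[i],
              if (!is.na(meta$ensembl_id[i])) meta$ensembl_id[i])
    tibble(database = dbs %||% character(), accession = accs %||% character())
  })
  names(node_xrefs) <- meta$node
  xref_of <- function(nodes) unname(node_xrefs[nodes])
  records <- tibble(
    interactor_a = el$node_a, interactor_b = el$node_b,
    taxon_a = spec$taxon, taxon_b = spec$taxon,
    xrefs_a = xref_of(el$node_a), xrefs_b = xref_of(el$node_b)
  )

  if (spec$n_satellites > 0) {
    sat <- purrr::map_dfr(seq_len(spec$n_satellites), function(s) {
      size <- sample(2:3, 1)
      ids <- sprintf("PS%02d%d", s, seq_len(size))
      tibble(interactor_a = ids[-size], interactor_b = ids[-1],
             taxon_a = spec$taxon, taxon_b = spec$taxon)
    })
    sat$xrefs_a <- rep(list(tibble(database = character(), accession = character())),
                       nrow(sat))
    sat$xrefs_b <- sat$xrefs_a
    records <- bind_rows(records, sat)
  }
  if (spec$n_foreign_records > 0) {
    core <- sample(node_names(net), spec$n_foreign_records, replace = TRUE)
    foreign <- tibble(
      interactor_a = core,
      interactor_b = sprintf("FX%03d", seq_len(spec$n_foreign_records)),
      taxon_a = spec$taxon, taxon_b = 9606L,
      xrefs_a = xref_of(core),
      xrefs_b = rep(list(tibble(database = character(), accession = character())),
                    spec$n_foreign_records)
    )
    records <- bind_rows(records, foreign)
  }

  raw <- build_network(records[records$taxon_a == spec$taxon &
                                 records$taxon_b == spec$taxon, ])
  filtered <- filter_small_components(raw)
  manifest <- list(
    spec = unclass(spec),
    counts = list(
      n_records = nrow(records),
      n_nodes_taxon = igraph::vcount(raw),
      n_edges_taxon = igraph::ecount(raw),
      n_nodes_filtered = igraph::vcount(filtered),
      n_edges_filtered = igraph::ecount(filtered),
      n_essential = length(essentials$genes)
    )
  )
  list(spec = spec, records = records, net = net, essentials = essentials,
       expr = xp$expr, annotations = xp$annotations, idmap = xp$idmap,
       manifest = manifest)
}

#' Write a fixture to disk in the formats the readers consume
#'
#' Emits `interactions.mitab` (MITAB 2.5), `expression.tsv`,
#' `annotations.tsv`, `essentials.txt` and `manifest.yaml`. Reading the
#' files back through the package's readers reproduces the in-memory
#' objects.
#'
#' @param fixture A fixture from [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return The manifest (spec, stage counts, file paths), invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    mitab = file.path(dir, "interactions.mitab"),
    expression = file.path(dir, "expression.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    essentials = file.path(dir, "essentials.txt"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_mitab(fixture$records, paths$mitab)
  write_expression_matrix(fixture$expr, paths$expression)
  utils::write.table(fixture$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# synthetic essential-gene list", fixture$essentials$genes),
             paths$essentials)
  manifest <- c(fixture$manifest, list(paths = paths))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}
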
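#' Label network nodes by essentiality
#'
#' A node is labeled 1 exactly when its gene is in the essential set; every
#' other node — including genes of unknown status — is labeled 0. Treating
#' unknowns as non-essential gives a conservative estimate of ranking
#' success: no "unknown" class exists.
#'
#' @param net An igraph network.
#' @param essentials An [essential_set()].
#' @param node_to_gene Optional named character vector translating node
#'   identifiers to gene identifiers; by default nodes are gene identifiers.
#' @return A tibble with columns `node` and `essential` (integer 0/1).
#' @export
label_nodes <- function(net, essentials, node_to_gene = NULL) {
  nodes <- node_names(net)
  genes <- if (is.null(node_to_gene)) nodes else {
    out <- unname(node_to_gene[nodes])
    ifelse(is.na(out), nodes, out)
  }
  tibble(node = nodes, essential = as.integer(is_essential(essentials, genes)))
}

join_labels <- function(scores, labels) {
  lab <- as_tibble(labels)
  r <- ranked(scores) |> left_join(lab, by = "node")
  if (anyNA(r$essential)) abort("labels missing for some scored nodes")
  r
}

#' Confusion matrix at a top-k cutoff
#'
#' The k top-ranked nodes (deterministic tie-breaking, see [ranked()]) are
#' predicted positive; all others negative.
#'
#' @param scores A [centrality_scores] tibble.
#' @param labels Tibble from [label_nodes()].
#' @param k Number of predicted positives, 0 <= k <= number of nodes.
#' @return A one-row tibble with columns `k`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_top_k <- function(scores, labels, k) {
  r <- join_labels(scores, labels)
  n <- nrow(r)
  if (k < 0 || k > n) abort(sprintf("k must be in [0, %d]", n))
  pos <- sum(r$essential)
  tp <- if (k == 0) 0L else sum(r$essential[seq_len(k)])
  tibble(k = as.integer(k), tp = as.integer(tp), fp = as.integer(k - tp),
         fn = as.integer(pos - tp), tn = as.integer(n - k - (pos - tp)))
}

# cumulative tp/fp at each distinct-score threshold; tied scores advance
# together so tie ordering cannot inflate the curve
threshold_counts <- function(r) {
  grp <- cumsum(!duplicated(r$score))  # runs of equal score in ranked order
  tibble(
    tp = cumsum(r$essential)[!duplicated(grp, fromLast = TRUE)],
    np = which(!duplicated(grp, fromLast = TRUE))
  )
}

#' ROC curve and trapezoid AUC of an essentiality ranking
#'
#' Sweeps a threshold over the distinct score values from high to low; nodes
#' with tied scores cross the threshold together. Points are the standard
#' (FPR, TPR) pairs from (0, 0) to (1, 1), and the area under the curve is
#' computed by the trapezoid rule — which, with this tie handling, equals
#' the Mann–Whitney probability that a random essential node outranks a
#' random non-essential one (ties counted 1/2). A perfect ranking has
#' AUC 1; an inverted one AUC 0.
#'
#' @param scores A [centrality_scores] tibble.
#' @param labels Tibble from [label_nodes()]; both classes must be present.
#' @return An `eval_curve` tibble with columns `fpr`, `tpr` and attributes
#'   `kind = "roc"`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  r <- join_labels(scores, labels)
  P <- sum(r$essential)
  N <- nrow(r) - P
  if (P == 0 || N == 0) {
    abort("ROC needs at least one essential and one non-essential node")
  }
  th <- threshold_counts(r)
  tpr <- c(0, th$tp / P, 1)
  fpr <- c(0, (th$np - th$tp) / N, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    tibble(fpr = fpr, tpr = tpr),
    kind = "roc", auc = auc,
    class = c("eval_curve", class(tibble()))
  )
}

#' Precision–recall curve of an essentiality ranking
#'
#' (recall, precision) at every distinct-score threshold, high to low; the
#' zero-prediction point is omitted because precision is undefined there.
#'
#' @inheritParams roc_curve
#' @return An `eval_curve` tibble with columns `recall`, `precision` and
#'   attribute `kind = "pr"`.
#' @export
pr_curve <- function(scores, labels) {
  r <- join_labels(scores, labels)
  P <- sum(r$essential)
  if (P == 0) abort("precision-recall needs at least one essential node")
  th <- threshold_counts(r)
  structure(
    tibble(recall = th$tp / P, precision = th$tp / th$np),
    kind = "pr",
    class = c("eval_curve", class(tibble()))
  )
}

#' Area under an ROC curve
#'
#' @param curve An `eval_curve` from [roc_curve()].
#' @return The trapezoid AUC.
#' @export
curve_auc <- function(curve) {
  auc <- attr(curve, "auc")
  if (is.null(auc)) abort("curve has no AUC (only ROC curves do)")
  auc
}

#' @export
glance.eval_curve <- function(x, ...) {
  tibble(kind = attr(x, "kind"), n_points = nrow(x),
         auc = attr(x, "auc") %||% NA_real_)
}

#' @export
tidy.eval_curve <- function(x, ...) as_tibble(x)

# internal: AUC straight from scores/labels (same conventions as roc_curve)
auc_of <- function(scores, labels) curve_auc(roc_curve(scores, labels))

#' Essential-protein counts in the top k percent of rankings
#'
#' For each method and each percent p, counts the essential nodes among its
#' top floor(p * N / 100) ranked nodes (`hits`), and among those the
#' essentials found by no other method's top slice at the same p
#' (`unique_hits`) — the statistic behind per-method "unique discovery"
#' comparisons.
#'
#' @param scores_list Named list of [centrality_scores] over the same node
#'   universe.
#' @param labels Tibble from [label_nodes()].
#' @param percents Percent cutoffs in (0, 100].
#' @return A tibble with columns `method`, `percent`, `n_top`, `hits`,
#'   `unique_hits`.
#' @export
top_percent_hits <- function(scores_list, labels,
                             percents = c(1, 5, 10, 15, 20, 25)) {
  if (is.null(names(scores_list)) || any(!nzchar(names(scores_list)))) {
    abort("`scores_list` must be a named list")
  }
  if (any(percents <= 0 | percents > 100)) abort("percents must be in (0, 100]")
  slices <- function(p) {
    lapply(scores_list, function(sc) {
      r <- join_labels(sc, labels)
      k <- floor(p * nrow(r) / 100)
      r$node[seq_len(k)][r$essential[seq_len(k)] == 1]
    })
  }
  purrr::map_dfr(percents, function(p) {
    ess <- slices(p)
    purrr::imap_dfr(ess, function(found, m) {
      others <- unique(unlist(ess[setdiff(names(ess), m)]))
      n_unique <- length(setdiff(found, others))
      r <- join_labels(scores_list[[m]], labels)
      tibble(method = m, percent = p,
             n_top = floor(p * nrow(r) / 100),
             hits = length(found),
             unique_hits = n_unique)
    })
  })
}

#' Overlap of essentials found by two rankings' top slices
#'
#' Venn partition of the essential nodes detected in each ranking's top
#' `percent` slice.
#'
#' @param scores_a,scores_b [centrality_scores] over the same node universe.
#' @param labels Tibble from [label_nodes()].
#' @param percent Percent cutoff in (0, 100].
#' @return A one-row tibble with columns `percent`, `shared`, `only_a`,
#'   `only_b`.
#' @export
ranking_overlap <- function(scores_a, scores_b, labels, percent) {
  if (percent <= 0 || percent > 100) abort("percent must be in (0, 100]")
  top_ess <- function(sc) {
    r <- join_labels(sc, labels)
    k <- floor(percent * nrow(r) / 100)
    r$node[seq_len(k)][r$essential[seq_len(k)] == 1]
  }
  a <- top_ess(scores_a)
  b <- top_ess(scores_b)
  tibble(percent = percent,
         shared = length(intersect(a, b)),
         only_a = length(setdiff(a, b)),
         only_b = length(setdiff(b, a)))
}

#' AUC over a beta/omega parameter grid
#'
#' Computes the ROC AUC of the combined score for every (beta, omega) pair.
#' Because BDC is linear in beta (a mix of the per-node incident-coexpression
#' and incident-ECC sums) and the final score linear in omega, the
#' eigenvector term and the two incident sums are each computed once and
#' remixed per cell — every cell is exactly the score a direct
#' [diffslc()] call would produce.
#'
#' @param net An igraph network.
#' @param weights `edge_weights` covering all edges.
#' @param labels Tibble from [label_nodes()].
#' @param beta_grid,omega_grid Numeric grids within \[0, 1\].
#' @param normalization Passed to the score combination; see [diffslc()].
#' @param ec_mode Adjacency used for the eigenvector term; see [diffslc()].
#' @return A `sweep_result` tibble with columns `beta`, `omega`, `auc`.
#' @export
parameter_sweep <- function(net, weights, labels,
                            beta_grid = seq(0.05, 1, by = 0.05),
                            omega_grid = seq(0.05, 1, by = 0.05),
                            normalization = c("ec_max", "minmax"),
                            ec_mode = c("unweighted", "weighted")) {
  normalization <- match.arg(normalization)
  ec_mode <- match.arg(ec_mode)
  if (!length(beta_grid) || !length(omega_grid) ||
      any(beta_grid < 0 | beta_grid > 1) || any(omega_grid < 0 | omega_grid > 1)) {
    abort("beta/omega grids must be non-empty and within [0, 1]")
  }
  w <- check_weight_cover(net, weights)
  nm <- node_names(net)
  sum_incident <- function(ew) {
    s <- numeric(length(nm))
    names(s) <- nm
    inc <- tapply(c(ew, ew), c(w$node_a, w$node_b), sum)
    s[names(inc)] <- inc
    unname(s)
  }
  s_coexpr <- sum_incident(w$coexpr)
  s_ecc <- sum_incident(w$ecc)
  ec <- if (ec_mode == "unweighted") eigenvector_centrality(net) else
    eigenvector_centrality(net, weights = weights)
  ecs <- ec$score
  grid <- tidyr::expand_grid(beta = beta_grid, omega = omega_grid)
  auc <- purrr::pmap_dbl(grid, function(beta, omega) {
    bds <- beta * s_coexpr + (1 - beta) * s_ecc
    e <- ecs
    if (normalization == "minmax") {
      bds <- minmax(bds)
      e <- minmax(e)
    }
    sc <- new_centrality_scores(nm, omega * e + (1 - omega) * bds, "diffslc",
                                list(beta = beta, omega = omega))
    auc_of(sc, labels)
  })
  structure(mutate(grid, auc = auc),
            normalization = normalization, ec_mode = ec_mode,
            class = c("sweep_result", class(tibble())))
}

#' Bootstrap confidence interval for a ranking's AUC
#'
#' Nonparametric bootstrap over nodes (resampling score/label pairs).
#' Off by default in all pipelines; provided as a helper for exploratory
#' use.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return A one-row tibble with `auc`, `lower`, `upper`, `conf`, `n_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, conf = 0.95) {
  r <- join_labels(scores, labels)
  auc0 <- auc_of(scores, labels)
  boots <- purrr::map_dbl(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(r), replace = TRUE)
    rb <- r[idx, ]
    if (sum(rb$essential) == 0 || sum(rb$essential) == nrow(rb)) return(NA_real_)
    sc <- new_centrality_scores(paste0("n", seq_len(nrow(rb))), rb$score, "boot")
    auc_of(sc, tibble(node = sc$node, essential = rb$essential))
  })
  q <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble(auc = auc0, lower = unname(q[1]), upper = unname(q[2]),
         conf = conf, n_boot = n_boot)
}
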
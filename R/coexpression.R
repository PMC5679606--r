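#' Pearson correlation of two expression profiles
#'
#' Standard sample product-moment correlation (via [stats::cor()], the same
#' built-in a typical microarray workflow uses). Assumes approximately
#' normal profiles; estimates the linear component of association.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  check_profiles(x, y, forbid_constant = TRUE)
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation of two expression profiles
#'
#' Non-parametric, rank-based measure of monotone association. Ties receive
#' average ranks (expression data routinely has ties even though the
#' classical 1 - 6*sum(d^2)/(m(m^2-1)) formula assumes none).
#'
#' @inheritParams pearson_cor
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  check_profiles(x, y, forbid_constant = TRUE)
  stats::cor(x, y, method = "spearman")
}

check_profiles <- function(x, y, forbid_constant = FALSE) {
  if (length(x) != length(y)) abort("profiles must have equal length")
  if (length(x) < 2L) abort("profiles must have length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("profiles must be finite")
  if (forbid_constant && (stats::sd(x) == 0 || stats::sd(y) == 0)) {
    abort("correlation undefined for a constant profile")
  }
  invisible(TRUE)
}

# double-centered pairwise-distance matrix for the empirical dCov estimator
dcor_center <- function(x) {
  d <- abs(outer(x, x, "-"))
  sweep(sweep(d, 1, rowMeans(d)), 2, colMeans(d)) + mean(d)
}

#' Distance correlation of two expression profiles
#'
#' Empirical distance correlation dCor = dCov / sqrt(dVar(X) dVar(Y)),
#' computed with the standard univariate estimator: double-center each
#' profile's pairwise Euclidean distance matrix and average elementwise
#' products. Unlike Pearson or Spearman it detects non-monotone dependence,
#' is non-negative by construction, and is zero (in population) exactly when
#' the variables are independent. When either profile has zero distance
#' variance (a constant profile) the correlation is defined as 0.
#'
#' @inheritParams pearson_cor
#' @return Distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  check_profiles(x, y)
  A <- dcor_center(x)
  B <- dcor_center(y)
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(0)
  dcov2 <- mean(A * B)
  r2 <- dcov2 / sqrt(dvar_x * dvar_y)
  sqrt(max(r2, 0))
}

#' Coexpression weights for every network edge
#'
#' For each edge whose two endpoints both map (through `idmap`) to probesets
#' present in the expression matrix, computes the chosen coexpression of
#' their profiles. Edges with an unmapped endpoint, a probeset missing from
#' the matrix, or (for the correlation methods) a constant profile get the
#' missing-data value (default 0, so the ECC term still carries those edges
#' in the biased degree) and are flagged in the `mapped` column; the total is
#' reported in the `n_missing` attribute and an informational message.
#'
#' @param net An igraph network.
#' @param expr Expression matrix (probesets x samples).
#' @param idmap Tibble from [build_id_map()] (columns `interactor`,
#'   `probeset`, `provenance`).
#' @param method `"dcor"` (default; non-negative, the weight used by the
#'   biased degree centrality by default), `"pearson"`, or `"spearman"`.
#' @param missing_value Value assigned to edges without usable profiles.
#' @param abs_values Take absolute values of Pearson/Spearman weights.
#'   Negative correlations otherwise pass through unmodified and reduce the
#'   biased degree of the incident nodes.
#' @return A tibble with columns `node_a`, `node_b`, `coexpr`, `mapped`
#'   (logical), one row per edge; attribute `n_missing` counts edges at the
#'   missing-data default.
#' @export
edge_coexpression <- function(net, expr, idmap,
                              method = c("dcor", "pearson", "spearman"),
                              missing_value = 0, abs_values = FALSE) {
  method <- match.arg(method)
  et <- edge_table(net)
  probe_of <- stats::setNames(idmap$probeset, idmap$interactor)
  pa <- unname(probe_of[et$node_a])
  pb <- unname(probe_of[et$node_b])
  ok <- !is.na(pa) & !is.na(pb) & pa %in% rownames(expr) & pb %in% rownames(expr)

  vals <- rep(missing_value, nrow(et))
  if (any(ok)) {
    if (method == "dcor") {
      probes <- unique(c(pa[ok], pb[ok]))
      centered <- lapply(probes, function(p) dcor_center(expr[p, ]))
      names(centered) <- probes
      dvar <- vapply(centered, function(A) mean(A * A), numeric(1))
      vals[ok] <- map2_dbl(pa[ok], pb[ok], function(u, v) {
        if (dvar[[u]] <= 0 || dvar[[v]] <= 0) return(0)
        sqrt(max(mean(centered[[u]] * centered[[v]]) / sqrt(dvar[[u]] * dvar[[v]]), 0))
      })
    } else {
      Z <- expr
      if (method == "spearman") Z <- t(apply(Z, 1, rank))
      mu <- rowMeans(Z)
      s <- apply(Z, 1, stats::sd)
      const <- s == 0
      Zs <- (Z - mu) / ifelse(const, 1, s)
      usable <- ok & !const[pa] & !const[pb]
      ok <- usable
      m <- ncol(expr)
      vals[ok] <- rowSums(Zs[pa[ok], , drop = FALSE] * Zs[pb[ok], , drop = FALSE]) / (m - 1)
      vals[ok] <- pmin(pmax(vals[ok], -1), 1)
      if (abs_values) vals[ok] <- abs(vals[ok])
    }
  }
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    inform(sprintf(
      "edge_coexpression: %d of %d edge(s) lack usable profiles; set to %s",
      n_missing, nrow(et), format(missing_value)
    ))
  }
  structure(
    tibble(node_a = et$node_a, node_b = et$node_b,
           coexpr = vals, mapped = ok),
    n_missing = n_missing
  )
}

#' @importFrom purrr map2_dbl
NULL
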
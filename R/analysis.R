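#' Survey an ensemble: global measures and local descriptors per model
#'
#' One row per model: G-density, mean in-degree of non-GoE states,
#' `lambda_goe`, `lambda_all`, the four network Z-parameters, `s_bar`, and
#' (optionally) `lambda_random`. Deterministic given the ensemble and seeds.
#'
#' @param ens a `bn_ensemble` (or plain list of [boolean_network]s).
#' @param n_samples samples per model for `lambda_random`; 0 skips the
#'   column, `Inf` (or `exhaustive = TRUE`) uses oracle mode.
#' @param seed base seed for `lambda_random` (model i uses `seed + i`).
#' @param exhaustive oracle mode: every state once per model.
#' @param max_nodes passed to [build_stg].
#' @return data.frame (the measure table), one row per model.
#' @export
measure_ensemble <- function(ens, n_samples = 0L, seed = 1L,
                             exhaustive = FALSE, max_nodes = 20L) {
  models <- if (inherits(ens, "bn_ensemble")) ens$models else ens
  rows <- lapply(seq_along(models), function(i) {
    m <- global_measures(models[[i]], n_samples = 0L, max_nodes = max_nodes)
    row <- data.frame(model = i, g_density = m$g_density,
                      mean_indegree_non_goe = m$mean_indegree_non_goe,
                      lambda_goe = m$lambda_goe, lambda_all = m$lambda_all,
                      z_bar_max = m$z_bar_max, z_bar_min = m$z_bar_min,
                      z_bar_ave = m$z_bar_ave, z_bar_mid = m$z_bar_mid,
                      s_bar = m$s_bar)
    if (exhaustive || n_samples > 0L) {
      lr <- lambda_random(models[[i]],
                          n_samples = if (exhaustive) 0L else n_samples,
                          seed = seed + i, exhaustive = exhaustive)
      row$lambda_random <- lr$lambda_random
    }
    row
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (a thin wrapper over
#' [stats::cor]). Zero variance in either vector yields `NA` with a
#' warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Evaluate a local descriptor as a proxy for a global measure
#'
#' Models in the top-`q` fraction of the reference (global) measure are the
#' positive class. The descriptor enters as a score with its sign flipped —
#' lower descriptor values predict higher bushiness/convergence. AUROC is
#' computed by the rank statistic (ties averaged); AUPRC by step
#' integration of the precision-recall curve (average precision). The
#' relative-rank mapping selects the models in the best-`q` stratum of the
#' descriptor (lowest values) and reports their mean relative rank
#' `(rank - 0.5)/n` under the reference, where rank 1 is the best
#' (largest) reference value; 0.5 means no predictive power.
#'
#' @param scores descriptor values (lower = better predicted global
#'   structure).
#' @param reference global measure values (higher = positive).
#' @param q top fraction defining positives (default 0.05).
#' @return list with `auroc`, `auprc`, `n_pos`, `mean_relative_rank` and
#'   `prevalence`.
#' @export
proxy_evaluation <- function(scores, reference, q = 0.05) {
  stopifnot(length(scores) == length(reference), q > 0, q < 1)
  n <- length(scores)
  n_pos <- sum(reference >= stats::quantile(reference, 1 - q, type = 1))
  if (n_pos == 0L || n_pos == n)
    stop("q = ", q, " yields no usable positive/negative split")
  pos <- rank(-reference, ties.method = "first") <= n_pos
  s <- -scores                                   # high score = predicted positive
  r <- rank(s, ties.method = "average")
  auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * (n - n_pos))

  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  prec <- tp / seq_len(n)
  rec <- tp / n_pos
  auprc <- sum(prec * diff(c(0, rec)))           # average precision

  ref_rel_rank <- (rank(-reference, ties.method = "average") - 0.5) / n
  stratum <- rank(scores, ties.method = "first") <= max(1L, round(q * n))
  list(auroc = auroc, auprc = auprc, n_pos = n_pos,
       mean_relative_rank = mean(ref_rel_rank[stratum]),
       prevalence = n_pos / n)
}

#' Correlations between local descriptors and global measures
#'
#' Spearman correlations of each descriptor column with each global-measure
#' column of a measure table, plus the G-density vs `lambda_goe`
#' correlation.
#'
#' @param mt a measure table from [measure_ensemble].
#' @return list with `matrix` (descriptors x measures) and
#'   `g_density_vs_lambda_goe`.
#' @export
proxy_correlations <- function(mt) {
  descriptors <- c("z_bar_max", "z_bar_min", "z_bar_ave", "z_bar_mid",
                   "s_bar")
  measures <- c("g_density", "lambda_goe")
  m <- matrix(NA_real_, length(descriptors), length(measures),
              dimnames = list(descriptors, measures))
  for (d in descriptors) for (g in measures) {
    x <- mt[[d]]; y <- mt[[g]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) >= 3L && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0)
      m[d, g] <- spearman(x[keep], y[keep])
  }
  gl <- mt$g_density; lg <- mt$lambda_goe
  keep <- !is.na(gl) & !is.na(lg)
  gvl <- if (sum(keep) >= 3L && stats::sd(gl[keep]) > 0 &&
             stats::sd(lg[keep]) > 0) spearman(gl[keep], lg[keep])
         else NA_real_
  list(matrix = m, g_density_vs_lambda_goe = gvl)
}
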
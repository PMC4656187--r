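# Hierarchical bootstrap for clustered (embryo -> cell -> observation) data.

#' Hierarchical bootstrap confidence interval
#'
#' Resamples embryos with replacement, then cells within each chosen embryo
#' with replacement, keeping all observations of a chosen cell (time points
#' within a cell are strongly autocorrelated, so they are never resampled).
#' At each stage, n - 1 of the n available units are drawn: sampling n units
#' with replacement deflates the resampled variance of a mean by
#' (n - 1)/n, and the n - 1 draw is the standard correction that makes the
#' bootstrap variance match the sampling variance of the estimator.
#' Percentile interval at the requested level; deterministic given the
#' seed. A single-embryo input yields an interval reflecting only
#' within-embryo variation, with a warning attached.
#'
#' The default statistic is the (weighted) mean, for which a fast
#' sufficient-statistics path is used; any custom `statistic(values,
#' weights)` function is supported.
#'
#' @param values numeric observations.
#' @param embryo,cell cluster labels, one per observation.
#' @param weight optional non-negative weights.
#' @param statistic reduction `function(values, weights)`; `NULL` (default)
#'   means weighted mean.
#' @param n_boot bootstrap replicates (>= 100 recommended).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `estimate`, `ci_low`, `ci_high`, `n_boot`, `level`,
#'   `n_embryos` and `single_embryo` flag.
#' @export
hierarchical_bootstrap <- function(values, embryo, cell, weight = NULL,
                                   statistic = NULL, n_boot = 1000,
                                   level = 0.95, seed = 1) {
  n <- length(values)
  stopifnot(length(embryo) == n, length(cell) == n)
  if (is.null(weight)) weight <- rep(1, n)
  emb <- as.character(embryo)
  key <- paste(emb, as.character(cell), sep = "\r")
  uq <- unique(data.frame(e = emb, k = key, stringsAsFactors = FALSE))
  cell_of_emb <- split(uq$k, uq$e)
  embryos <- names(cell_of_emb)
  nE <- length(embryos)
  if (nE == 1) {
    warning("hierarchical_bootstrap: single embryo; interval reflects only within-embryo variation")
  }
  fast <- is.null(statistic)
  stat_fun <- if (fast) {
    function(v, w) sum(v * w) / sum(w)
  } else statistic
  estimate <- stat_fun(values, weight)
  if (fast) {
    wsum <- tapply(values * weight, key, sum)
    wtot <- tapply(weight, key, sum)
  } else {
    idx_of_cell <- split(seq_len(n), key)
  }
  alpha <- (1 - level) / 2
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      es <- embryos[sample.int(nE, max(nE - 1L, 1L), replace = TRUE)]
      cs <- unlist(lapply(es, function(e) {
        cc <- cell_of_emb[[e]]
        m <- max(length(cc) - 1L, 1L)
        cc[sample.int(length(cc), m, replace = TRUE)]
      }), use.names = FALSE)
      if (fast) {
        sum(wsum[cs]) / sum(wtot[cs])
      } else {
        ii <- unlist(idx_of_cell[cs], use.names = FALSE)
        stat_fun(values[ii], weight[ii])
      }
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(estimate = unname(estimate), ci_low = qs[1], ci_high = qs[2],
       n_boot = n_boot, level = level, n_embryos = nE,
       single_embryo = nE == 1)
}
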
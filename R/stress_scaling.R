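# Hysteretic-damping scale factors and relative stress fold-changes.
#
# The hysteretic damping law eps(t) = (sigma/G0)*(t/t0)^(2*delta/pi)
# (creep response to a unit stress step) implies, for sinusoidal loading,
# E(omega) = G0 * Gamma(1 - 2*delta/pi) * (omega*t0)^(2*delta/pi).
# Fitting (G0, t0) to (omega, delta, E) triples lets external relative
# (unscaled) stress measurements Delta = sigma/(G0*t0^(2*delta/pi)) from
# ablation recoil be converted into stress fold-changes between stages.

#' Fit the hysteretic-damping scale factors
#'
#' Least squares in log space: with `p = 2*delta/pi`,
#' `log E - log Gamma(1 - p) - p*log(omega) = log G0 + p*log t0`,
#' which is linear in `(log G0, log t0)` and solved exactly. Relative
#' residuals are equalised by the log transform. With a single distinct
#' loss angle the two parameters are not jointly identifiable.
#'
#' @param samples data.frame with columns `omega` (rad/s), `delta`
#'   (radians, each < pi/2) and `E` (stiffness).
#' @return list of class `scale_factors` with `G0`, `t0`, `fit_residual`
#'   (relative RMS in log space), `covariance` (2x2, for (G0, t0) by the
#'   delta method) and `log_covariance` (for (log G0, log t0)).
#' @export
fit_scale_factors <- function(samples) {
  stopifnot(all(c("omega", "delta", "E") %in% names(samples)))
  if (nrow(samples) < 2) stop("fit_scale_factors: need at least two samples")
  if (any(samples$delta >= pi / 2)) {
    stop("fit_scale_factors: delta >= pi/2 outside the hysteretic-damping domain")
  }
  if (any(samples$delta < 0) || any(samples$omega <= 0) || any(samples$E <= 0)) {
    stop("fit_scale_factors: need delta >= 0, omega > 0, E > 0")
  }
  p <- 2 * samples$delta / pi
  if (diff(range(p)) < 1e-8) {
    stop("fit_scale_factors: all loss angles equal; G0 and t0 not jointly identifiable")
  }
  y <- log(samples$E) - lgamma(1 - p) - p * log(samples$omega)
  fit <- stats::lm(y ~ p)
  co <- stats::coef(fit)
  logG0 <- unname(co[1]); logt0 <- unname(co[2])
  V <- suppressWarnings(stats::vcov(fit))   # near-perfect fits are fine here
  if (any(!is.finite(V))) V <- matrix(0, 2, 2)
  J <- diag(c(exp(logG0), exp(logt0)))
  structure(list(
    G0 = exp(logG0), t0 = exp(logt0),
    fit_residual = sqrt(mean(stats::residuals(fit)^2)),
    covariance = J %*% V %*% J,
    log_covariance = unname(V),
    n_samples = nrow(samples)
  ), class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("<scale_factors> G0 = %.4g, t0 = %.4g s (rel. log-residual %.2g, n = %d)\n",
              x$G0, x$t0, x$fit_residual, x$n_samples))
  invisible(x)
}

#' Stress fold-change between developmental stages
#'
#' Combines relative (unscaled) ablation stresses with the fitted time
#' scale: `sigma_late/sigma_early = (Delta_late/Delta_early) *
#' t0^(2*(delta_late - delta_early)/pi)`. G0 cancels exactly. Uncertainty
#' is propagated to first order from the Delta standard errors, the fit
#' covariance of `log t0` and (if supplied) the loss-angle standard errors.
#'
#' @param delta_early,delta_late loss angles at the two stages, radians.
#' @param Delta_early,Delta_late relative unscaled stresses (> 0).
#' @param factors a `scale_factors` fit from [fit_scale_factors()].
#' @param se_Delta_early,se_Delta_late,se_delta_early,se_delta_late optional
#'   standard errors for the inputs.
#' @return list with `fold_change` and `se`.
#' @export
relative_stress <- function(delta_early, delta_late, Delta_early, Delta_late,
                            factors, se_Delta_early = 0, se_Delta_late = 0,
                            se_delta_early = 0, se_delta_late = 0) {
  stopifnot(inherits(factors, "scale_factors"),
            Delta_early > 0, Delta_late > 0)
  dd <- 2 * (delta_late - delta_early) / pi
  fold <- (Delta_late / Delta_early) * factors$t0^dd
  logt0 <- log(factors$t0)
  var_logt0 <- factors$log_covariance[2, 2]
  var_log_fold <- (se_Delta_late / Delta_late)^2 +
    (se_Delta_early / Delta_early)^2 +
    dd^2 * var_logt0 +
    (2 * logt0 / pi)^2 * (se_delta_late^2 + se_delta_early^2)
  list(fold_change = fold, se = fold * sqrt(var_log_fold))
}

#' Stage-compared stress table for a set of sites
#'
#' Convenience wrapper producing one row per ablation site (e.g. medial,
#' junctional): relative stiffness (if both stage stiffnesses are given)
#' and relative stress with standard errors.
#'
#' @param inputs data.frame with columns `site`, `Delta_early`,
#'   `Delta_late`, `delta_early`, `delta_late` and optional `se_*` columns.
#' @param factors a `scale_factors` fit.
#' @return data.frame with `site`, `relative_stress`, `se`.
#' @export
stress_table <- function(inputs, factors) {
  need <- c("site", "Delta_early", "Delta_late", "delta_early", "delta_late")
  stopifnot(all(need %in% names(inputs)))
  g <- function(col) if (col %in% names(inputs)) inputs[[col]] else 0
  out <- lapply(seq_len(nrow(inputs)), function(i) {
    rs <- relative_stress(inputs$delta_early[i], inputs$delta_late[i],
                          inputs$Delta_early[i], inputs$Delta_late[i],
                          factors,
                          se_Delta_early = g("se_Delta_early")[min(i, length(g("se_Delta_early")))],
                          se_Delta_late = g("se_Delta_late")[min(i, length(g("se_Delta_late")))],
                          se_delta_early = g("se_delta_early")[min(i, length(g("se_delta_early")))],
                          se_delta_late = g("se_delta_late")[min(i, length(g("se_delta_late")))])
    data.frame(site = inputs$site[i], relative_stress = rs$fold_change,
               se = rs$se)
  })
  do.call(rbind, out)
}
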
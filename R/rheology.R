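# Contractile linear viscoelastic (active Maxwell) constitutive model.
#
# The constitutive equation sigma + tau_R*dsigma/dt = tau_bar*kappa*c_m
# + tau_R*kappa*deps/dt relates stress to rescaled myosin (the active
# forcing) and strain rate. For sinusoidal inputs
#   eps   = eps0*cos(omega*t),
#   c_m   = c0*cos(omega*t + delta_m),
# the steady-state stress is sigma = E*eps0*cos(omega*t + delta) with
# closed-form stiffness E and loss angle delta evaluated below; omega_bar =
# omega*tau_R and tau_bar = tau_R/tau_m are the dimensionless frequency and
# timescale ratio. kappa and tau_R only set the stress and time units.

#' Effective stiffness of the contractile Maxwell model
#'
#' `E = (kappa/eps0) * sqrt((c0^2*tb^2*cos(dm)^2 +
#' (eps0*wb + c0*tb*sin(dm))^2) / (1 + wb^2))`.
#' Components with `eps0` below `floor` are undefined (stress with no
#' strain) and returned as NA, never infinite.
#'
#' @param eps0 strain amplitude (dimensionless).
#' @param c0 myosin amplitude (dimensionless).
#' @param delta_m strain-to-myosin lag, radians (myosin minus strain).
#' @param omega_bar dimensionless frequency `omega * tau_R`.
#' @param tau_bar timescale ratio `tau_R / tau_m`.
#' @param kappa bulk elastic modulus (stress units).
#' @param floor strain amplitudes below this are masked.
#' @return stiffness in units of `kappa` (vectorised).
#' @export
stiffness <- function(eps0, c0, delta_m, omega_bar, tau_bar = 1, kappa = 1,
                      floor = 1e-6) {
  num <- c0^2 * tau_bar^2 * cos(delta_m)^2 +
    (eps0 * omega_bar + c0 * tau_bar * sin(delta_m))^2
  E <- (kappa / eps0) * sqrt(num / (1 + omega_bar^2))
  E[eps0 < floor] <- NA_real_
  E
}

#' Loss angle of the contractile Maxwell model
#'
#' Default (`"literal"`) mode evaluates the single-argument arctangent
#' `delta = arctan[(eps0*wb - c0*tb*wb*cos(dm) + c0*tb*sin(dm)) /
#' (eps0*wb^2 + c0*tb*cos(dm) + c0*tb*wb*sin(dm))]`, range (-pi/2, pi/2);
#' `"quadrature"` applies atan2 to the same numerator and denominator,
#' resolving the quadrant (range (-pi, pi]), which matches the phase of the
#' steady-state stress of the constitutive equation even when the
#' denominator turns negative (active regime).
#'
#' @inheritParams stiffness
#' @param mode `"literal"` or `"quadrature"`.
#' @return loss angle in radians (vectorised); NA where numerator and
#'   denominator both vanish.
#' @export
loss_angle <- function(eps0, c0, delta_m, omega_bar, tau_bar = 1,
                       mode = c("literal", "quadrature")) {
  mode <- match.arg(mode)
  num <- eps0 * omega_bar - c0 * tau_bar * omega_bar * cos(delta_m) +
    c0 * tau_bar * sin(delta_m)
  den <- eps0 * omega_bar^2 + c0 * tau_bar * cos(delta_m) +
    c0 * tau_bar * omega_bar * sin(delta_m)
  d <- if (mode == "literal") atan(num / den) else atan2(num, den)
  d[num == 0 & den == 0] <- NA_real_
  d
}

#' Loss tangent
#' @inheritParams loss_angle
#' @return `tan(loss_angle(...))`.
#' @export
loss_tangent <- function(eps0, c0, delta_m, omega_bar, tau_bar = 1,
                         mode = "literal") {
  tan(loss_angle(eps0, c0, delta_m, omega_bar, tau_bar, mode))
}

#' Stress time series by exact integration of the constitutive equation
#'
#' Integrates `sigma + tau_R*sigma' = tau_bar*kappa*c_m + tau_R*kappa*eps'`
#' with an exact exponential integrator per step, treating the forcing as
#' piecewise linear. The strain rate defaults to central finite differences
#' of `strain`.
#'
#' @param strain,myosin series on a uniform grid, NA-free.
#' @param dt sampling interval, seconds.
#' @param tau_R stress relaxation time, seconds.
#' @param tau_bar timescale ratio.
#' @param kappa bulk modulus (stress scale).
#' @param sigma0 initial stress.
#' @param strain_rate optional strain-rate series (overrides the finite
#'   difference).
#' @return stress series (same length as the inputs).
#' @export
stress_series <- function(strain, myosin, dt, tau_R = 1, tau_bar = 1,
                          kappa = 1, sigma0 = 0, strain_rate = NULL) {
  stopifnot(length(strain) == length(myosin))
  if (anyNA(strain) || anyNA(myosin)) stop("stress_series: NA in input")
  n <- length(strain)
  eps_dot <- if (is.null(strain_rate)) fd_derivative(strain, dt) else strain_rate
  f <- tau_bar * kappa * myosin + tau_R * kappa * eps_dot
  a <- exp(-dt / tau_R)
  # sigma_{k+1} = a*sigma_k + (1-a)*f_k + (f_{k+1}-f_k)*(1 - (tau_R/dt)*(1-a))
  g <- (1 - a) * f[-n] + (f[-1] - f[-n]) * (1 - (tau_R / dt) * (1 - a))
  sig <- stats::filter(g, a, method = "recursive", init = sigma0)
  c(sigma0, as.numeric(sig))
}

#' Bin spectral components into material states
#'
#' Evaluates stiffness and loss angle for every (cell, frequency, time)
#' component, then averages within `material_bin`-second bins of analysis
#' time across frequencies and cells. Frequency averaging is
#' amplitude-weighted by default (`w = strain_amp * myosin_amp`), which
#' down-weights empty frequency bins; set `freq_weighting = "uniform"` in
#' the config for plain means. Loss angles are averaged as angles and the
#' tangent taken afterwards (a single component near pi/2 would otherwise
#' dominate a mean of tangents); `angle_average = "tangent"` averages
#' tangents directly. Confidence intervals are hierarchical-bootstrap
#' percentiles over (embryo, cell) clusters.
#'
#' @param components table from [spectral_components()].
#' @param config an [pipeline_config()] list (`tau_bar`, `tau_R`, `kappa`,
#'   `material_bin`, weighting and averaging modes, bootstrap settings).
#' @param ci compute bootstrap confidence intervals (default TRUE).
#' @return `data.table` with one row per time bin: `t` (bin centre),
#'   `stiffness`, `loss_angle`, `loss_tangent`, CI bounds for stiffness and
#'   loss tangent, and `n_components`. The unbinned per-component surface is
#'   attached as `attr(, "surface")`.
#' @export
material_state <- function(components, config = pipeline_config(), ci = TRUE) {
  stopifnot(nrow(components) > 0)
  comp <- data.table::copy(components)
  if (!is.null(config$component_floor) && config$component_floor > 0) {
    # noise-floor selection: the median amplitude over the frequency grid at
    # one window time tracks the noise floor (most grid frequencies carry no
    # signal); components must clear it in both channels
    comp[, `:=`(med_s = stats::median(strain_amp),
                med_m = stats::median(myosin_amp)),
         by = c("embryo_id", "cell_id", "t")]
    comp <- comp[comp$strain_amp > config$component_floor * comp$med_s &
                   comp$myosin_amp > config$component_floor * comp$med_m, ]
    comp$med_s <- comp$med_m <- NULL
    if (!nrow(comp)) stop("material_state: no component clears the noise floor")
  }
  comp$omega_bar <- 2 * pi * comp$freq * config$tau_R
  comp$E <- stiffness(comp$strain_amp, comp$myosin_amp, comp$lag,
                      comp$omega_bar, config$tau_bar, config$kappa,
                      floor = config$amplitude_floor)
  comp$delta <- loss_angle(comp$strain_amp, comp$myosin_amp, comp$lag,
                           comp$omega_bar, config$tau_bar,
                           mode = config$loss_angle_mode)
  comp$w <- if (config$freq_weighting == "amplitude")
    comp$strain_amp * comp$myosin_amp else 1
  comp$bin <- base::floor(comp$t / config$material_bin) * config$material_bin +
    config$material_bin / 2
  ok <- stats::complete.cases(comp[, c("E", "delta", "w")])
  surface <- comp
  comp <- comp[ok]
  if (ci && length(unique(comp$embryo_id)) == 1) {
    warning("material_state: single embryo; bootstrap intervals reflect only within-embryo variation")
  }
  agg <- comp[, {
    E_hat <- stats::weighted.mean(E, w)
    d_hat <- if (config$angle_average == "angle")
      stats::weighted.mean(delta, w) else atan(stats::weighted.mean(tan(delta), w))
    res <- list(stiffness = E_hat, loss_angle = d_hat,
                loss_tangent = tan(d_hat), n_components = .N,
                stiffness_lo = NA_real_, stiffness_hi = NA_real_,
                tan_delta_lo = NA_real_, tan_delta_hi = NA_real_)
    if (ci && .N >= 2) {
      bE <- suppressWarnings(
        hierarchical_bootstrap(E, embryo_id, cell_id, weight = w,
                               n_boot = config$bootstrap_n,
                               level = config$ci_level,
                               seed = bin_seed(config$seed, .GRP)))
      bd <- suppressWarnings(
        hierarchical_bootstrap(delta, embryo_id, cell_id, weight = w,
                               n_boot = config$bootstrap_n,
                               level = config$ci_level,
                               seed = bin_seed(config$seed, .GRP) + 1L))
      res$stiffness_lo <- bE$ci_low; res$stiffness_hi <- bE$ci_high
      res$tan_delta_lo <- tan(bd$ci_low); res$tan_delta_hi <- tan(bd$ci_high)
    }
    res
  }, by = "bin"]
  data.table::setnames(agg, "bin", "t")
  data.table::setorderv(agg, "t")
  attr(agg, "surface") <- surface
  agg
}

# deterministic per-bin seeds derived from the config seed
bin_seed <- function(seed, grp) {
  base <- if (is.null(seed)) 77003L else as.integer(seed)
  (base * 1009L + as.integer(grp) * 2L) %% 2147483647L
}

#' Sensitivity scan over the timescale ratio
#'
#' Re-evaluates the binned material state for each value of `tau_bar` on a
#' grid within the physiological range, keeping everything else fixed.
#'
#' @param components table from [spectral_components()].
#' @param config an [pipeline_config()] list.
#' @param tau_bar_grid values to scan (default 7 log-spaced points over the
#'   configured range).
#' @return `data.table` with columns `tau_bar`, `t`, `stiffness`,
#'   `loss_angle`, `loss_tangent`, `n_components`.
#' @export
tau_scan <- function(components, config = pipeline_config(),
                     tau_bar_grid = NULL) {
  if (is.null(tau_bar_grid)) {
    tau_bar_grid <- 10^seq(log10(config$tau_bar_range[1]),
                           log10(config$tau_bar_range[2]), length.out = 7)
  }
  rng <- config$tau_bar_range
  if (any(tau_bar_grid < rng[1] - 1e-9 | tau_bar_grid > rng[2] + 1e-9)) {
    stop("tau_scan: grid outside the configured tau_bar range")
  }
  out <- lapply(tau_bar_grid, function(tb) {
    cfg <- config; cfg$tau_bar <- tb
    ms <- material_state(components, cfg, ci = FALSE)
    ms$tau_bar <- tb
    ms[, c("tau_bar", "t", "stiffness", "loss_angle", "loss_tangent",
           "n_components")]
  })
  data.table::rbindlist(out)
}

utils::globalVariables(c("E", "delta", "w", "embryo_id", "cell_id", ".GRP",
                         "med_s", "med_m", "strain_amp", "myosin_amp"))
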
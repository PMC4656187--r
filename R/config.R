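#' Pipeline configuration
#'
#' Central container for every tunable parameter of the analysis chain, with
#' defaults matching the standard study conditions: 10-s sampling, a 6-min
#' (360-s) trend window, a 1--12.5 mHz passband, 0.195-mHz frequency
#' resolution, 100-s material bins and 600-s hysteresis-loop bins.
#'
#' @param trend_window boxcar trend window, seconds.
#' @param band_low,band_high bandpass edges, Hz.
#' @param freq_resolution spectral grid step, Hz.
#' @param fir_taps FIR bandpass length (odd number of taps). The default 201
#'   taps at 0.1 Hz sampling meet the response requirements (forward-backward
#'   DC rejection below 1e-3, unity passband gain at 5 mHz, stopband below
#'   1e-2 at 25 mHz).
#' @param filter_passes 2 for forward-backward filtering (default), 1 for a
#'   single centred pass of the symmetric kernel.
#' @param trend_refine iterations of oscillation-corrected trend refinement
#'   (0 = plain boxcar).
#' @param envelope_mode `"divide"` (default; gain-invariant rescaling by the
#'   lower envelope) or `"subtract"` (envelope subtraction only).
#' @param tau_bar ratio of stress-relaxation to active-force timescales.
#' @param tau_bar_range admissible physiological range for `tau_bar`.
#' @param tau_R stress relaxation time, seconds (free time scale).
#' @param kappa bulk cell elastic modulus (free stress scale).
#' @param material_bin material-state bin width, seconds.
#' @param loop_bin hysteresis-loop developmental bin width, seconds.
#' @param n_phase_bins phase bins per hysteresis loop.
#' @param bootstrap_n bootstrap replicates for confidence intervals.
#' @param ci_level confidence level for bootstrap intervals.
#' @param morlet_omega0 Morlet wavelet centre frequency (dimensionless).
#' @param coherence_time_smooth coherence smoothing window, in oscillation
#'   periods at each scale.
#' @param coherence_scale_band relative frequency band for cross-scale
#'   smoothing: scales with frequency in `[f/band, f*band]` are averaged.
#' @param freq_weighting `"amplitude"` (weights `strain_amp * myosin_amp`,
#'   default) or `"uniform"` frequency averaging in [material_state()].
#' @param loss_angle_mode `"literal"` (single-argument arctangent, default) or
#'   `"quadrature"` (two-argument, quadrant-resolving).
#' @param angle_average `"angle"` (average loss angles, take tan afterwards;
#'   default) or `"tangent"` (average tangents directly).
#' @param amplitude_floor strain amplitudes below this are masked as
#'   undefined rather than divided by.
#' @param component_floor noise-floor selection for material averaging:
#'   components are kept only where both amplitudes exceed this multiple of
#'   the cell's median amplitude over the frequency grid at the same window
#'   time (the median tracks the noise floor, since most grid frequencies
#'   hold no signal). 0 disables selection.
#' @param fluct_cycle_range admissible myosin cycle lengths, seconds.
#' @param fluct_threshold threshold on amplitude x frequency
#'   (rescaled-myosin units x cycles/min) above which myosin counts as
#'   fluctuating.
#' @param peak_min_separation minimum separation between myosin peaks,
#'   seconds.
#' @param seed integer seed for stochastic stages (`NULL` = leave RNG alone).
#'
#' @return a list of class `oscrheo_config`.
#' @export
pipeline_config <- function(trend_window = 360,
                            band_low = 1e-3,
                            band_high = 12.5e-3,
                            freq_resolution = 0.195e-3,
                            fir_taps = 201,
                            filter_passes = 2,
                            trend_refine = 2,
                            envelope_mode = c("divide", "subtract"),
                            tau_bar = 1,
                            tau_bar_range = c(0.1, 100),
                            tau_R = 1,
                            kappa = 1,
                            material_bin = 100,
                            loop_bin = 600,
                            n_phase_bins = 24,
                            bootstrap_n = 1000,
                            ci_level = 0.95,
                            morlet_omega0 = 6,
                            coherence_time_smooth = 3,
                            coherence_scale_band = 1.15,
                            freq_weighting = c("amplitude", "uniform"),
                            loss_angle_mode = c("literal", "quadrature"),
                            angle_average = c("angle", "tangent"),
                            amplitude_floor = 1e-6,
                            component_floor = 1.5,
                            fluct_cycle_range = c(60, 360),
                            fluct_threshold = 0.3,
                            peak_min_separation = 60,
                            seed = NULL) {
  cfg <- list(
    trend_window = trend_window, band_low = band_low, band_high = band_high,
    freq_resolution = freq_resolution, fir_taps = as.integer(fir_taps),
    filter_passes = as.integer(filter_passes),
    trend_refine = as.integer(trend_refine),
    envelope_mode = match.arg(envelope_mode),
    tau_bar = tau_bar, tau_bar_range = tau_bar_range, tau_R = tau_R,
    kappa = kappa, material_bin = material_bin, loop_bin = loop_bin,
    n_phase_bins = as.integer(n_phase_bins),
    bootstrap_n = as.integer(bootstrap_n), ci_level = ci_level,
    morlet_omega0 = morlet_omega0,
    coherence_time_smooth = coherence_time_smooth,
    coherence_scale_band = coherence_scale_band,
    freq_weighting = match.arg(freq_weighting),
    loss_angle_mode = match.arg(loss_angle_mode),
    angle_average = match.arg(angle_average),
    amplitude_floor = amplitude_floor,
    component_floor = component_floor,
    fluct_cycle_range = fluct_cycle_range,
    fluct_threshold = fluct_threshold,
    peak_min_separation = peak_min_separation,
    seed = seed
  )
  class(cfg) <- "oscrheo_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$band_low > 0, cfg$band_low < cfg$band_high,
    cfg$trend_window > 0, cfg$freq_resolution > 0,
    cfg$fir_taps %% 2 == 1, cfg$fir_taps >= 3,
    cfg$filter_passes %in% c(1L, 2L),
    cfg$tau_bar_range[1] >= 0.1 - 1e-12, cfg$tau_bar_range[2] <= 100 + 1e-12,
    cfg$tau_R > 0, cfg$kappa > 0, cfg$material_bin > 0,
    cfg$n_phase_bins >= 3, cfg$bootstrap_n >= 1,
    cfg$ci_level > 0, cfg$ci_level < 1
  )
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return an `oscrheo_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("read_config: unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.oscrheo_config <- function(x, ...) {
  cat("<oscrheo_config>\n")
  cat(sprintf("  passband: [%g, %g] mHz; trend window %g s; FIR %d taps x%d\n",
              x$band_low * 1e3, x$band_high * 1e3, x$trend_window,
              x$fir_taps, x$filter_passes))
  cat(sprintf("  tau_bar = %g (scan range [%g, %g]); tau_R = %g s; kappa = %g\n",
              x$tau_bar, x$tau_bar_range[1], x$tau_bar_range[2], x$tau_R, x$kappa))
  cat(sprintf("  bins: material %g s, loops %g s x %d phase bins; bootstrap n = %d\n",
              x$material_bin, x$loop_bin, x$n_phase_bins, x$bootstrap_n))
  invisible(x)
}
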
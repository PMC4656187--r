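#' oscrheo: rheology of pulsatile epithelial cells
#'
#' Non-invasive inference of effective mechanical properties from
#' tracked-cell fluorescence time series: apical-area and medial-myosin
#' signals become dimensionless strain and rescaled myosin, are decomposed
#' into time-resolved frequency components, and evaluated through a
#' contractile linear viscoelastic constitutive model to yield effective
#' stiffness and loss tangent over developmental time, with
#' hysteretic-damping scale factors converting external relative-stress
#' measurements into stress fold-changes.
#'
#' @keywords internal
#' @import data.table
"_PACKAGE"

#' Run the full analysis chain on a dataset
#'
#' preprocess -> spectral decomposition -> material state (plus, optionally,
#' the timescale-ratio scan and hysteresis loops).
#'
#' @param ds an [embryo_dataset()].
#' @param config an [pipeline_config()] list.
#' @param scan also run [tau_scan()] (default FALSE).
#' @param loops also run [hysteresis_loops()] (default FALSE).
#' @param ci bootstrap confidence intervals on the material state.
#' @return list with `processed`, `components`, `material` and optionally
#'   `tau_scan`, `loops`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), scan = FALSE,
                         loops = FALSE, ci = TRUE) {
  proc <- preprocess_dataset(ds, config)
  if (!nrow(proc)) stop("run_pipeline: no track survived preprocessing")
  comps <- spectral_components(proc, config)
  mat <- material_state(comps, config, ci = ci)
  out <- list(processed = proc, components = comps, material = mat)
  if (scan) out$tau_scan <- tau_scan(comps, config)
  if (loops) out$loops <- hysteresis_loops(proc, config)
  out
}

#' Evaluate the constitutive closed forms on ground truth
#'
#' Direct evaluation of the stiffness and loss-angle formulas on a
#' ground-truth table (as emitted by [generate_embryo()]), binned on the
#' same time grid as [material_state()] — the reference against which the
#' pipeline estimate is scored in parameter-recovery experiments.
#'
#' @param truth ground-truth `data.table` with `time_s`, `strain_amp`,
#'   `myosin_amp`, `lag`, `freq_hz`.
#' @param config an [pipeline_config()] list.
#' @return `data.table` with `t` (bin centre), `stiffness`, `loss_angle`,
#'   `loss_tangent`.
#' @export
truth_material <- function(truth, config = pipeline_config()) {
  tt <- data.table::copy(truth)
  tt$omega_bar <- 2 * pi * tt$freq_hz * config$tau_R
  tt$E <- stiffness(tt$strain_amp, tt$myosin_amp, tt$lag, tt$omega_bar,
                    config$tau_bar, config$kappa)
  tt$delta <- loss_angle(tt$strain_amp, tt$myosin_amp, tt$lag, tt$omega_bar,
                         config$tau_bar, mode = config$loss_angle_mode)
  tt$bin <- base::floor(tt$time_s / config$material_bin) *
    config$material_bin + config$material_bin / 2
  agg <- tt[, list(stiffness = mean(E), loss_angle = mean(delta),
                   loss_tangent = tan(mean(delta))), by = "bin"]
  data.table::setnames(agg, "bin", "t")
  data.table::setorderv(agg, "t")
  agg
}
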
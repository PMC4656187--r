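# Synthetic embryos with known ground truth.
#
# The generator emulates the observed phenomenology of amnioserosa apical
# dynamics during dorsal closure: a contracting area trend carrying
# oscillations whose dominant frequency ramps from ~3.5 to ~6.5 mHz, strain
# amplitude that decays while myosin amplitude stays constant, a
# strain-to-myosin lag in [pi, 3*pi/2] narrowing over time, and a myosin
# baseline that decays exponentially (photobleaching) on top of a constant
# background. Myosin pulses ADD fluorescence to the baseline, so the signal
# minima trace background + baseline — the property the lower-envelope
# rescaling relies on.

#' Default synthetic scenario
#'
#' Parameters are the standard study conditions: frequency ramp
#' 3.51 -> 6.54 mHz, strain amplitude decaying 0.08 -> 0.04, constant myosin
#' amplitude 0.2, lag ramping 3*pi/2 -> 9*pi/8, exponential area contraction
#' and photobleached myosin baseline, plus mild Gaussian noise and
#' phase-jitter so coherence stays below 1.
#'
#' @param ... overrides for any scenario field.
#' @return named list of scenario parameters.
#' @export
scenario_default <- function(...) {
  sc <- list(
    nu_start = 3.51e-3, nu_end = 6.54e-3,      # Hz
    eps0_start = 0.08, eps0_end = 0.04,        # strain amplitude
    c0_start = 0.2, c0_end = 0.2,              # myosin amplitude
    lag_start = 3 * pi / 2, lag_end = 9 * pi / 8,  # radians, myosin - strain
    area0 = 280, area_tau = 12000,             # um^2; contraction timescale s
    area_spread = 0.1,                         # lognormal sd of per-cell size
    myosin_base = 1000, bleach_tau = 6000,     # a.u.; photobleaching tau s
    background = 200,                          # a.u., per-embryo constant
    area_noise = 0.003,    # additive Gaussian sd, relative to the local trend
    myosin_noise = 0.01,   # additive Gaussian sd, relative to the local baseline B(t)
    bg_noise = 0,          # additive Gaussian sd on the background series
    phase_jitter = 0.03,   # sd of per-step random-walk phase increments, rad
    dev_time_offset = 0    # seconds; analysis-time alignment of the tracks
  )
  utils::modifyList(sc, list(...))
}

#' ctMLCK-like scenario preset
#'
#' A constitutively-active-MLCK perturbation raises myosin amplitude and
#' baseline and lowers strain amplitude, leaving lag and frequency as in the
#' wild type — stiffer and more solid-like, with no new machinery.
#'
#' @param ... further overrides.
#' @return scenario list.
#' @export
scenario_ctmlck <- function(...) {
  scenario_default(c0_start = 0.3, c0_end = 0.3,
                   eps0_start = 0.04, eps0_end = 0.02,
                   myosin_base = 1500, ...)
}

#' Noisy scenario at a given amplitude signal-to-noise ratio
#'
#' Sets the additive noise levels (relative to the local trend/baseline) so
#' that the mean oscillation amplitude over noise standard deviation equals
#' `snr` for both channels.
#'
#' @param snr amplitude signal-to-noise ratio.
#' @param ... further overrides.
#' @return scenario list.
#' @export
scenario_noisy <- function(snr = 3, ...) {
  sc <- scenario_default(...)
  eps_mean <- (sc$eps0_start + sc$eps0_end) / 2
  c_mean <- (sc$c0_start + sc$c0_end) / 2
  sc$area_noise <- eps_mean / snr
  sc$myosin_noise <- c_mean / snr
  sc
}

ramp <- function(t, from, to) {
  if (length(t) < 2 || t[length(t)] == t[1]) return(rep(from, length(t)))
  from + (to - from) * (t - t[1]) / (t[length(t)] - t[1])
}

#' Generate a synthetic embryo with ground truth
#'
#' Area follows `Abar(t) * (1 + eps0(t) * cos(phi(t)))` with
#' `dphi/dt = 2*pi*nu(t)` plus random-walk jitter; raw myosin is
#' `background + B(t) * (1 + c0(t) * (1 + cos(phi + lag)))` plus Gaussian
#' noise, so pulse minima trace `background + B(t)` exactly.
#'
#' @param n_cells number of cells.
#' @param duration track duration, seconds.
#' @param scenario list from [scenario_default()] (or a preset).
#' @param seed integer; generation is deterministic given the seed.
#' @param dt sampling interval, seconds.
#' @param embryo_id identifier for the generated embryo.
#' @return list with `dataset` (an [embryo_dataset()]) and `truth`
#'   (a `data.table` keyed by embryo, cell and frame with the true strain
#'   amplitude, myosin amplitude, lag, instantaneous frequency, area trend,
#'   myosin baseline and oscillation phase per frame).
#' @export
generate_embryo <- function(n_cells = 20, duration = 6000,
                            scenario = scenario_default(), seed = 1,
                            dt = 10, embryo_id = "E1") {
  stopifnot(n_cells >= 1, duration >= 360)
  nyq <- 1 / (2 * dt)
  if (scenario$nu_start <= 0 || scenario$nu_end <= 0 ||
      scenario$nu_start >= nyq || scenario$nu_end >= nyq) {
    stop("generate_embryo: requested frequency outside (0, Nyquist)")
  }
  withr::with_seed(seed, {
    times <- seq(0, duration, by = dt)
    n <- length(times)
    nu <- ramp(times, scenario$nu_start, scenario$nu_end)
    eps0 <- ramp(times, scenario$eps0_start, scenario$eps0_end)
    c0 <- ramp(times, scenario$c0_start, scenario$c0_end)
    lag <- ramp(times, scenario$lag_start, scenario$lag_end)
    bg <- scenario$background +
      if (scenario$bg_noise > 0) stats::rnorm(n, 0, scenario$bg_noise) else 0
    bg <- rep_len(bg, n)

    tracks <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      jit <- if (scenario$phase_jitter > 0)
        cumsum(stats::rnorm(n, 0, scenario$phase_jitter)) else 0
      # trapezoidal phase accumulation of the instantaneous frequency
      phi <- phi0 + 2 * pi * c(0, cumsum((nu[-1] + nu[-n]) / 2 * dt)) + jit
      size <- exp(stats::rnorm(1, 0, scenario$area_spread))
      Abar <- scenario$area0 * size * exp(-times / scenario$area_tau)
      area <- Abar * (1 + eps0 * cos(phi))
      if (scenario$area_noise > 0) {
        # noise scales with the local trend (shot-noise-like)
        area <- area + stats::rnorm(n, 0, scenario$area_noise * Abar)
      }
      B <- scenario$myosin_base * size * exp(-times / scenario$bleach_tau)
      myo <- bg + B * (1 + c0 * (1 + cos(phi + lag)))
      if (scenario$myosin_noise > 0) {
        myo <- myo + stats::rnorm(n, 0, scenario$myosin_noise * B)
      }
      cid <- sprintf("c%03d", i)
      tracks[[i]] <- cell_track(embryo_id, cid, times, area, myo,
                                dev_time_offset_s = scenario$dev_time_offset)
      truth[[i]] <- data.table::data.table(
        embryo_id = embryo_id, cell_id = cid,
        frame = as.integer(round(times / dt)), time_s = times,
        strain_amp = eps0, myosin_amp = c0, lag = wrap_2pi(lag),
        freq_hz = nu, area_trend = Abar, myosin_baseline = B, phase = phi
      )
    }
    dataset <- embryo_dataset(
      tracks,
      background = data.frame(embryo_id = embryo_id, time_s = times,
                              background = bg),
      stage_label = "synthetic"
    )
    list(dataset = dataset, truth = data.table::rbindlist(truth))
  })
}

#' Generate a lattice of phase-coupled cells for the neighbour analysis
#'
#' Cells sit on a rows x cols square lattice (toroidal mechanics, so every
#' cell behaves as an interior cell). Each cell's half-axis displacement is
#' `u_i = disp_amp * cos(phi_i)`; the width of cell i along an axis is
#' `w0 + u_i - coupling * (u_left + u_right) / 2`, so with
#' `coupling = 1/3` the width-oscillation amplitude of anti-correlated
#' neighbours is exactly twice that of correlated neighbours
#' ((1 + c)/(1 - c) = 2). Myosin peaks in antiphase with cell size.
#'
#' @param n_rows,n_cols lattice dimensions (>= 2; even for the
#'   anti-correlated checkerboard).
#' @param phase_coupling `"correlated"` (all phases equal), `"uncorrelated"`
#'   (iid uniform) or `"anti-correlated"` (checkerboard 0/pi).
#' @param seed integer seed.
#' @param duration,dt track length and sampling step, seconds.
#' @param freq oscillation frequency, Hz.
#' @param cell_size lattice pitch and resting width, micron.
#' @param disp_amp membrane displacement amplitude, micron.
#' @param coupling neighbour coupling constant in [0, 1); 0 decouples cells.
#' @param myosin_amp rescaled-myosin pulse amplitude.
#' @param myosin_base,background fluorescence scales, a.u.
#' @param embryo_id identifier.
#' @return list with `dataset` (tracks carrying neighbours, centroids and
#'   rectangle outline vertices) and `truth` (per cell: oscillation phase
#'   `phase`, myosin phase `myosin_phase`, width along x/y per frame).
#' @export
generate_neighbour_lattice <- function(n_rows, n_cols,
                                       phase_coupling = c("correlated",
                                                          "uncorrelated",
                                                          "anti-correlated"),
                                       seed = 1, duration = 3000, dt = 10,
                                       freq = 5e-3, cell_size = 10,
                                       disp_amp = 0.5, coupling = 1 / 3,
                                       myosin_amp = 1.2, myosin_base = 1000,
                                       background = 200, embryo_id = "L1") {
  phase_coupling <- match.arg(phase_coupling)
  stopifnot(n_rows >= 2, n_cols >= 2, coupling >= 0, coupling < 1)
  if (phase_coupling == "anti-correlated" &&
      (n_rows %% 2 != 0 || n_cols %% 2 != 0)) {
    stop("anti-correlated checkerboard needs even lattice dimensions")
  }
  withr::with_seed(seed, {
    times <- seq(0, duration, by = dt)
    n <- length(times)
    idx <- function(r, c) (r - 1) * n_cols + c
    phi0 <- switch(phase_coupling,
      "correlated" = matrix(0, n_rows, n_cols),
      "anti-correlated" = outer(seq_len(n_rows), seq_len(n_cols),
                                function(r, c) pi * ((r + c) %% 2)),
      "uncorrelated" = matrix(stats::runif(n_rows * n_cols, 0, 2 * pi),
                              n_rows, n_cols)
    )
    omega <- 2 * pi * freq
    u <- array(0, c(n_rows, n_cols, n))
    for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
      u[r, c, ] <- disp_amp * cos(omega * times + phi0[r, c])
    }
    wrap_i <- function(i, m) ((i - 1) %% m) + 1
    tracks <- vector("list", n_rows * n_cols)
    truth <- vector("list", n_rows * n_cols)
    for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
      ul <- u[r, wrap_i(c - 1, n_cols), ]; ur <- u[r, wrap_i(c + 1, n_cols), ]
      ud <- u[wrap_i(r - 1, n_rows), c, ]; uu <- u[wrap_i(r + 1, n_rows), c, ]
      wx <- cell_size + u[r, c, ] - coupling * (ul + ur) / 2
      wy <- cell_size + u[r, c, ] - coupling * (ud + uu) / 2
      area <- wx * wy
      phi <- omega * times + phi0[r, c]
      myo <- background + myosin_base *
        (1 + myosin_amp * (1 + cos(phi + pi)))
      cid <- sprintf("r%02dc%02d", r, c)
      cen <- cbind(rep(c * cell_size, n), rep(r * cell_size, n))
      nbr <- character(0)
      if (r > 1) nbr <- c(nbr, sprintf("r%02dc%02d", r - 1, c))
      if (r < n_rows) nbr <- c(nbr, sprintf("r%02dc%02d", r + 1, c))
      if (c > 1) nbr <- c(nbr, sprintf("r%02dc%02d", r, c - 1))
      if (c < n_cols) nbr <- c(nbr, sprintf("r%02dc%02d", r, c + 1))
      verts <- lapply(seq_len(n), function(k) {
        cbind(cen[k, 1] + c(-1, 1, 1, -1) * wx[k] / 2,
              cen[k, 2] + c(-1, -1, 1, 1) * wy[k] / 2)
      })
      tracks[[idx(r, c)]] <- cell_track(
        embryo_id, cid, times, area, myo, centroid = cen,
        neighbours = rep(list(nbr), n), vertices = verts
      )
      truth[[idx(r, c)]] <- data.table::data.table(
        embryo_id = embryo_id, cell_id = cid,
        frame = as.integer(round(times / dt)), time_s = times,
        phase = wrap_2pi(phi), myosin_phase = wrap_2pi(phi + pi),
        width_x = wx, width_y = wy
      )
    }
    dataset <- embryo_dataset(
      tracks,
      background = data.frame(embryo_id = embryo_id, time_s = times,
                              background = background),
      stage_label = paste0("lattice-", phase_coupling)
    )
    list(dataset = dataset, truth = data.table::rbindlist(truth))
  })
}

#' Generate stiffness samples from the hysteretic damping law
#'
#' Evaluates `E = G0 * Gamma(1 - 2*delta/pi) * (omega * t0)^(2*delta/pi)`
#' on the Cartesian product of `deltas` and `omegas`, optionally with
#' multiplicative Gaussian noise — the oracle for [fit_scale_factors()].
#'
#' @param G0 stiffness scale factor (> 0).
#' @param t0 time scale factor, seconds (> 0).
#' @param deltas loss angles, radians, each in `[0, pi/2)`.
#' @param omegas angular frequencies, rad/s, each > 0.
#' @param noise_sd relative multiplicative noise standard deviation.
#' @param seed seed used when `noise_sd > 0`.
#' @return data.frame with columns `omega`, `delta`, `E`.
#' @export
generate_damping_curve <- function(G0, t0, deltas, omegas, noise_sd = 0,
                                   seed = 1) {
  stopifnot(G0 > 0, t0 > 0)
  if (any(deltas < 0 | deltas >= pi / 2)) {
    stop("generate_damping_curve: delta must lie in [0, pi/2)")
  }
  if (any(omegas <= 0)) stop("generate_damping_curve: omega must be positive")
  g <- expand.grid(omega = omegas, delta = deltas)
  E <- G0 * gamma(1 - 2 * g$delta / pi) * (g$omega * t0)^(2 * g$delta / pi)
  if (noise_sd > 0) {
    E <- withr::with_seed(seed, E * (1 + stats::rnorm(length(E), 0, noise_sd)))
  }
  data.frame(omega = g$omega, delta = g$delta, E = E)
}
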
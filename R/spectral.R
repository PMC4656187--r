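# Frequency-resolved description of strain and rescaled myosin.

#' Frequency grid of the analysis
#'
#' @param config an [pipeline_config()] list.
#' @return frequencies in Hz from `band_low` to `band_high` in steps of
#'   `freq_resolution`.
#' @export
frequency_grid <- function(config = pipeline_config()) {
  f <- seq(config$band_low, config$band_high, by = config$freq_resolution)
  f[f <= config$band_high + 1e-12]
}

hann_window <- function(L) {
  if (L == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
}

#' Sliding-window Fourier amplitudes
#'
#' For each frequency nu, a Hann-tapered window of length 3/nu slides in
#' steps of 1/(2*nu). Within each window the single-frequency Fourier
#' coefficient at nu is computed and the corresponding time-domain component
#' reconstructed; the amplitude is the absolute value of the reconstruction
#' at its extremum nearest the window centre (parabolically refined), which
#' for a pure unit sinusoid is 1. The plain coefficient estimator
#' `2|X|/sum(w)` is returned alongside.
#'
#' @param x signal on a uniform grid, NA-free.
#' @param dt sampling interval, seconds.
#' @param freqs frequencies to evaluate, Hz.
#' @param t0 time of the first sample (analysis time), seconds.
#' @param estimator `"peak"` (reconstruction extremum, default) or
#'   `"coefficient"` (plain normalised Fourier coefficient) for the
#'   `amplitude` column.
#' @return `data.table` with columns `freq`, `t` (window centre), `amplitude`,
#'   `amplitude_coef`, `phase` (radians at the window-centre time).
#'   Frequencies whose window does not fit are skipped.
#' @export
sliding_fourier <- function(x, dt, freqs, t0 = 0,
                            estimator = c("peak", "coefficient")) {
  estimator <- match.arg(estimator)
  if (anyNA(x)) stop("sliding_fourier: input contains NA")
  n <- length(x)
  out <- vector("list", length(freqs))
  for (j in seq_along(freqs)) {
    nu <- freqs[j]
    L <- round(3 / (nu * dt))
    if (L > n || L < 4) next
    S <- max(1L, as.integer(round(1 / (2 * nu * dt))))
    starts <- seq.int(1L, n - L + 1L, by = S)
    w <- hann_window(L)
    trel <- (0:(L - 1)) * dt
    ew <- w * exp(-2i * pi * nu * trel)
    sw <- sum(w)
    amp <- phase <- ampc <- numeric(length(starts))
    centre_t <- numeric(length(starts))
    ic <- (L - 1) / 2          # window-centre offset in samples
    for (k in seq_along(starts)) {
      seg <- x[starts[k]:(starts[k] + L - 1L)]
      X <- sum(seg * ew)
      a <- 2 * Mod(X) / sw
      ph <- Arg(X)
      ampc[k] <- a
      if (estimator == "coefficient" || a == 0) {
        amp[k] <- a
      } else {
        r <- a * cos(2 * pi * nu * trel + ph)
        ext <- local_extrema(abs(r), "max")
        if (!length(ext)) {
          amp[k] <- a
        } else {
          i0 <- ext[which.min(abs(ext - 1 - ic))]
          if (i0 > 1 && i0 < L) {
            # parabolic refinement of the sampled extremum
            y1 <- abs(r[i0 - 1]); y2 <- abs(r[i0]); y3 <- abs(r[i0 + 1])
            den <- y1 - 2 * y2 + y3
            amp[k] <- if (den != 0) y2 - (y1 - y3)^2 / (8 * den) else y2
          } else {
            amp[k] <- abs(r[i0])
          }
        }
      }
      # phase referenced to the window-centre time
      phase[k] <- wrap_2pi(ph + 2 * pi * nu * ic * dt)
      centre_t[k] <- t0 + (starts[k] - 1 + ic) * dt
    }
    out[[j]] <- data.table::data.table(freq = nu, t = centre_t,
                                       amplitude = amp,
                                       amplitude_coef = ampc, phase = phase)
  }
  data.table::rbindlist(out)
}

#' Instantaneous strain-to-myosin phase lag in a frequency band
#'
#' Both signals are band-isolated around `freq` (Fourier-domain masking,
#' exactly zero-phase) and their analytic-signal phases differenced:
#' `lag(t) = wrap(phase_myosin - phase_strain)` in `[0, 2*pi)`. The first
#' and last 10\% of samples are masked as end effects, as are samples where
#' either band amplitude falls below `floor` times its median.
#'
#' @param strain,myosin series on a common uniform grid, NA-free.
#' @param dt sampling interval, seconds.
#' @param freq band centre frequency, Hz.
#' @param bandwidth full bandwidth, Hz (default `freq/3`).
#' @param trim_frac fraction of each end masked.
#' @param floor relative amplitude floor below which the lag is undefined.
#' @return numeric vector of lags, NA where masked.
#' @export
band_phase_lag <- function(strain, myosin, dt, freq, bandwidth = freq / 3,
                           trim_frac = 0.1, floor = 1e-3) {
  stopifnot(length(strain) == length(myosin))
  za <- band_analytic(strain, dt, freq, bandwidth)
  zb <- band_analytic(myosin, dt, freq, bandwidth)
  lag <- wrap_2pi(Arg(zb) - Arg(za))
  n <- length(lag)
  ntrim <- base::floor(trim_frac * n)
  if (ntrim > 0) lag[c(seq_len(ntrim), n - seq_len(ntrim) + 1L)] <- NA_real_
  aa <- Mod(za); ab <- Mod(zb)
  lag[aa < floor * stats::median(aa) | ab < floor * stats::median(ab)] <- NA_real_
  lag
}

#' Per-cell spectral components
#'
#' Sliding-window Fourier amplitudes of strain and myosin over the
#' configured frequency grid, with the strain-to-myosin lag per component.
#'
#' With `lag_source = "fourier"` (default) the lag is the phase difference
#' of the two windowed Fourier coefficients of the same window: both
#' coefficients carry the identical window leakage factor, which cancels in
#' the difference, so the lag of an oscillatory component is recovered
#' exactly at every grid frequency its window responds to. With
#' `lag_source = "hilbert"` the lag is the analytic-signal phase difference
#' in a narrow band around each grid frequency ([band_phase_lag()]),
#' evaluated at the window centre; this measures an instantaneous lag but is
#' only meaningful at frequencies whose band genuinely contains signal.
#'
#' @param proc processed-signals table from [preprocess_dataset()].
#' @param config an [pipeline_config()] list.
#' @param estimator amplitude estimator passed to [sliding_fourier()].
#' @param lag_source `"fourier"` (default) or `"hilbert"`.
#' @return `data.table` with `embryo_id`, `cell_id`, `freq`, `t`,
#'   `strain_amp`, `myosin_amp`, `lag`.
#' @export
spectral_components <- function(proc, config = pipeline_config(),
                                estimator = "peak",
                                lag_source = c("fourier", "hilbert")) {
  lag_source <- match.arg(lag_source)
  dt <- attr(proc, "dt")
  if (is.null(dt) || is.na(dt)) {
    dt <- uniform_step(sort(unique(proc$time_s))[1:2])
    if (is.na(dt)) stop("spectral_components: cannot infer sampling step")
  }
  freqs <- frequency_grid(config)
  cells <- split(proc, paste(proc$embryo_id, proc$cell_id, sep = "\r"))
  out <- lapply(cells, function(cc) {
    cc <- cc[order(cc$time_s)]
    x <- cc$strain; m <- cc$myosin
    as <- sliding_fourier(x, dt, freqs, t0 = cc$time_s[1], estimator = estimator)
    if (!nrow(as)) return(NULL)
    am <- sliding_fourier(m, dt, freqs, t0 = cc$time_s[1], estimator = estimator)
    comp <- merge(
      as[, list(freq = freq, t = t, strain_amp = amplitude, phase_s = phase)],
      am[, list(freq = freq, t = t, myosin_amp = amplitude, phase_m = phase)],
      by = c("freq", "t")
    )
    if (lag_source == "fourier") {
      comp$lag <- wrap_2pi(comp$phase_m - comp$phase_s)
    } else {
      lags <- rep(NA_real_, nrow(comp))
      for (nu in unique(comp$freq)) {
        lg <- band_phase_lag(x, m, dt, nu)
        sel <- comp$freq == nu
        idx <- round((comp$t[sel] - cc$time_s[1]) / dt) + 1L
        lags[sel] <- lg[idx]
      }
      comp$lag <- lags
    }
    comp$phase_s <- comp$phase_m <- NULL
    comp$embryo_id <- cc$embryo_id[1]
    comp$cell_id <- cc$cell_id[1]
    comp
  })
  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res)) {
    data.table::setcolorder(res, c("embryo_id", "cell_id", "freq", "t",
                                   "strain_amp", "myosin_amp", "lag"))
  }
  attr(res, "dt") <- dt
  res
}

# ---- Morlet wavelet coherence ----------------------------------------------

# Morlet CWT at the requested frequencies (Fourier-domain implementation).
# Returns a length(freqs) x n complex matrix.
morlet_cwt <- function(x, dt, freqs, omega0 = 6) {
  n <- length(x)
  X <- stats::fft(x)
  wk <- 2 * pi * (seq_len(n) - 1) / (n * dt)
  wk[wk > pi / dt] <- wk[wk > pi / dt] - 2 * pi / dt   # signed angular freqs
  # scale such that the wavelet's peak response sits at frequency nu
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  W <- matrix(0i, length(freqs), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-(s * wk - omega0)^2 / 2) * (wk > 0)
    W[j, ] <- stats::fft(X * psi, inverse = TRUE) / n
  }
  W
}

smooth_rows <- function(M, k) {
  # centred boxcar along rows (time); k may vary per row
  out <- M
  for (j in seq_len(nrow(M))) {
    kk <- if (length(k) > 1) k[j] else k
    kk <- max(1L, min(as.integer(kk), ncol(M)))
    if (kk > 1) {
      re <- boxcar(Re(M[j, ]), kk); im <- boxcar(Im(M[j, ]), kk)
      out[j, ] <- complex(real = re, imaginary = im)
    }
  }
  out
}

# average rows (scales) over a relative frequency band [f/r, f*r]
smooth_scales <- function(M, freqs, r) {
  if (r <= 1) return(M)
  out <- M
  for (j in seq_along(freqs)) {
    sel <- which(freqs >= freqs[j] / r & freqs <= freqs[j] * r)
    out[j, ] <- if (length(sel) > 1) colMeans(M[sel, , drop = FALSE]) else M[j, ]
  }
  out
}

smooth_spectrum <- function(M, freqs, dt, time_smooth, scale_band) {
  k_t <- pmax(1, round(time_smooth / (freqs * dt)))   # periods per scale
  S <- M
  if (is.complex(M)) {
    S <- smooth_rows(M, k_t)
    complex_mat <- function(Re_s, Im_s) {
      matrix(complex(real = Re_s, imaginary = Im_s), nrow(M), ncol(M))
    }
    complex_mat(smooth_scales(Re(S), freqs, scale_band),
                smooth_scales(Im(S), freqs, scale_band))
  } else {
    for (j in seq_len(nrow(M))) {
      kk <- max(1L, min(k_t[j], ncol(M)))
      if (kk > 1) S[j, ] <- boxcar(M[j, ], kk)
    }
    smooth_scales(S, freqs, scale_band)
  }
}

#' Morlet wavelet coherence between strain and myosin
#'
#' Magnitude coherence in [0, 1] from smoothed Morlet cross- and
#' auto-spectra. Smoothing (a boxcar over `coherence_time_smooth`
#' oscillation periods in time at each scale, and across scales within the
#' `coherence_scale_band` relative frequency band) is mandatory: unsmoothed
#' wavelet coherence is identically 1. The defaults (3 periods, +/-15\%)
#' give roughly 4-5 effective degrees of freedom, so independent noise
#' yields coherence well below 1 while a coherent pair stays near 1.
#'
#' @param strain,myosin series on a common uniform grid, NA-free, with
#'   non-zero variance.
#' @param dt sampling interval, seconds.
#' @param config an [pipeline_config()] list (frequency grid, Morlet
#'   parameter, smoothing spans).
#' @param freqs optional frequency vector overriding the config grid.
#' @return list with `freq`, `time` (sample offsets, seconds) and
#'   `coherence` (length(freq) x n matrix, NA where smoothing is undefined).
#' @export
wavelet_coherence <- function(strain, myosin, dt,
                              config = pipeline_config(), freqs = NULL) {
  if (stats::sd(strain) == 0 || stats::sd(myosin) == 0) {
    stop("wavelet_coherence: zero-variance input")
  }
  if (is.null(freqs)) freqs <- frequency_grid(config)
  Wx <- morlet_cwt(strain, dt, freqs, config$morlet_omega0)
  Wy <- morlet_cwt(myosin, dt, freqs, config$morlet_omega0)
  Sxy <- smooth_spectrum(Wx * Conj(Wy), freqs, dt,
                         config$coherence_time_smooth,
                         config$coherence_scale_band)
  Sxx <- smooth_spectrum(Mod(Wx)^2, freqs, dt,
                         config$coherence_time_smooth,
                         config$coherence_scale_band)
  Syy <- smooth_spectrum(Mod(Wy)^2, freqs, dt,
                         config$coherence_time_smooth,
                         config$coherence_scale_band)
  coh <- Mod(Sxy) / sqrt(pmax(Sxx, .Machine$double.eps) *
                         pmax(Syy, .Machine$double.eps))
  coh <- pmin(pmax(coh, 0), 1)
  coh[is.na(Mod(Sxy))] <- NA_real_
  list(freq = freqs, time = (seq_along(strain) - 1) * dt, coherence = coh)
}

#' Resampling null for the strain-to-myosin coherence
#'
#' Pairs the myosin signal of one randomly sampled cell with the strain
#' signal of another, recomputes the coherence, and returns per time step
#' the 90th (by default) percentile of the null coherence values pooled
#' over iterations and frequencies (accumulated on a fixed 0.002-wide
#' histogram). Deterministic given the seed.
#'
#' @param proc processed-signals table (>= 2 cells on a shared grid).
#' @param config an [pipeline_config()] list.
#' @param n_iter resampling iterations.
#' @param seed integer seed.
#' @param level percentile level (default 0.9).
#' @param freqs optional frequency grid override.
#' @return list with `time`, `threshold` (per time step) and `n_iter`.
#' @export
coherence_null <- function(proc, config = pipeline_config(), n_iter = 1000,
                           seed = 1, level = 0.9, freqs = NULL) {
  cells <- split(proc, paste(proc$embryo_id, proc$cell_id, sep = "\r"))
  if (length(cells) < 2) stop("coherence_null: need at least two cells")
  if (is.null(freqs)) freqs <- frequency_grid(config)
  # align on the intersection of the cells' time grids
  t_common <- Reduce(intersect, lapply(cells, function(cc) cc$time_s))
  if (length(t_common) < 16) stop("coherence_null: too little shared support")
  t_common <- sort(t_common)
  dt <- uniform_step(t_common)
  strains <- lapply(cells, function(cc) cc$strain[match(t_common, cc$time_s)])
  myosins <- lapply(cells, function(cc) cc$myosin[match(t_common, cc$time_s)])
  Wx <- lapply(strains, morlet_cwt, dt = dt, freqs = freqs,
               omega0 = config$morlet_omega0)
  Wy <- lapply(myosins, morlet_cwt, dt = dt, freqs = freqs,
               omega0 = config$morlet_omega0)
  Sxx <- lapply(Wx, function(W) smooth_spectrum(Mod(W)^2, freqs, dt,
                config$coherence_time_smooth, config$coherence_scale_band))
  Syy <- lapply(Wy, function(W) smooth_spectrum(Mod(W)^2, freqs, dt,
                config$coherence_time_smooth, config$coherence_scale_band))
  nC <- length(cells)
  nT <- length(t_common)
  nbins <- 500L
  withr::with_seed(seed, {
    counts <- matrix(0L, nT, nbins)      # per-time histogram of null values
    for (it in seq_len(n_iter)) {
      a <- sample.int(nC, 1)
      b <- sample.int(nC - 1, 1); if (b >= a) b <- b + 1   # strain != myosin cell
      Sxy <- smooth_spectrum(Wx[[a]] * Conj(Wy[[b]]), freqs, dt,
                             config$coherence_time_smooth,
                             config$coherence_scale_band)
      coh <- Mod(Sxy) / sqrt(pmax(Sxx[[a]], .Machine$double.eps) *
                             pmax(Syy[[b]], .Machine$double.eps))
      bin <- pmin(pmax(ceiling(coh * nbins), 1L), nbins)   # freq x time
      for (jt in seq_len(nT)) {
        v <- bin[, jt]; v <- v[!is.na(v)]
        if (length(v)) counts[jt, ] <- counts[jt, ] + tabulate(v, nbins)
      }
    }
    thr <- vapply(seq_len(nT), function(jt) {
      cs <- cumsum(counts[jt, ]); tot <- cs[nbins]
      if (tot == 0) return(NA_real_)
      (which(cs >= level * tot)[1]) / nbins
    }, numeric(1))
    list(time = t_common, threshold = thr, n_iter = n_iter)
  })
}

# ---- strain-myosin hysteresis loops ----------------------------------------

#' Strain-myosin hysteresis loops by instantaneous phase
#'
#' The instantaneous oscillation phase is defined by the strain signal
#' (analytic-signal argument). Within each developmental stage bin
#' (`loop_bin` seconds of analysis time) the strain and myosin signals of
#' all cells are averaged in each phase bin, yielding one closed loop per
#' stage; the signed enclosed area (positive = counter-clockwise in the
#' (strain, myosin) plane) quantifies hysteresis.
#'
#' @param proc processed-signals table.
#' @param config an [pipeline_config()] list (`loop_bin`, `n_phase_bins`).
#' @return list with `loops` (stage_bin, phase_bin, phase centre,
#'   mean_strain, mean_myosin, n_obs) and `areas` (stage_bin, signed `area`,
#'   `orientation`).
#' @export
hysteresis_loops <- function(proc, config = pipeline_config()) {
  cells <- split(proc, paste(proc$embryo_id, proc$cell_id, sep = "\r"))
  rows <- lapply(cells, function(cc) {
    cc <- cc[order(cc$time_s)]
    ph <- wrap_2pi(Arg(analytic_signal(cc$strain)))
    data.table::data.table(time_s = cc$time_s, strain = cc$strain,
                           myosin = cc$myosin, phase = ph)
  })
  d <- data.table::rbindlist(rows)
  nb <- config$n_phase_bins
  d$stage_bin <- base::floor(d$time_s / config$loop_bin) * config$loop_bin
  d$phase_bin <- pmin(base::floor(d$phase / (2 * pi / nb)), nb - 1L)
  loops <- d[, list(mean_strain = mean(strain), mean_myosin = mean(myosin),
                    n_obs = .N),
             by = c("stage_bin", "phase_bin")]
  loops$phase <- (loops$phase_bin + 0.5) * 2 * pi / nb
  data.table::setorderv(loops, c("stage_bin", "phase_bin"))
  areas <- loops[, {
    if (.N >= 3) {
      a <- polygon_area(mean_strain, mean_myosin)
      list(area = a, orientation = sign(a), n_bins = .N)
    } else list(area = NA_real_, orientation = NA_real_, n_bins = .N)
  }, by = "stage_bin"]
  list(loops = loops, areas = areas)
}

# data.table NSE columns
utils::globalVariables(c("freq", "t", "amplitude", "strain", "myosin",
                         "mean_strain", "mean_myosin", ".N"))
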
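# From raw area and myosin to dimensionless strain and rescaled myosin.
#
# All stage functions operate on plain numeric vectors on a uniform grid and
# return full-length vectors padded with NA wherever a windowed operation is
# not valid (edges are trimmed, never padded with synthetic data).
# process_track() assembles the per-track result on the common valid range.

# Hann-windowed linear-phase FIR bandpass kernel.
fir_kernel <- function(dt, low, high, taps) {
  nyq <- 1 / (2 * dt)
  if (!(low > 0 && low < high && high < nyq)) {
    stop("bandpass_filter: need 0 < low < high < Nyquist")
  }
  signal::fir1(taps - 1, c(low, high) / nyq, type = "pass",
               window = signal::hanning(taps))
}

#' Zero-phase FIR bandpass filter
#'
#' Hann-windowed FIR design; forward-backward filtering is applied as a
#' single centred convolution with the kernel's autocorrelation, which is
#' algebraically identical on the interior and exactly zero-phase. Edges
#' where the (effective) filter support is incomplete are returned as NA.
#'
#' @param x numeric series on a uniform grid (NA-free).
#' @param dt sampling interval, seconds.
#' @param low,high passband edges, Hz.
#' @param taps FIR length (odd).
#' @param passes 2 = forward-backward (default), 1 = single pass.
#' @return numeric vector, NA outside the valid interior;
#'   `attr(, "trim")` gives the number of edge samples removed per side.
#' @export
bandpass_filter <- function(x, dt, low = 1e-3, high = 12.5e-3, taps = 201,
                            passes = 2) {
  if (anyNA(x)) stop("bandpass_filter: input contains NA")
  if (length(x) <= taps) {
    stop("bandpass_filter: signal too short for a ", taps, "-tap filter (",
         length(x), " samples)")
  }
  b <- fir_kernel(dt, low, high, taps)
  h <- if (passes == 2) stats::convolve(b, rev(b), type = "open") else b
  y <- as.numeric(stats::filter(x, h, sides = 2))
  attr(y, "trim") <- (length(h) - 1L) / 2L
  y
}

#' Slow area trend by (refined) boxcar averaging
#'
#' Centred moving average over `window` seconds. A plain boxcar leaks a
#' fraction of the oscillation into the trend (its frequency response at the
#' oscillation frequency), biasing the recovered strain amplitude; each
#' refinement iteration divides the current band-limited oscillation
#' estimate out of the raw series and re-smooths, reducing the bias from
#' O(a) to O(a^(r+1)) where a is the boxcar response.
#'
#' @param x area series (NA-free, uniform grid).
#' @param dt sampling interval, seconds.
#' @param window boxcar window, seconds (default 360 s = 37 samples at 10 s).
#' @param refine refinement iterations (0 = plain boxcar).
#' @param band passband used for the oscillation estimate during refinement.
#' @param taps,passes FIR parameters for the refinement bandpass.
#' @return trend series, NA at edges with incomplete windows.
#' @export
area_trend <- function(x, dt, window = 360, refine = 0,
                       band = c(1e-3, 12.5e-3), taps = 201, passes = 2) {
  k <- 2L * floor(window / dt / 2) + 1L
  if (k > length(x)) {
    stop("area_trend: track shorter than the trend window")
  }
  tr <- boxcar(x, k)
  for (r in seq_len(refine)) {
    ok <- !is.na(tr)
    if (any(tr[ok] <= 0)) stop("area_trend: non-positive trend")
    seg <- range(which(ok))
    res <- (x[seg[1]:seg[2]] - tr[seg[1]:seg[2]]) / tr[seg[1]:seg[2]]
    flt <- tryCatch(bandpass_filter(res, dt, band[1], band[2], taps, passes),
                    error = function(e) NULL)
    if (is.null(flt)) break   # too short to refine; keep the plain boxcar trend
    # oscillation estimate taken as zero where the filter is not valid, so the
    # trend's own valid domain is preserved; near the edges the refinement
    # degrades gracefully to the plain boxcar (and those samples are trimmed
    # by the final bandpass anyway)
    eps <- rep(0, length(x))
    eps[seg[1]:seg[2]][!is.na(flt)] <- flt[!is.na(flt)]
    tr <- boxcar(x / (1 + eps), k)
  }
  tr
}

#' Apical area strain
#'
#' `eps(t) = (A - Abar)/Abar`, band-limited to the configured passband.
#'
#' @param area area series (um^2, NA-free, uniform grid).
#' @param dt sampling interval, seconds.
#' @param config an [pipeline_config()] list.
#' @return list with `strain` (NA-padded) and `trend`.
#' @export
compute_strain <- function(area, dt, config = pipeline_config()) {
  tr <- area_trend(area, dt, config$trend_window, refine = config$trend_refine,
                   band = c(config$band_low, config$band_high),
                   taps = config$fir_taps, passes = config$filter_passes)
  ok <- !is.na(tr)
  if (!any(ok)) stop("compute_strain: no valid trend samples")
  if (any(tr[ok] <= 0)) {
    stop("compute_strain: non-positive area trend; track rejected")
  }
  seg <- range(which(ok))
  raw <- (area[seg[1]:seg[2]] - tr[seg[1]:seg[2]]) / tr[seg[1]:seg[2]]
  flt <- bandpass_filter(raw, dt, config$band_low, config$band_high,
                         config$fir_taps, config$filter_passes)
  strain <- rep(NA_real_, length(area))
  strain[seg[1]:seg[2]] <- flt
  list(strain = strain, trend = tr)
}

# extend a series across its NA edges by the nearest valid value
fill_edges <- function(y, fallback = NA_real_) {
  ok <- which(!is.na(y))
  if (!length(ok)) return(rep(fallback, length(y)))
  y[seq_len(ok[1] - 1)] <- y[ok[1]]
  n <- length(y)
  last <- ok[length(ok)]
  if (last < n) y[(last + 1):n] <- y[last]
  y
}

# Dirichlet-kernel gain of a k-sample boxcar at a period of P samples
boxcar_gain <- function(k, P) {
  if (k <= 1 || !is.finite(P) || P <= 0) return(1)
  sin(k * pi / P) / (k * sin(pi / P))
}

#' Lower envelope of the myosin signal
#'
#' The minima trend of the pulsatile fluorescence signal, built to be
#' unbiased both for clean and for noisy data. Pulse peak positions are
#' detected on a band-limited copy of the signal (linear filtering, so
#' broadband noise does not spawn spurious peaks), with a minimum
#' separation of `min_separation` seconds. Troughs are taken midway between
#' consecutive peaks; the trough value is the mean of the pre-smoothed
#' signal in a small window there — no extremal value selection, so noise
#' does not bias the envelope downwards — corrected for the known boxcar
#' attenuation of the oscillation at the measured cycle length (solving the
#' two-point peak/trough system for the baseline). The trough values are
#' linearly interpolated onto the full grid, extended by the nearest trough
#' at the ends, and smoothed with a centred boxcar over `window` seconds.
#'
#' When fewer than two pulse peaks exist (constant or non-oscillatory
#' signal), the envelope falls back to the `window`-boxcar trend of the
#' signal itself.
#'
#' @param m background-subtracted myosin series (NA-free).
#' @param dt sampling interval, seconds.
#' @param window smoothing window, seconds.
#' @param presmooth pre-smoothing window for trough measurement, seconds.
#' @param min_separation minimum pulse-peak separation, seconds.
#' @param band passband used for peak detection, Hz.
#' @param taps FIR length for peak detection (shrunk for short tracks).
#' @return envelope series (same length, no NA).
#' @export
myosin_envelope <- function(m, dt, window = 360, presmooth = 50,
                            min_separation = 60, band = c(1e-3, 12.5e-3),
                            taps = 201) {
  if (anyNA(m)) stop("myosin_envelope: input contains NA")
  n <- length(m)
  k <- 2L * floor(window / dt / 2) + 1L
  fallback <- function() {
    env <- fill_edges(boxcar(m, min(k, 2L * floor((n - 1) / 2) + 1L)),
                      stats::median(m))
    env
  }
  # peak positions from the band-limited signal (noise-immune)
  taps_eff <- min(taps, 2L * floor((n - 2) / 2) + 1L)
  mb <- tryCatch(bandpass_filter(m, dt, band[1], band[2], taps_eff, passes = 1),
                 error = function(e) NULL)
  if (is.null(mb)) return(fallback())
  mb[is.na(mb)] <- 0
  pk <- local_extrema(mb, "max")
  pk <- pk[mb[pk] > 0]
  if (length(pk) >= 2) {
    repeat {
      gaps <- diff(pk) * dt
      bad <- which(gaps < min_separation)
      if (!length(bad)) break
      b <- bad[1]
      drop <- if (mb[pk[b]] < mb[pk[b + 1]]) b else b + 1L
      pk <- pk[-drop]
    }
  }
  if (length(pk) < 2) return(fallback())
  kp <- 2L * floor(presmooth / dt / 2) + 1L
  ms <- if (kp >= 3 && kp < n) fill_edges(boxcar(m, kp)) else m
  hw <- 2L
  mids <- as.integer(floor((pk[-length(pk)] + pk[-1]) / 2))
  vals <- vapply(seq_along(mids), function(j) {
    i <- mids[j]
    P <- pk[j + 1] - pk[j]                      # cycle length, samples
    tv <- mean(ms[max(1, i - hw):min(n, i + hw)])
    pkv <- (ms[pk[j]] + ms[pk[j + 1]]) / 2
    a_pre <- boxcar_gain(kp, P)
    a_win <- boxcar_gain(2L * hw + 1L, P) * a_pre
    # smoothed peak = B + c0B*(1 + a_pre); smoothed trough = B + c0B*(1 - a_win)
    c0B <- (pkv - tv) / (a_pre + a_win)
    max(tv - c0B * (1 - a_win), .Machine$double.eps)
  }, numeric(1))
  env <- stats::approx(mids, vals, xout = seq_len(n), rule = 2)$y
  if (k < n) env <- fill_edges(boxcar(env, k))
  env
}

#' Rescaled myosin fluorescence
#'
#' Subtracts the per-frame background, divides by the lower-envelope minima
#' trend and removes the unit offset:
#' `c_m = (myosin_raw - background)/envelope - 1`, then bandpass-filters.
#' Division makes the result invariant under any positive gain applied above
#' background. The `"subtract"` mode replaces division by subtraction of the
#' envelope (sensitivity variant; not gain-invariant).
#'
#' @param myosin_raw raw fluorescence series (a.u., NA-free).
#' @param background background level: scalar or per-frame series (a.u.).
#' @param dt sampling interval, seconds.
#' @param config an [pipeline_config()] list.
#' @return list with `myosin` (dimensionless, NA-padded) and `envelope`.
#' @export
rescale_myosin <- function(myosin_raw, background, dt,
                           config = pipeline_config()) {
  m <- myosin_raw - background
  env <- myosin_envelope(m, dt, config$trend_window)
  if (any(env <= 0)) {
    stop("rescale_myosin: non-positive envelope (over-subtracted background); track rejected")
  }
  raw <- if (config$envelope_mode == "divide") m / env - 1 else m - env
  myo <- bandpass_filter(raw, dt, config$band_low, config$band_high,
                         config$fir_taps, config$filter_passes)
  list(myosin = as.numeric(myo), envelope = env,
       trim = attr(myo, "trim"))
}

#' Preprocess one track into strain and rescaled myosin
#'
#' @param track a [cell_track()].
#' @param background background series aligned to the track's frames
#'   (scalar, vector, or NULL for zero background).
#' @param config an [pipeline_config()] list.
#' @return `data.table` with columns `embryo_id`, `cell_id`, `time_s`
#'   (analysis time, offset applied), `strain`, `myosin`, trimmed to the
#'   common valid range; zero-row table if nothing survives trimming.
#' @export
process_track <- function(track, background = NULL,
                          config = pipeline_config()) {
  dt <- uniform_step(track$time_s)
  if (is.null(background)) background <- 0
  st <- compute_strain(track$area_um2, dt, config)
  my <- rescale_myosin(track$myosin, background, dt, config)
  ok <- which(!is.na(st$strain) & !is.na(my$myosin))
  data.table::data.table(
    embryo_id = track$embryo_id, cell_id = track$cell_id,
    time_s = analysis_time(track)[ok],
    strain = st$strain[ok], myosin = my$myosin[ok]
  )
}

#' Preprocess every track of a dataset
#'
#' Tracks that fail (too short for the filter, non-positive trend or
#' envelope) are recorded in the `report` attribute with the error message,
#' not dropped silently.
#'
#' @param ds an [embryo_dataset()].
#' @param config an [pipeline_config()] list.
#' @return `data.table` of processed signals (one row per surviving frame);
#'   `attr(, "report")` lists per-track failures.
#' @export
preprocess_dataset <- function(ds, config = pipeline_config()) {
  failures <- character(0)
  out <- lapply(ds$tracks, function(tr) {
    bg <- 0
    if (!is.null(ds$background)) {
      b <- ds$background[ds$background$embryo_id == tr$embryo_id, ]
      if (nrow(b)) {
        bg <- stats::approx(b$time_s, b$background, xout = tr$time_s,
                            rule = 2)$y
      }
    }
    tryCatch(process_track(tr, bg, config), error = function(e) {
      failures[[length(failures) + 1]] <<-
        paste0(tr$embryo_id, "/", tr$cell_id, ": ", conditionMessage(e))
      NULL
    })
  })
  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  attr(res, "report") <- failures
  attr(res, "dt") <- if (length(ds$tracks))
    uniform_step(ds$tracks[[1]]$time_s) else NA_real_
  attr(res, "config") <- config
  res
}
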
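# Neighbour myosin-phase analysis: peak-based myosin phase, pair phase
# correlation and classification, cell-shape strain-rate tensors projected
# along the neighbour axis, and the randomised-partner null.

#' Myosin phase, cycle length and fluctuation flag from peaks
#'
#' Peaks are strict local maxima of the rescaled myosin signal separated by
#' at least `min_separation` seconds (the smaller of two closer peaks is
#' dropped). Phase at time t between consecutive peaks P_prev <= t < P_next
#' is `2*pi*(t - P_prev)/(P_next - P_prev)`; the cycle length is their
#' separation and the amplitude half the peak-to-trough range within the
#' cycle. Myosin counts as fluctuating where the cycle length lies within
#' `cycle_range` and amplitude times frequency (cycles/min) exceeds
#' `threshold`.
#'
#' @param myosin rescaled (band-limited) myosin series, NA-free.
#' @param dt sampling interval, seconds.
#' @param min_separation minimum peak separation, seconds.
#' @param cycle_range admissible cycle lengths, seconds.
#' @param threshold on amplitude x frequency (units x cycles/min).
#' @return `data.table` with one row per sample: `phase` (radians, NA
#'   outside complete cycles), `cycle_length` (s), `amplitude`,
#'   `amp_freq` (amplitude x cycles/min) and `fluctuating`.
#' @export
myosin_phase <- function(myosin, dt, min_separation = 60,
                         cycle_range = c(60, 360), threshold = 0.3) {
  n <- length(myosin)
  pk <- local_extrema(myosin, "max")
  # enforce minimum separation, keeping the larger peak
  if (length(pk) >= 2) {
    repeat {
      gaps <- diff(pk) * dt
      bad <- which(gaps < min_separation)
      if (!length(bad)) break
      b <- bad[1]
      drop <- if (myosin[pk[b]] < myosin[pk[b + 1]]) b else b + 1L
      pk <- pk[-drop]
    }
  }
  out <- data.table::data.table(
    phase = rep(NA_real_, n), cycle_length = NA_real_,
    amplitude = NA_real_, amp_freq = NA_real_, fluctuating = FALSE
  )
  if (length(pk) < 2) return(out)
  for (j in seq_len(length(pk) - 1)) {
    i0 <- pk[j]; i1 <- pk[j + 1]
    span <- i0:i1
    cl <- (i1 - i0) * dt
    amp <- (max(myosin[span]) - min(myosin[span])) / 2
    af <- amp * 60 / cl                 # amplitude x frequency in cycles/min
    # the final peak closes the last cycle and carries its statistics
    idx <- if (j == length(pk) - 1) i0:i1 else i0:(i1 - 1L)
    data.table::set(out, idx, "phase",
                    wrap_2pi(2 * pi * (idx - i0) / (i1 - i0)))
    data.table::set(out, idx, "cycle_length", cl)
    data.table::set(out, idx, "amplitude", amp)
    data.table::set(out, idx, "amp_freq", af)
    data.table::set(out, idx, "fluctuating",
                    cl >= cycle_range[1] && cl <= cycle_range[2] &&
                      af > threshold)
  }
  out
}

#' Myosin-phase correlation of a neighbour pair
#'
#' `r_m = cos(phase_a - phase_b)`: 1 for in-phase, -1 for antiphase.
#'
#' @param phase_a,phase_b phases in radians (vectorised).
#' @return `r_m` in [-1, 1].
#' @export
pair_phase_correlation <- function(phase_a, phase_b) cos(phase_a - phase_b)

#' Classify a phase correlation
#'
#' Thresholds partition [-1, 1]: correlated for `r_m > 0.33`,
#' anti-correlated for `r_m < -0.33`, uncorrelated between.
#'
#' @param r_m phase correlation values.
#' @return factor with levels correlated / uncorrelated / anti-correlated.
#' @export
classify_rm <- function(r_m) {
  cls <- ifelse(r_m > 0.33, "correlated",
                ifelse(r_m < -0.33, "anti-correlated", "uncorrelated"))
  factor(cls, levels = c("correlated", "uncorrelated", "anti-correlated"))
}

#' Cell-shape strain-rate tensor between two outlines
#'
#' Least-squares symmetric linear map M minimising
#' `sum || (v'_i - c') - M (v_i - c) ||^2` over centroid-relative vertices
#' (no rotation), with the strain-rate tensor `(M - I)/dt`. Requires vertex
#' correspondence between the two frames.
#'
#' @param outline0,outline1 2-column vertex matrices (same count and order).
#' @param dt time step between the frames, seconds.
#' @return 2x2 symmetric strain-rate tensor (1/s) with attribute `trace`.
#' @export
shape_strain_rate <- function(outline0, outline1, dt) {
  stopifnot(is.matrix(outline0), is.matrix(outline1),
            nrow(outline0) == nrow(outline1), ncol(outline0) == 2)
  if (abs(polygon_area(outline0[, 1], outline0[, 2])) < 1e-12) {
    stop("shape_strain_rate: degenerate outline")
  }
  v0 <- sweep(outline0, 2, colMeans(outline0))
  v1 <- sweep(outline1, 2, colMeans(outline1))
  x <- v0[, 1]; y <- v0[, 2]
  # unknowns (m11, m12, m22): x' = m11*x + m12*y ; y' = m12*x + m22*y
  A <- rbind(cbind(x, y, 0), cbind(0, x, y))
  b <- c(v1[, 1], v1[, 2])
  m <- stats::lm.fit(A, b)$coefficients
  M <- matrix(c(m[1], m[2], m[2], m[3]), 2, 2)
  Tns <- (M - diag(2)) / dt
  Tns <- (Tns + t(Tns)) / 2
  attr(Tns, "trace") <- sum(diag(Tns))
  Tns
}

#' Project a strain-rate tensor on an axis
#'
#' `n . T . n` for the unit vector along `axis`.
#'
#' @param tensor 2x2 symmetric tensor.
#' @param axis length-2 vector (any non-zero length).
#' @return scalar projection.
#' @export
project_strain_rate <- function(tensor, axis) {
  l <- sqrt(sum(axis^2))
  if (l == 0) stop("project_strain_rate: zero-length axis")
  nvec <- axis / l
  drop(t(nvec) %*% tensor %*% nvec)
}

#' Neighbour-phase effect on shape change, with a randomised null
#'
#' For every neighbour pair where both cells have fluctuating myosin, the
#' pair is classified by myosin-phase correlation; the focal cell's strain
#' rate projected on the centroid-centroid axis and its relative area rate
#' are binned by the focal myosin phase and averaged per class. The null
#' replaces each partner by a cell sampled uniformly from the other cells
#' present at the same time, preserving pair counts.
#'
#' @param ds an [embryo_dataset()] whose tracks carry neighbours, centroids
#'   and outline vertices (see [generate_neighbour_lattice()]).
#' @param config an [pipeline_config()] list (fluctuation thresholds,
#'   bootstrap settings).
#' @param seed integer seed for the null resampling and bootstrap.
#' @param n_phase_bins phase bins for the curves.
#' @param bandpass band-limit the rescaled myosin before peak detection
#'   (needs tracks much longer than the FIR; default FALSE).
#' @return list with `pairs` (per pair-instance table), `curves` (class x
#'   phase-bin means with bootstrap CIs) and `null_curves` (same, partners
#'   randomised).
#' @export
neighbour_effect_analysis <- function(ds, config = pipeline_config(),
                                      seed = 1, n_phase_bins = 8,
                                      bandpass = FALSE) {
  trk <- ds$tracks
  ids <- vapply(trk, `[[`, character(1), "cell_id")
  names(trk) <- ids
  dt <- uniform_step(trk[[1]]$time_s)
  bg_of <- function(tr) {
    if (is.null(ds$background)) return(0)
    b <- ds$background[ds$background$embryo_id == tr$embryo_id, ]
    if (!nrow(b)) return(0)
    stats::approx(b$time_s, b$background, xout = tr$time_s, rule = 2)$y
  }
  # per-cell: rescaled myosin, phase state, strain-rate tensors, area rate
  state <- lapply(trk, function(tr) {
    m <- tr$myosin - bg_of(tr)
    env <- myosin_envelope(m, dt, config$trend_window)
    cm <- m / env - 1
    if (bandpass) {
      cm2 <- bandpass_filter(cm, dt, config$band_low, config$band_high,
                             config$fir_taps, config$filter_passes)
      ok <- !is.na(cm2)
      cm[ok] <- cm2[ok]                 # keep edges unfiltered
    }
    ph <- myosin_phase(cm, dt, config$peak_min_separation,
                       config$fluct_cycle_range, config$fluct_threshold)
    n <- length(tr$time_s)
    tens <- vector("list", n)
    if (!is.null(tr$vertices)) {
      for (k in seq_len(n - 1)) {
        tens[[k]] <- shape_strain_rate(tr$vertices[[k]], tr$vertices[[k + 1]], dt)
      }
    }
    area_rate <- c(diff(tr$area_um2) / dt, NA) / tr$area_um2
    list(track = tr, phase = ph, tensors = tens, area_rate = area_rate)
  })
  build_pairs <- function(partner_of) {
    rows <- list()
    for (ci in ids) {
      st <- state[[ci]]
      tr <- st$track
      if (is.null(tr$neighbours)) next
      n <- length(tr$time_s)
      for (k in seq_len(n - 1)) {
        if (!st$phase$fluctuating[k]) next
        for (nb in partner_of(ci, k, tr$neighbours[[k]])) {
          stn <- state[[nb]]
          if (is.null(stn) || k > nrow(stn$phase) ||
              !isTRUE(stn$phase$fluctuating[k])) next
          rm_ <- pair_phase_correlation(st$phase$phase[k], stn$phase$phase[k])
          axis <- stn$track$centroid[k, ] - tr$centroid[k, ]
          psr <- if (!is.null(st$tensors[[k]]))
            project_strain_rate(st$tensors[[k]], axis) else NA_real_
          rows[[length(rows) + 1]] <- data.table::data.table(
            focal_id = ci, neighbour_id = nb, time_s = tr$time_s[k],
            focal_phase = st$phase$phase[k], r_m = rm_,
            pair_axis_strain_rate = psr, focal_area_rate = st$area_rate[k]
          )
        }
      }
    }
    p <- data.table::rbindlist(rows)
    if (nrow(p)) p$phase_class <- classify_rm(p$r_m)
    p
  }
  pairs <- build_pairs(function(ci, k, nbrs) intersect(nbrs, ids))
  null_pairs <- withr::with_seed(seed, {
    build_pairs(function(ci, k, nbrs) {
      pool <- setdiff(ids, ci)
      pool[sample.int(length(pool), length(intersect(nbrs, ids)),
                      replace = FALSE)]
    })
  })
  curve <- function(p, tag) {
    if (!nrow(p)) return(data.table::data.table())
    p$phase_bin <- pmin(base::floor(p$focal_phase / (2 * pi / n_phase_bins)),
                        n_phase_bins - 1L)
    cv <- p[, {
      bs <- suppressWarnings(hierarchical_bootstrap(
        pair_axis_strain_rate, rep("e", .N), focal_id,
        n_boot = config$bootstrap_n, level = config$ci_level,
        seed = bin_seed(seed, .GRP)))
      ba <- suppressWarnings(hierarchical_bootstrap(
        focal_area_rate, rep("e", .N), focal_id,
        n_boot = config$bootstrap_n, level = config$ci_level,
        seed = bin_seed(seed, .GRP) + 1L))
      list(pair_axis_strain_rate = bs$estimate,
           psr_lo = bs$ci_low, psr_hi = bs$ci_high,
           area_rate = ba$estimate, ar_lo = ba$ci_low, ar_hi = ba$ci_high,
           n_obs = .N)
    }, by = c("phase_class", "phase_bin")]
    cv$phase <- (cv$phase_bin + 0.5) * 2 * pi / n_phase_bins
    cv$which <- tag
    data.table::setorderv(cv, c("phase_class", "phase_bin"))
    cv
  }
  list(pairs = pairs, curves = curve(pairs, "observed"),
       null_curves = curve(null_pairs, "null"))
}

utils::globalVariables(c("pair_axis_strain_rate", "focal_id",
                         "focal_area_rate", "phase_class", "phase_bin"))
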
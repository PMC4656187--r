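dt <- 10

test_that("sliding Fourier amplitudes are normalised, linear and resolve two tones", {
  t <- seq(0, 6000, by = dt)
  # zero signal -> all amplitudes zero
  z <- sliding_fourier(rep(0, length(t)), dt, c(3e-3, 5e-3))
  expect_true(all(z$amplitude == 0))
  # unit sinusoid -> amplitude 1 within 2 %
  sf <- sliding_fourier(cos(2 * pi * 5e-3 * t), dt, 5e-3)
  expect_equal(mean(sf$amplitude), 1, tolerance = 0.02)
  # window centres advance in steps of 1/(2 nu)
  expect_equal(unique(diff(sf$t)), 1 / (2 * 5e-3), tolerance = 0.1)
  # two tones resolved within 5 %
  x2 <- 0.4 * cos(2 * pi * 3e-3 * t) + 0.1 * cos(2 * pi * 9e-3 * t)
  sf2 <- sliding_fourier(x2, dt, c(3e-3, 9e-3))
  expect_equal(mean(sf2$amplitude[sf2$freq == 3e-3]), 0.4, tolerance = 0.05)
  expect_equal(mean(sf2$amplitude[sf2$freq == 9e-3]), 0.1, tolerance = 0.05)
  # linearity: scaling the input scales all amplitudes
  sf3 <- sliding_fourier(3 * x2, dt, c(3e-3, 9e-3))
  expect_equal(sf3$amplitude, 3 * sf2$amplitude, tolerance = 1e-9)
  # the two amplitude estimators agree within 3 % on clean sinusoids
  sfc <- sliding_fourier(cos(2 * pi * 5e-3 * t), dt, 5e-3,
                         estimator = "coefficient")
  expect_equal(mean(sf$amplitude / sfc$amplitude), 1, tolerance = 0.03)
})

test_that("band phase lag recovers injected lags and time shifts", {
  t <- seq(0, 6000, by = dt)
  x <- cos(2 * pi * 6e-3 * t)
  # identical signals -> lag 0 (mod 2pi)
  l0 <- band_phase_lag(x, x, dt, 6e-3)
  expect_lt(max(abs(angle_diff(l0, 0)), na.rm = TRUE), 1e-6)
  # antiphase -> pi
  lpi <- band_phase_lag(x, -x, dt, 6e-3)
  expect_lt(max(abs(angle_diff(lpi, pi)), na.rm = TRUE), 1e-6)
  # injected lag pi/3 recovered within 0.03 rad
  lg <- band_phase_lag(x, cos(2 * pi * 6e-3 * t + pi / 3), dt, 6e-3)
  expect_lt(max(abs(angle_diff(lg, pi / 3)), na.rm = TRUE), 0.03)
  # a time shift Dt appears as lag 2 pi nu Dt, at several frequencies
  for (nu in c(3e-3, 5e-3, 8e-3)) {
    xx <- cos(2 * pi * nu * t)
    yy <- cos(2 * pi * nu * (t - 30))      # shifted by 30 s
    lsh <- band_phase_lag(xx, yy, dt, nu)
    expect_lt(max(abs(angle_diff(lsh, -2 * pi * nu * 30)), na.rm = TRUE), 0.03)
  }
  # near-zero amplitude is masked, not reported as zero lag
  lz <- band_phase_lag(rep(1e-12, length(t)), x, dt, 6e-3)
  expect_true(anyNA(lz))
})

test_that("the strain spectrogram ridge follows the generator frequency schedule", {
  g <- generate_embryo(n_cells = 2, duration = 6000,
                       scenario = clean_scenario(), seed = 31)
  cfg <- test_config()
  proc <- preprocess_dataset(g$dataset, cfg)
  comps <- spectral_components(proc, cfg)
  tt <- g$truth[g$truth$cell_id == g$truth$cell_id[1], ]
  # window centres differ per frequency, so compare within coarse time bins
  comps$tb <- base::floor(comps$t / 300) * 300 + 150
  # interior window centres only: the outermost bins hold truncated coverage
  tbr <- range(comps$tb)
  comps <- comps[comps$tb > tbr[1] & comps$tb < tbr[2], ]
  ridge <- comps[, list(freq = freq[which.max(strain_amp)]),
                 by = c("cell_id", "tb")]
  ridge$true_nu <- stats::approx(tt$time_s, tt$freq_hz, ridge$tb)$y
  # within one grid step, plus the frequency drift across the bin
  drift <- (6.54e-3 - 3.51e-3) / 6000 * 150
  expect_true(all(abs(ridge$freq - ridge$true_nu) <=
                    cfg$freq_resolution + drift + 1e-12))
})

test_that("strain attenuates over time while myosin amplitude does not", {
  # the generator's asymmetry: late/early dominant-amplitude ratio is lower
  # for strain than for myosin
  g <- generate_embryo(n_cells = 4, duration = 6000,
                       scenario = clean_scenario(), seed = 32)
  comps <- spectral_components(preprocess_dataset(g$dataset, test_config()),
                               test_config())
  comps$tb <- base::floor(comps$t / 300)
  tbr <- range(comps$tb)
  comps <- comps[comps$tb > tbr[1] & comps$tb < tbr[2], ]
  dom <- comps[, list(s = max(strain_amp), m = max(myosin_amp)),
               by = c("cell_id", "tb")]
  early <- dom$tb <= stats::quantile(dom$tb, 0.25)
  late <- dom$tb >= stats::quantile(dom$tb, 0.75)
  ratio_s <- mean(dom$s[late]) / mean(dom$s[early])
  ratio_m <- mean(dom$m[late]) / mean(dom$m[early])
  expect_lt(ratio_s, ratio_m)
  expect_lt(ratio_s, 1)
})

test_that("wavelet coherence separates coherent pairs from independent noise
           and decreases with SNR", {
  t <- seq(0, 5000, by = dt)
  cfg <- test_config()
  x <- cos(2 * pi * 5e-3 * t)
  wc <- wavelet_coherence(x, 0.5 * cos(2 * pi * 5e-3 * t - 1), dt, cfg)
  i5 <- which.min(abs(wc$freq - 5e-3))
  expect_gte(stats::quantile(wc$coherence[i5, ], 0.1, na.rm = TRUE), 0.95)
  cohm <- vapply(c(4, 1, 0.25), function(snr) {
    withr::with_seed(3, {
      xx <- x + stats::rnorm(length(t), 0, 1 / snr)
      yy <- 0.5 * cos(2 * pi * 5e-3 * t - 1) +
        stats::rnorm(length(t), 0, 0.5 / snr)
      stats::median(wavelet_coherence(xx, yy, dt, cfg)$coherence[i5, ],
                    na.rm = TRUE)
    })
  }, numeric(1))
  expect_true(all(diff(cohm) < 0))
  expect_error(wavelet_coherence(rep(0, 100), rep(0, 100), dt, cfg),
               "zero-variance")
})

test_that("independent noise falls below the resampling null threshold", {
  t <- seq(0, 5000, by = dt)
  cfg <- test_config()
  cells <- withr::with_seed(8, {
    stats::setNames(lapply(1:6, function(i)
      list(strain = stats::rnorm(length(t)), myosin = stats::rnorm(length(t)))),
      paste0("c", 1:6))
  })
  proc <- proc_table(cells, t)
  cn <- coherence_null(proc, cfg, n_iter = 300, seed = 2)
  expect_true(all(cn$threshold > 0 & cn$threshold < 1, na.rm = TRUE))
  wp <- wavelet_coherence(cells$c1$strain, cells$c1$myosin, dt, cfg)
  below <- sweep(wp$coherence, 2, cn$threshold, "<")
  expect_gte(mean(below, na.rm = TRUE), 0.85)
  # convergence: 150 vs 300 iterations agree closely
  cn2 <- coherence_null(proc, cfg, n_iter = 150, seed = 3)
  expect_lt(stats::median(abs(cn2$threshold - cn$threshold), na.rm = TRUE), 0.02)
  expect_error(coherence_null(proc[proc$cell_id == "c1", ], cfg, 10, 1),
               "two cells")
})

test_that("hysteresis loops have the analytic ellipse area and tighten as
           the lag approaches pi", {
  t <- seq(0, 30000, by = dt)
  th <- 2 * pi * 8e-3 * t
  a <- 0.05; c0 <- 0.2
  area_at <- function(lag) {
    proc <- proc_table(list(c1 = list(strain = a * cos(th),
                                      myosin = c0 * cos(th + lag))), t)
    hysteresis_loops(proc, pipeline_config(loop_bin = 1e9))$areas$area
  }
  # lag pi/2: |area| = pi*a*c0 within 3 %
  expect_equal(abs(area_at(pi / 2)), pi * a * c0, tolerance = 0.03)
  # lag 0: degenerate loop, area ~ 0
  expect_lt(abs(area_at(0)), 0.05 * pi * a * c0)
  # tightness |area|/(a*c0) decreases monotonically as lag -> pi
  areas <- abs(vapply(c(pi / 2, 3 * pi / 4, 0.9 * pi), area_at, numeric(1)))
  expect_true(all(diff(areas) < 0))
  # lag pi vs pi + 0.4: the loop at pi is tighter
  expect_lt(abs(area_at(pi)), abs(area_at(pi + 0.4)))
})
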
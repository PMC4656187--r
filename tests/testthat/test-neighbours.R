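dt <- 10

test_that("myosin phase interpolates linearly between peaks with correct
           cycle statistics", {
  # cosine of period 150 s
  t <- seq(0, 3000, by = dt)
  m <- 0.4 * cos(2 * pi * t / 150)
  ph <- myosin_phase(m, dt)
  ok <- !is.na(ph$phase)
  expect_true(all(abs(ph$cycle_length[ok] - 150) <= 10))
  # phases advance uniformly: steps of 2*pi*dt/150 except at wraps
  dphi <- diff(ph$phase[ok]) %% (2 * pi)
  expect_lt(max(abs(dphi - 2 * pi * dt / 150)), 0.05)
  # peaks 120 s apart (at 30 and 150 s) -> phase pi midway, pi/2 a quarter in
  m2 <- cos(2 * pi * (seq(0, 240, by = dt) - 30) / 120)
  ph2 <- myosin_phase(m2, dt)
  expect_equal(ph2$phase[10], pi)        # t = 90 s, midway
  expect_equal(ph2$phase[7], pi / 2)     # t = 60 s, quarter cycle
  # fluctuation thresholds: cycle 90 s in [60, 360] and amp*freq 0.4 > 0.3
  m3 <- 0.6 * cos(2 * pi * t / 90)       # amp 0.6 * (60/90) = 0.4
  ph3 <- myosin_phase(m3, dt)
  expect_true(any(ph3$fluctuating))
  # weak fluctuation fails the threshold
  m4 <- 0.1 * cos(2 * pi * t / 90)       # amp*freq = 0.067
  expect_false(any(myosin_phase(m4, dt)$fluctuating))
  # fewer than two peaks -> all phases undefined
  expect_true(all(is.na(myosin_phase(rep(0.5, 30), dt)$phase)))
})

test_that("pair phase correlation maps phase differences onto [-1, 1]", {
  expect_equal(pair_phase_correlation(1.2, 1.2), 1)
  expect_equal(pair_phase_correlation(0, pi), -1)
  expect_equal(pair_phase_correlation(0, pi / 2), 0)
  expect_equal(pair_phase_correlation(0.3, 1.4),
               pair_phase_correlation(1.4, 0.3))  # symmetric
  expect_equal(as.character(classify_rm(c(1, 0, -1, 0.2, -0.2))),
               c("correlated", "uncorrelated", "anti-correlated",
                 "uncorrelated", "uncorrelated"))
  # thresholds partition [-1, 1] with no gaps
  r <- seq(-1, 1, by = 0.01)
  expect_false(anyNA(classify_rm(r)))
})

test_that("the shape strain-rate tensor recovers canonical deformations", {
  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  # identity motion -> zero tensor
  T0 <- shape_strain_rate(sq, sq, 10)
  expect_equal(max(abs(T0)), 0)
  # uniform scaling by (1 + s)
  s <- 0.04
  T1 <- shape_strain_rate(sq, (1 + s) * sq, 10)
  expect_equal(T1, (s / 10) * diag(2), ignore_attr = TRUE)
  expect_equal(attr(T1, "trace"), 2 * s / 10)
  # pure shear: trace ~ 0, eigenvalues +-s/dt to first order
  T2 <- shape_strain_rate(sq, cbind(sq[, 1] * (1 + s), sq[, 2] / (1 + s)), 10)
  expect_lt(abs(attr(T2, "trace")), 2 * s^2 / 10)
  expect_equal(sort(eigen(T2)$values), sort(c(-s, s) / 10), tolerance = s)
  expect_error(shape_strain_rate(cbind(c(0, 0, 0), c(0, 0, 0)), sq[1:3, ], 10),
               "degenerate")
  # trace equals relative polygon-area rate within 2 % for small steps
  g <- generate_neighbour_lattice(3, 3, "uncorrelated", seed = 5)
  tr <- g$dataset$tracks[[5]]
  for (k in c(10, 60, 110)) {
    Tk <- shape_strain_rate(tr$vertices[[k]], tr$vertices[[k + 1]], dt)
    ar <- (tr$area_um2[k + 1] - tr$area_um2[k]) / dt / tr$area_um2[k]
    expect_equal(attr(Tk, "trace"), ar, tolerance = 0.02)
  }
})

test_that("tensor projection obeys the rotation algebra", {
  Td <- diag(c(3, -1))
  expect_equal(project_strain_rate(Td, c(1, 0)), 3)
  expect_equal(project_strain_rate(Td, c(1, 1)), 1)          # (a+b)/2
  # even in the axis direction
  A <- matrix(c(1.2, 0.4, 0.4, -0.7), 2, 2)
  v <- c(0.3, -0.8)
  expect_equal(project_strain_rate(A, v), project_strain_rate(A, -v))
  expect_error(project_strain_rate(Td, c(0, 0)), "zero-length")
})

test_that("anti-correlated lattices double the pair-axis strain-rate
           amplitude of correlated ones", {
  cfg <- test_config(bootstrap_n = 100)
  g1 <- generate_neighbour_lattice(4, 4, "correlated", seed = 1)
  g2 <- generate_neighbour_lattice(4, 4, "anti-correlated", seed = 1)
  na1 <- neighbour_effect_analysis(g1$dataset, cfg, seed = 2)
  na2 <- neighbour_effect_analysis(g2$dataset, cfg, seed = 2)
  expect_equal(unique(na1$pairs$r_m), 1)
  expect_equal(unique(na2$pairs$r_m), -1)
  ampl <- function(cv, cls) {
    v <- cv[cv$phase_class == cls, ]$pair_axis_strain_rate
    (max(v) - min(v)) / 2
  }
  ratio <- ampl(na2$curves, "anti-correlated") / ampl(na1$curves, "correlated")
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("class dependence vanishes for uncoupled cells and under the
           randomised-partner null", {
  cfg <- test_config(bootstrap_n = 100)
  g0 <- generate_neighbour_lattice(4, 4, "uncorrelated", seed = 3,
                                   coupling = 0)
  na0 <- neighbour_effect_analysis(g0$dataset, cfg, seed = 4)
  cv <- na0$curves
  # per phase bin, class means agree within the bootstrap interval widths
  for (pb in unique(cv$phase_bin)) {
    sl <- cv[cv$phase_bin == pb, ]
    if (nrow(sl) < 2) next
    spread <- max(sl$pair_axis_strain_rate) - min(sl$pair_axis_strain_rate)
    width <- max(sl$psr_hi - sl$psr_lo)
    expect_lt(spread, 3 * width)
  }
  # null curves exist and have the same structure as observed ones
  expect_setequal(names(na0$null_curves), names(na0$curves))
  expect_gt(nrow(na0$null_curves), 0)
})
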
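test_that("ADE coefficients reduce to the classical Drude update at alpha = beta = 1", {
  m <- fig1_medium()
  cc <- ade_coefficients(m, dt = 0.5, n_terms = 8)
  # closed-form classical coefficients: 2/(1 + g dt/2), -(1 - g dt/2)/(1 + g dt/2)
  expect_equal(cc$coef_P_t, 2 / 1.025, tolerance = 1e-14)
  expect_equal(cc$coef_P_tm1, -0.975 / 1.025, tolerance = 1e-14)
  expect_equal(cc$coef_E, 0.09 * 0.25 / 1.025, tolerance = 1e-14)
  # all memory weights beyond the two-term recurrence vanish
  expect_equal(cc$mem_alpha, rep(0, 7))
  expect_equal(cc$mem_beta, rep(0, 7))
  expect_equal(cc$coef_hist[3:9], rep(0, 7))
})

test_that("ADE coefficients are finite with the expected drive sign", {
  m <- fractional_drude_medium(0.25, 1, 0.3, alpha = 0.5, beta = 0.5)
  for (dt in c(0.05, 0.5, 1)) {
    cc <- ade_coefficients(m, dt, 16)
    expect_true(all(is.finite(cc$coef_hist)))
    expect_gt(cc$coef_E, 0)
    expect_gt(cc$denom, 0)
  }
  expect_error(ade_coefficients(m, -0.1, 16), "positive")
  expect_error(ade_coefficients(m, 0.5, 0), "at least 1")
})

test_that("fractional stepper at alpha = beta = 1 matches an independent classical Drude FDTD", {
  m <- fig1_medium()
  dt <- 0.5; n_steps <- 2000
  grid <- grid1d(400, med_start = 150, med_end = 399, src_pos = 60)
  src <- source_spec("monochromatic_soft", omega = 0.2, ramp_cycles = 10)
  rec <- fdtd_run(grid, ade_coefficients(m, dt, 32), src, n_steps, 170)
  ref <- drude_fdtd_reference(400, 150, 399, dt, wp2 = 0.09, g = 0.1,
                              n_steps = n_steps, src_pos = 60, omega = 0.2,
                              probe = 170)
  expect_false(rec$diverged)
  expect_lt(max(abs(rec$e[, 1] - ref$e)), 1e-10)
  expect_lt(max(abs(rec$p[, 1] - ref$p)), 1e-10)
})

test_that("a vacuum pulse propagates at c with its peak preserved", {
  grid <- grid1d(700, src_pos = 100)
  src <- source_spec("gaussian_pulse", amplitude = 1, pulse_center = 40,
                     pulse_width = 10)
  rec <- fdtd_run(grid, NULL, src, 1400, probe_cells = c(150, 550), dt = 0.5)
  t1 <- which.max(rec$e[, 1]); t2 <- which.max(rec$e[, 2])
  speed <- (550 - 150) / ((t2 - t1) * 0.5)
  expect_equal(speed, 1, tolerance = 0.02)
  peak_ratio <- max(rec$e[, 2]) / max(rec$e[, 1])
  expect_gt(peak_ratio, 0.99)
  # causality: nothing beyond the Gaussian's far tail arrives at a probe
  # before light can reach it
  early <- rec$e[seq_len(floor((150 - 100) / 0.5) - 2), 1]
  expect_lt(max(abs(early)), 1e-6)
})

test_that("the all-zero state with no source is a fixed point", {
  m <- fig1_medium(0.7, 0.4)
  grid <- grid1d(100, med_start = 30, med_end = 80, src_pos = 5)
  src <- source_spec("monochromatic_soft", omega = 0.2, amplitude = 0)
  rec <- fdtd_run(grid, ade_coefficients(m, 0.5, 16), src, 300, 50)
  expect_true(all(rec$e == 0))
  expect_true(all(rec$p == 0))
})

test_that("vacuum field energy never grows once the source is quiet", {
  grid <- grid1d(600, src_pos = 300)
  src <- source_spec("gaussian_pulse", amplitude = 1, pulse_center = 30,
                     pulse_width = 8)
  rec <- fdtd_run(grid, NULL, src, 1200, 300, dt = 0.5, record_energy = TRUE)
  quiet <- seq.int(ceiling((30 + 5 * 8) / 0.5), 1200)
  en <- rec$energy[quiet]
  expect_true(all(diff(en) <= 1e-12 * en[1]))
})

test_that("super-Courant time steps trip the divergence flag", {
  m <- fig1_medium()
  grid <- grid1d(300, med_start = 100, med_end = 299, src_pos = 50)
  src <- source_spec("monochromatic_soft", omega = 0.2)
  rec <- fdtd_run(grid, ade_coefficients(m, 1.1, 8), src, 4000, 120)
  expect_true(rec$diverged)
  expect_lt(rec$steps_done, 4000)
})

test_that("grid and probe validation", {
  expect_error(grid1d(300, med_start = 1, med_end = 100), "inside")
  expect_error(grid1d(3), "short")
  grid <- grid1d(100, src_pos = 10)
  src <- source_spec("monochromatic_soft", omega = 0.3)
  expect_error(fdtd_run(grid, NULL, src, 10, probe_cells = 101, dt = 0.5),
               "probe")
  expect_error(source_spec("monochromatic_soft"), "omega")
})
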
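# reported soft-tissue orders (alpha = 0.31, beta = 0.04); wp2 sized so the
# spectrum has blood-like amplitude (eps' falling from ~2300 to ~60 across
# 1e7-1e10 Hz, conductivity rising above its dc floor). wp2 > 0 here: under
# the consistent e^{-iwt} convention the anomalous-dispersion branch carries
# the opposite sign from the engineering-convention report.
synthetic_truth <- function(wp2 = 1880) {
  fractional_drude_medium(omega_p_sq = wp2, gamma_alpha = 13,
                          gamma_beta = 0.99, alpha = 0.31, beta = 0.04,
                          eps_inf = 61.6, sigma_dc = 1.33)
}

truth_spectrum <- function(noise_seed = NULL, noise = 0, wp2 = 1880) {
  truth <- synthetic_truth(wp2)
  f <- 10^seq(7, 10, length.out = 40)
  ch <- fracdrude:::.model_channels(truth, f, 2 * pi * 1e9, "conductivity")
  er <- ch$eps_real; lo <- ch$loss
  if (noise > 0) {
    set.seed(noise_seed)
    er <- er * rnorm(length(f), 1, noise)
    lo <- lo * rnorm(length(f), 1, noise)
  }
  spectrum_data(f, er, lo, "conductivity")
}

test_that("the synthetic spectrum generator is deterministic and anomalous", {
  a <- generate_synthetic_spectrum(seed = 11)
  b <- generate_synthetic_spectrum(seed = 11)
  expect_identical(a, b)
  d <- generate_synthetic_spectrum(seed = 12)
  expect_false(identical(a$eps_real, d$eps_real))

  clean <- generate_synthetic_spectrum(noise_rel_sd = 0)
  clean2 <- generate_synthetic_spectrum(noise_rel_sd = 0, seed = 99)
  expect_identical(clean, clean2)          # noiseless: seed-independent
  # broad anomalous dispersion across the tabulated band
  expect_gte(mean(diff(clean$eps_real) < 0), 0.9)
  expect_true(all(diff(clean$freq_hz) > 0))
  expect_error(generate_synthetic_spectrum(n_points = 4), "n_points")
})

test_that("noiseless self-generated spectra are recovered exactly", {
  dat <- truth_spectrum()
  fit <- fit_fractional_drude(dat, n_starts = 8, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$residual, 1e-6)
  expect_lt(abs(fit$params$alpha - 0.31), 0.02)
  expect_lt(abs(fit$params$beta - 0.04), 0.02)

  # the signed-wp2 branch: a low-amplitude negative-wp2 truth is also
  # recovered, with the sign intact
  dat2 <- truth_spectrum(wp2 = -3.5)
  fit2 <- fit_fractional_drude(dat2, n_starts = 8, seed = 2)
  expect_lt(fit2$residual, 1e-6)
  expect_lt(abs(fit2$params$alpha - 0.31), 0.02)
  expect_lt(fit2$params$omega_p_sq, 0)
})

test_that("1% noise still pins the fractional orders to within 0.1", {
  dat <- truth_spectrum(noise_seed = 42, noise = 0.01)
  fit <- fit_fractional_drude(dat, n_starts = 8, seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha - 0.31), 0.1)
  expect_lt(abs(fit$params$beta - 0.04), 0.1)
})

test_that("the standard-Drude fit recovers classical truth and respects its constraints", {
  truth <- fractional_drude_medium(omega_p_sq = -50, gamma_alpha = 1,
                                   gamma_beta = 2.3, alpha = 1, beta = 1,
                                   eps_inf = 20, sigma_dc = 0.4)
  f <- 10^seq(7, 10, length.out = 40)
  ch <- fracdrude:::.model_channels(truth, f, 2 * pi * 1e9, "conductivity")
  dat <- spectrum_data(f, ch$eps_real, ch$loss, "conductivity")
  fit <- fit_standard_drude(dat, n_starts = 8, seed = 3)
  expect_true(fit$converged)
  expect_equal(fit$params$alpha, 1)
  expect_equal(fit$params$beta, 1)
  expect_equal(fit$params$gamma_alpha, 1)
  expect_lt(abs(fit$params$gamma_beta - 2.3) / 2.3, 0.01)
  expect_lt(abs(fit$params$omega_p_sq - (-50)) / 50, 0.01)
  expect_lt(abs(fit$params$eps_inf - 20) / 20, 0.01)
})

test_that("the nested-model residual inequality holds on blood-like spectra", {
  sp <- generate_synthetic_spectrum(noise_rel_sd = 0.01, seed = 7)
  fd <- fit_standard_drude(sp, n_starts = 8, seed = 3)
  ff <- fit_fractional_drude(sp, n_starts = 8, seed = 3,
                             extra_starts = list(drude_start(fd)))
  expect_lte(ff$residual, fd$residual)
  # fitted parameters stay inside the declared stability bounds
  expect_gt(ff$params$alpha, 0)
  expect_lt(ff$params$alpha, 2)
  expect_gte(ff$params$beta, 0)
  expect_lt(ff$params$beta, 1.3)
})

test_that("spectrum containers validate their invariants", {
  expect_error(spectrum_data(c(1, 2), c(1, 2, 3), c(1, 2)), "equal length")
  expect_error(spectrum_data(c(2, 1), c(1, 2), c(1, 2)), "increasing")
  expect_error(fit_fractional_drude(
    spectrum_data(1:5, rep(1, 5), rep(1, 5)), n_starts = 2), "at least 8")
})
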
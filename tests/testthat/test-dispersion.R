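test_that("fractional susceptibility reduces to the classical Drude form", {
  m <- fig1_medium()
  # direct complex arithmetic oracle: chi = -wp^2 / (w^2 + i g w)
  expect_equal(susceptibility(m, 0.3), -0.9 + 0.3i, tolerance = 1e-14)
  w <- exp(seq(log(0.01), log(10), length.out = 50))
  chi_oracle <- -0.09 / (w^2 + 1i * 0.1 * w)
  expect_equal(susceptibility(m, w), chi_oracle, tolerance = 1e-14)

  # lossless limit is purely real -wp^2/w^2
  m0 <- fractional_drude_medium(0.09, 1, 0, 1, 1)
  expect_equal(susceptibility(m0, w), complex(real = -0.09 / w^2),
               tolerance = 1e-14)
})

test_that("alpha = beta = 0 with unit gamma_beta gives a Debye-type relaxation", {
  # chi = wp2 / (ga (-iw) + 1): delta_eps = +wp2, tau = ga
  tau <- 2.5; de <- 0.7
  m <- fractional_drude_medium(de, tau, 1, alpha = 0, beta = 0)
  w <- c(0.1, 1 / tau, 3)
  expect_equal(susceptibility(m, w), de / (1 - 1i * w * tau),
               tolerance = 1e-14)
})

test_that("permittivity has the high-frequency asymptote and conduction term", {
  m <- fractional_drude_medium(0.09, 1, 0.1, 1, 1, eps_inf = 1)
  wp <- 0.3
  expect_lt(abs(permittivity(m, 1e6 * wp) - 1), 1e-6)
  expect_lt(Mod(susceptibility(m, 1e6 * wp)), 1e-6)

  ms <- fractional_drude_medium(0.09, 1, 0.1, 1, 1, eps_inf = 4, sigma_dc = 2)
  w <- 0.7
  expect_equal(permittivity(ms, w),
               4 + susceptibility(ms, w) + 2i / w, tolerance = 1e-14)
})

test_that("anomalous dispersion at the reported soft-tissue parameter set", {
  # blood-like fit parameters; frequencies in the same (Hz) unit system
  m <- fractional_drude_medium(omega_p_sq = -(1e7)^2, gamma_alpha = 13,
                               gamma_beta = 0.99, alpha = 0.31, beta = 0.04,
                               eps_inf = 61.6, sigma_dc = 1.33)
  w <- c(1e8, 1.01e8)
  eps <- permittivity(m, w, unit_system(eps0 = 8.8541878128e-12))
  expect_true(all(is.finite(Re(eps)) & is.finite(Im(eps))))
  expect_lt(Re(eps[2]), Re(eps[1]))   # d Re(eps) / d w < 0
})

test_that("reference relaxation models nest into each other", {
  w20 <- exp(seq(log(0.01), log(100), length.out = 20))
  # Debye at w tau = 1 equals eps_inf + de (1 + i)/2 (physics convention)
  d <- debye_params(eps_inf = 2, delta_eps = 10, tau = 0.5)
  expect_equal(reference_permittivity(d, 2), 2 + 10 * (1 + 1i) / 2,
               tolerance = 1e-14)
  # Cole-Cole with alpha_cc = 0 is exactly Debye
  cc0 <- cole_cole_params(2, 10, 0.5, alpha_cc = 0)
  expect_equal(reference_permittivity(cc0, w20),
               reference_permittivity(d, w20), tolerance = 1e-14)
  # Havriliak-Negami with both exponents 1 is Debye too
  hn1 <- hn_params(2, 10, 0.5, alpha_hn = 1, beta_hn = 1)
  expect_equal(reference_permittivity(hn1, w20),
               reference_permittivity(d, w20), tolerance = 1e-14)
})

test_that("wave vector picks the decaying root", {
  vac <- fractional_drude_medium(0, 1, 0, 1, 1)
  w <- c(0.2, 1, 5)
  expect_equal(wavevector(vac, w), complex(real = w), tolerance = 1e-14)

  # lossless Drude below the plasma frequency: evanescent, purely imaginary
  m0 <- fractional_drude_medium(0.09, 1, 1e-12, 1, 1)
  k <- wavevector(m0, 0.1)
  expect_lt(abs(Re(k)), 1e-6)
  expect_gt(Im(k), 0)

  # high-frequency expansion for alpha = 1, beta = 1:
  # k ~ (w/c)(1 - wp^2 gb w^{b}/(2 ga^2 w^4) ... ), Im k from the closed form
  m <- fig1_medium()
  w <- 1e3 * 0.3
  imk_approx <- (w) * 0.09 * 0.1 * w^(1) / (2 * 1 * w^4)
  expect_lt(abs(Im(wavevector(m, w)) - imk_approx) / imk_approx, 0.01)
})

test_that("predicted absorption power-law exponent is beta - 3", {
  expect_equal(imk_asymptotic_exponent(fig1_medium(1, 1)), -2)
  expect_equal(imk_asymptotic_exponent(fig1_medium(1, 0.5)), -2.5)
  expect_equal(imk_asymptotic_exponent(
    fractional_drude_medium(0.09, 1, 0.1, alpha = 0.01, beta = 1)), 0)
  expect_warning(imk_asymptotic_exponent(fig1_medium(0.5, 1)), "regime")
})

test_that("conductivity spectrum behaves like the classical Drude result", {
  # lossless medium conducts nothing
  m0 <- fractional_drude_medium(0.09, 1, 0, 1, 1)
  expect_equal(conductivity_spectrum(m0, c(0.1, 1, 10)), c(0, 0, 0))

  # high-frequency conductivity of the standard Drude model: Im chi ~
  # wp^2 g / w^3, so sigma = eps0 w Im chi ~ w^{-2}; log-log slope -2
  m <- fig1_medium()
  w <- exp(seq(log(100 * 0.3), log(1e4 * 0.3), length.out = 40))
  s <- conductivity_spectrum(m, w)
  slope <- unname(coef(lm(log(s) ~ log(w)))[2])
  expect_lt(abs(slope - (-2)), 0.05)

  # finite and continuous across w = wp for fractional beta
  m9 <- fig1_medium(1, 0.9)
  w <- seq(0.29, 0.31, length.out = 21)
  s <- conductivity_spectrum(m9, w)
  expect_true(all(is.finite(s)))
  expect_lt(max(abs(diff(s))), 0.05 * max(abs(s)))

  # passivity holds in the standard-Drude sub-case
  expect_true(all(conductivity_spectrum(m, exp(seq(-3, 3, 0.2))) >= 0))
})

test_that("beta = 0 turns the response into a resonance near sqrt(gb/ga)", {
  m <- fig1_medium(1, 0)
  w_res <- sqrt(0.1 / 1)
  re_lo <- Re(susceptibility(m, w_res * 0.99))
  re_hi <- Re(susceptibility(m, w_res * 1.01))
  expect_true(sign(re_lo) != sign(re_hi))   # sign change brackets resonance
})

test_that("engineering convention conjugates and omega <= 0 is rejected", {
  m <- fig1_medium()
  ue <- unit_system(convention = "engineering")
  expect_equal(susceptibility(m, 0.3, ue), Conj(susceptibility(m, 0.3)))
  expect_equal(permittivity(m, 0.4, ue), Conj(permittivity(m, 0.4)))
  expect_error(susceptibility(m, 0), "positive")
  expect_error(permittivity(m, -1), "positive")
  expect_error(reference_permittivity(debye_params(1, 1, 1), 0), "positive")
})

test_that("frequency-unit rescaling leaves the susceptibility invariant", {
  m <- fractional_drude_medium(-3.5, 13, 0.99, 0.31, 0.04, 61.6, 1.33)
  s <- 1e9
  m2 <- rescale_medium(m, s)
  w <- c(1e7, 1e8, 1e9)
  expect_equal(susceptibility(m2, w / s), susceptibility(m, w),
               tolerance = 1e-12)
})
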
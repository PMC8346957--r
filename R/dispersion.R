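# Closed-form frequency-domain material functions: the fractional Drude
# susceptibility/permittivity, reference relaxation models (Debye, Cole-Cole,
# Havriliak-Negami), wave vector and conductivity spectra.
#
# Internally everything uses the physics time-harmonic convention e^{-i w t},
# with the principal branch (-i w)^x = w^x e^{-i pi x / 2} for w > 0. The
# engineering convention e^{+i w t} is obtained by conjugation through the
# unit-system flag.

#' Fractional Drude medium
#'
#' The seven-parameter dielectric model in which the classical Drude equation
#' of motion for the polarization, \eqn{\ddot P + \gamma \dot P = \omega_p^2 E},
#' is generalised by replacing the two time derivatives with fractional
#' derivatives of orders \eqn{\alpha + 1} and \eqn{\beta}:
#' \deqn{\gamma_\alpha D^{\alpha+1} P + \gamma_\beta D^{\beta} P =
#'   \omega_p^2 E.}
#' The dimensional constants \eqn{\gamma_\alpha, \gamma_\beta} keep the
#' susceptibility dimensionless for non-integer orders. \eqn{\alpha = \beta =
#' \gamma_\alpha = 1} recovers the classical Drude model.
#'
#' @param omega_p_sq Squared plasma frequency \eqn{\omega_p^2}; may be
#'   negative (anomalous-dispersion fits to tissue use a negative value).
#' @param gamma_alpha Dimensional constant of the order-\eqn{\alpha+1} term;
#'   must be positive.
#' @param gamma_beta Dimensional damping constant of the order-\eqn{\beta}
#'   term; non-negative.
#' @param alpha,beta Fractional orders. The time-domain scheme is stable for
#'   \eqn{0 < \alpha < 2} and \eqn{0 \le \beta < 1.3} (plus the isolated
#'   integer point \eqn{\beta = 2}).
#' @param eps_inf High-frequency permittivity \eqn{\epsilon_\infty}.
#' @param sigma_dc Static conductivity \eqn{\sigma} (same frequency units as
#'   the rest of the parameter set).
#' @return An object of class `fractional_drude_medium`.
#' @examples
#' m <- fractional_drude_medium(omega_p_sq = 0.3^2, gamma_alpha = 1,
#'                              gamma_beta = 0.1, alpha = 1, beta = 1)
#' susceptibility(m, 0.3)   # -0.9 + 0.3i
#' @export
fractional_drude_medium <- function(omega_p_sq, gamma_alpha = 1,
                                    gamma_beta = 0.1, alpha = 1, beta = 1,
                                    eps_inf = 1, sigma_dc = 0) {
  vals <- c(omega_p_sq = omega_p_sq, gamma_alpha = gamma_alpha,
            gamma_beta = gamma_beta, alpha = alpha, beta = beta,
            eps_inf = eps_inf, sigma_dc = sigma_dc)
  if (!all(is.finite(vals)))
    stop("all medium parameters must be finite", call. = FALSE)
  if (gamma_alpha <= 0)
    stop("`gamma_alpha` must be positive", call. = FALSE)
  if (gamma_beta < 0)
    stop("`gamma_beta` must be non-negative", call. = FALSE)
  if (sigma_dc < 0)
    stop("`sigma_dc` must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "fractional_drude_medium")
}

#' @export
print.fractional_drude_medium <- function(x, ...) {
  cat("Fractional Drude medium\n")
  cat(sprintf("  omega_p^2 = %g  (|omega_p| = %g)\n",
              x$omega_p_sq, sqrt(abs(x$omega_p_sq))))
  cat(sprintf("  gamma_alpha = %g, gamma_beta = %g\n",
              x$gamma_alpha, x$gamma_beta))
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  cat(sprintf("  eps_inf = %g, sigma_dc = %g\n", x$eps_inf, x$sigma_dc))
  invisible(x)
}

#' Unit system and time-harmonic convention
#'
#' @param c Wave speed (default 1, normalized units).
#' @param eps0 Vacuum permittivity (default 1).
#' @param convention `"physics"` for \eqn{e^{-i\omega t}} (the internal
#'   canonical convention) or `"engineering"` for \eqn{e^{+i\omega t}}
#'   (returned quantities are conjugated).
#' @return An object of class `unit_system`.
#' @export
unit_system <- function(c = 1, eps0 = 1,
                        convention = c("physics", "engineering")) {
  convention <- match.arg(convention)
  if (c <= 0 || eps0 <= 0)
    stop("`c` and `eps0` must be positive", call. = FALSE)
  structure(list(c = c, eps0 = eps0, convention = convention),
            class = "unit_system")
}

.apply_convention <- function(z, units) {
  if (units$convention == "engineering") Conj(z) else z
}

.check_omega <- function(omega) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("`omega` must be finite and strictly positive ",
         "(electrostatics is not modelled)", call. = FALSE)
}

# principal branch (-i w)^x = w^x e^{-i pi x / 2}, w > 0
.neg_i_omega_pow <- function(omega, x) {
  omega^x * exp(complex(imaginary = -pi * x / 2))
}

#' Fractional Drude susceptibility
#'
#' Evaluates
#' \deqn{\chi(\omega) = \frac{\omega_p^2}
#'   {\gamma_\alpha(-i\omega)^{\alpha+1} + \gamma_\beta(-i\omega)^{\beta}}}
#' with principal-branch fractional powers, under the \eqn{e^{-i\omega t}}
#' convention (conjugated for an engineering unit system).
#'
#' @param medium A [fractional_drude_medium()].
#' @param omega Strictly positive frequencies (vectorised).
#' @param units A [unit_system()].
#' @return Complex vector of susceptibilities.
#' @export
susceptibility <- function(medium, omega, units = unit_system()) {
  .check_omega(omega)
  den <- medium$gamma_alpha * .neg_i_omega_pow(omega, medium$alpha + 1) +
    medium$gamma_beta * .neg_i_omega_pow(omega, medium$beta)
  if (any(den == 0))
    stop("susceptibility denominator vanishes at a requested frequency",
         call. = FALSE)
  .apply_convention(medium$omega_p_sq / den, units)
}

#' Fractional Drude complex permittivity
#'
#' \eqn{\epsilon(\omega) = \epsilon_\infty + \chi(\omega) +
#' i\sigma/(\omega\epsilon_0)} under the physics convention; the conduction
#' term adds positive imaginary part (absorption) for \eqn{\sigma > 0}.
#'
#' @inheritParams susceptibility
#' @return Complex vector of relative permittivities.
#' @export
permittivity <- function(medium, omega, units = unit_system()) {
  .check_omega(omega)
  chi <- susceptibility(medium, omega, unit_system(units$c, units$eps0))
  eps <- medium$eps_inf + chi +
    complex(imaginary = medium$sigma_dc / (omega * units$eps0))
  .apply_convention(eps, units)
}

#' Debye relaxation parameters
#' @param eps_inf High-frequency permittivity.
#' @param delta_eps Relaxation strength \eqn{\delta\epsilon}.
#' @param tau Relaxation time, positive.
#' @return An object of class `debye_params`.
#' @export
debye_params <- function(eps_inf, delta_eps, tau) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau),
            class = c("debye_params", "relaxation_params"))
}

#' Cole-Cole relaxation parameters
#' @inheritParams debye_params
#' @param alpha_cc Broadening exponent in \eqn{[0, 1)}; 0 recovers Debye.
#' @param sigma_dc Static conductivity, non-negative.
#' @return An object of class `cole_cole_params`.
#' @export
cole_cole_params <- function(eps_inf, delta_eps, tau, alpha_cc = 0,
                             sigma_dc = 0) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (alpha_cc < 0 || alpha_cc >= 1)
    stop("`alpha_cc` must lie in [0, 1)", call. = FALSE)
  if (sigma_dc < 0) stop("`sigma_dc` must be non-negative", call. = FALSE)
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau,
                 alpha_cc = alpha_cc, sigma_dc = sigma_dc),
            class = c("cole_cole_params", "relaxation_params"))
}

#' Havriliak-Negami relaxation parameters
#' @inheritParams debye_params
#' @param alpha_hn Shape exponent in \eqn{(0, 1]}.
#' @param beta_hn Asymmetry exponent in \eqn{(0, 1]}; `alpha_hn = 1` recovers
#'   Cole-Cole with `alpha_cc = 0`, and both equal to 1 recover Debye.
#' @return An object of class `hn_params`.
#' @export
hn_params <- function(eps_inf, delta_eps, tau, alpha_hn = 1, beta_hn = 1) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (alpha_hn <= 0 || alpha_hn > 1 || beta_hn <= 0 || beta_hn > 1)
    stop("`alpha_hn` and `beta_hn` must lie in (0, 1]", call. = FALSE)
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau,
                 alpha_hn = alpha_hn, beta_hn = beta_hn),
            class = c("hn_params", "relaxation_params"))
}

#' Reference relaxation-model permittivity
#'
#' Evaluates the Debye, Cole-Cole or Havriliak-Negami permittivity under the
#' same principal-branch and convention rules as the fractional Drude model,
#' for side-by-side comparison. Under the physics convention the Debye term
#' reads \eqn{\delta\epsilon/(1 - i\omega\tau)}.
#'
#' @param params A [debye_params()], [cole_cole_params()] or [hn_params()].
#' @param omega Strictly positive frequencies (vectorised).
#' @param units A [unit_system()].
#' @return Complex vector of relative permittivities.
#' @export
reference_permittivity <- function(params, omega, units = unit_system()) {
  .check_omega(omega)
  eps <- if (inherits(params, "debye_params")) {
    params$eps_inf + params$delta_eps / (1 - 1i * omega * params$tau)
  } else if (inherits(params, "cole_cole_params")) {
    params$eps_inf +
      params$delta_eps /
        (1 + .neg_i_omega_pow(omega * params$tau, 1 - params$alpha_cc)) +
      complex(imaginary = params$sigma_dc / (omega * units$eps0))
  } else if (inherits(params, "hn_params")) {
    params$eps_inf +
      params$delta_eps /
        (1 + .neg_i_omega_pow(omega * params$tau, params$alpha_hn))^params$beta_hn
  } else {
    stop("unknown relaxation parameter class", call. = FALSE)
  }
  .apply_convention(eps, units)
}

#' Complex wave vector
#'
#' \eqn{k(\omega) = (\omega/c)\sqrt{\epsilon(\omega)}}, taking the root with
#' \eqn{\mathrm{Im}\,k \ge 0} (forward wave decaying in its direction of
#' propagation). Below the plasma frequency of a low-loss Drude medium the
#' permittivity is negative and \eqn{k} is (almost) purely imaginary —
#' evanescent, strongly absorbed waves.
#'
#' @inheritParams susceptibility
#' @return Complex vector of wave numbers.
#' @export
wavevector <- function(medium, omega, units = unit_system()) {
  eps <- permittivity(medium, omega, unit_system(units$c, units$eps0))
  k <- (omega / units$c) * sqrt(eps)
  k <- ifelse(Im(k) < 0, -k, k)
  .apply_convention(k, units)
}

#' Predicted high-frequency log-log slope of Im k
#'
#' For \eqn{\alpha = 1} and \eqn{\beta} near 1 the high-frequency expansion
#' of the wave vector gives a power-law absorption
#' \eqn{\mathrm{Im}\,k \sim \omega^{\beta - 3}}; the function returns
#' \eqn{\beta - 3}. In the opposite limit \eqn{\alpha \to 0} the absorption
#' becomes frequency-independent and 0 is returned. A warning flags use
#' outside the stated regime of validity.
#'
#' @param medium A [fractional_drude_medium()].
#' @return The predicted slope (a real number).
#' @export
imk_asymptotic_exponent <- function(medium) {
  if (abs(medium$alpha) < 0.05) return(0)
  if (abs(medium$alpha - 1) > 1e-8 || abs(medium$beta - 1) > 0.5)
    warning("power-law exponent beta - 3 is derived for alpha = 1, ",
            "beta near 1; parameters are outside this regime",
            call. = FALSE)
  medium$beta - 3
}

#' Conductivity spectrum
#'
#' The dynamic conductivity \eqn{\sigma(\omega) = \epsilon_0\,\omega\,
#' \mathrm{Im}\,\chi(\omega)}, non-negative for passive media in the
#' standard-Drude sub-case.
#'
#' @inheritParams susceptibility
#' @return Real vector of conductivities.
#' @export
conductivity_spectrum <- function(medium, omega, units = unit_system()) {
  chi <- susceptibility(medium, omega, unit_system(units$c, units$eps0))
  units$eps0 * omega * Im(chi)
}

#' Rescale a medium to a new frequency unit
#'
#' Re-expresses the parameter set for frequencies measured in units of
#' `omega / scale`: \eqn{\gamma_\alpha \to \gamma_\alpha s^{\alpha+1}},
#' \eqn{\gamma_\beta \to \gamma_\beta s^{\beta}},
#' \eqn{\omega_p^2 \to \omega_p^2} (dimensionless \eqn{\chi} preserved) and
#' \eqn{\sigma \to \sigma/s}. `susceptibility(rescale_medium(m, s), w/s)`
#' equals `susceptibility(m, w)`.
#'
#' @param medium A [fractional_drude_medium()].
#' @param scale Positive rescaling factor \eqn{s}.
#' @return A rescaled `fractional_drude_medium`.
#' @export
rescale_medium <- function(medium, scale) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  fractional_drude_medium(
    omega_p_sq = medium$omega_p_sq,
    gamma_alpha = medium$gamma_alpha * scale^(medium$alpha + 1),
    gamma_beta = medium$gamma_beta * scale^medium$beta,
    alpha = medium$alpha, beta = medium$beta,
    eps_inf = medium$eps_inf,
    sigma_dc = medium$sigma_dc / scale
  )
}
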
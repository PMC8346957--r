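# Fitting the fractional Drude model (and the nested standard-Drude special
# case) to broadband tissue permittivity spectra, with a synthetic two-term
# Cole-Cole spectrum generator for download-free testing.

#' Spectrum container
#'
#' Tabulated broadband permittivity data: frequency in Hz, the real
#' permittivity \eqn{\epsilon'}, and a loss channel that is either the
#' imaginary permittivity \eqn{\epsilon''} or the total conductivity
#' \eqn{\sigma_{tot}(\omega) = \epsilon_0\,\omega\,\epsilon''} in S/m
#' (broadband tissue tabulations usually report the latter).
#'
#' @param freq_hz Strictly increasing positive frequencies (Hz).
#' @param eps_real Real permittivity at each frequency.
#' @param loss Loss channel values.
#' @param loss_kind `"conductivity"` (S/m) or `"eps_imag"`.
#' @return An object of class `spectrum_data`.
#' @export
spectrum_data <- function(freq_hz, eps_real, loss,
                          loss_kind = c("conductivity", "eps_imag")) {
  loss_kind <- match.arg(loss_kind)
  n <- length(freq_hz)
  if (length(eps_real) != n || length(loss) != n)
    stop("`freq_hz`, `eps_real`, `loss` must have equal length",
         call. = FALSE)
  if (any(freq_hz <= 0) || any(diff(freq_hz) <= 0))
    stop("`freq_hz` must be positive and strictly increasing", call. = FALSE)
  structure(list(freq_hz = freq_hz, eps_real = eps_real, loss = loss,
                 loss_kind = loss_kind),
            class = "spectrum_data")
}

EPS0_SI <- 8.8541878128e-12   # vacuum permittivity, F/m

#' Synthetic two-relaxation tissue spectrum
#'
#' Generates a broadband permittivity spectrum from a two-term Cole-Cole
#' model plus a dc conductivity on a log-spaced frequency grid, with
#' independent multiplicative Gaussian noise on both channels — a synthetic
#' stand-in for tabulated soft-tissue (e.g. blood) spectra, which show broad
#' anomalous dispersion across 10^7-10^10 Hz produced by overlapping
#' relaxation processes.
#'
#' The default parameters are the published Cole-Cole dispersion terms for
#' blood that dominate this band (\eqn{\Delta\epsilon_1 = 56},
#' \eqn{\tau_1 = 8.38} ps, \eqn{\Delta\epsilon_2 = 5200},
#' \eqn{\tau_2 = 132.6} ns, both with broadening exponent 0.1,
#' \eqn{\epsilon_\infty = 4}, \eqn{\sigma_{dc} = 0.7} S/m).
#'
#' @param term1,term2 [cole_cole_params()] for the two relaxation terms
#'   (only the first carries `sigma_dc`; it is ignored here in favour of
#'   `sigma_dc` below).
#' @param sigma_dc dc conductivity, S/m.
#' @param eps_inf High-frequency permittivity added once.
#' @param freq_range_hz Length-2 vector (min, max), Hz.
#' @param n_points Number of log-spaced frequencies (>= 8).
#' @param noise_rel_sd Relative standard deviation of the multiplicative
#'   Gaussian noise (0 = noiseless).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param loss_kind Loss channel to tabulate.
#' @return A [spectrum_data()].
#' @export
generate_synthetic_spectrum <- function(
    term1 = cole_cole_params(0, 56, 8.377e-12, 0.10),
    term2 = cole_cole_params(0, 5200, 132.63e-9, 0.10),
    sigma_dc = 0.7, eps_inf = 4,
    freq_range_hz = c(1e7, 1e10), n_points = 60L,
    noise_rel_sd = 0.01, seed = 1L,
    loss_kind = c("conductivity", "eps_imag")) {
  loss_kind <- match.arg(loss_kind)
  if (n_points < 8) stop("`n_points` must be >= 8", call. = FALSE)
  if (freq_range_hz[1] >= freq_range_hz[2])
    stop("`freq_range_hz` must be (min, max) with min < max", call. = FALSE)
  if (noise_rel_sd < 0) stop("`noise_rel_sd` must be >= 0", call. = FALSE)

  f <- 10^seq(log10(freq_range_hz[1]), log10(freq_range_hz[2]),
              length.out = n_points)
  omega <- 2 * pi * f
  eps <- eps_inf +
    (reference_permittivity(term1, omega) - term1$eps_inf) +
    (reference_permittivity(term2, omega) - term2$eps_inf)
  eps_re <- Re(eps)
  eps_im <- Im(eps)                       # relaxation loss only (physics conv.)
  loss <- if (loss_kind == "conductivity") {
    sigma_dc + EPS0_SI * omega * eps_im
  } else {
    eps_im + sigma_dc / (omega * EPS0_SI)
  }

  if (noise_rel_sd > 0) {
    rng <- .with_seed(seed, {
      list(a = stats::rnorm(n_points, 1, noise_rel_sd),
           b = stats::rnorm(n_points, 1, noise_rel_sd))
    })
    eps_re <- eps_re * rng$a
    loss <- loss * rng$b
  }
  spectrum_data(f, eps_re, loss, loss_kind)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# model spectrum in the data's channels; medium parameters live in
# normalized frequency units omega / omega_ref
.model_channels <- function(medium, freq_hz, omega_ref, loss_kind) {
  x <- 2 * pi * freq_hz / omega_ref
  chi <- susceptibility(medium, x)
  eps_re <- medium$eps_inf + Re(chi)
  if (loss_kind == "conductivity") {
    omega_si <- 2 * pi * freq_hz
    loss <- medium$sigma_dc + EPS0_SI * omega_si * Im(chi)
  } else {
    loss <- Im(chi) + medium$sigma_dc / (2 * pi * freq_hz * EPS0_SI)
  }
  list(eps_real = eps_re, loss = loss)
}

# exact weighted least squares for the linearly entering parameters
# (eps_inf, wp2, sigma_dc) given the shape parameters; weights are the
# relative-residual weights of the full objective
.varpro_linear <- function(data, omega_ref, alpha, beta, gamma_beta) {
  x <- 2 * pi * data$freq_hz / omega_ref
  chi0 <- 1 / (.neg_i_omega_pow(x, alpha + 1) +
                 gamma_beta * .neg_i_omega_pow(x, beta))
  omega_si <- 2 * pi * data$freq_hz
  w1 <- 1 / pmax(abs(data$eps_real), 1e-12)
  w2 <- 1 / pmax(abs(data$loss), 1e-12)
  A_eps <- cbind(1, Re(chi0), 0) * w1
  A_loss <- if (data$loss_kind == "conductivity") {
    cbind(0, EPS0_SI * omega_si * Im(chi0), 1) * w2
  } else {
    cbind(0, Im(chi0), 1 / (omega_si * EPS0_SI)) * w2
  }
  A <- rbind(A_eps, A_loss)
  y <- c(data$eps_real * w1, data$loss * w2)
  theta <- tryCatch(qr.coef(qr(A), y), error = function(e) c(1, 1, 0))
  theta[!is.finite(theta)] <- 0
  list(eps_inf = theta[1], wp2 = theta[2], sigma_dc = theta[3])
}

.fit_bounds_default <- function() {
  list(lower = c(log_wp2 = log(1e-8), log_ga = log(1e-6), log_gb = log(1e-6),
                 alpha = 0.01, beta = 0, eps_inf = 1, sigma_dc = 0),
       upper = c(log_wp2 = log(1e8), log_ga = log(1e6), log_gb = log(1e6),
                 alpha = 1.99, beta = 1.29, eps_inf = 200, sigma_dc = 50))
}

.par_to_medium <- function(par, sign_wp2) {
  fractional_drude_medium(
    omega_p_sq = sign_wp2 * exp(par[["log_wp2"]]),
    gamma_alpha = exp(par[["log_ga"]]),
    gamma_beta = exp(par[["log_gb"]]),
    alpha = par[["alpha"]], beta = par[["beta"]],
    eps_inf = par[["eps_inf"]], sigma_dc = par[["sigma_dc"]]
  )
}

.fit_residuals <- function(par, sign_wp2, data, omega_ref) {
  med <- tryCatch(.par_to_medium(par, sign_wp2), error = function(e) NULL)
  if (is.null(med)) return(rep(1e6, 2L * length(data$freq_hz)))
  mod <- .model_channels(med, data$freq_hz, omega_ref, data$loss_kind)
  r1 <- (mod$eps_real - data$eps_real) / pmax(abs(data$eps_real), 1e-12)
  r2 <- (mod$loss - data$loss) / pmax(abs(data$loss), 1e-12)
  r <- c(r1, r2)
  r[!is.finite(r)] <- 1e6
  r
}

.run_lm <- function(start, sign_wp2, data, omega_ref, bounds) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      lower = bounds$lower, upper = bounds$upper,
      fn = .fit_residuals, sign_wp2 = sign_wp2, data = data,
      omega_ref = omega_ref,
      control = minpack.lm::nls.lm.control(maxiter = 400, maxfev = 4000)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(par = stats::coef(fit), sign_wp2 = sign_wp2,
       rms = sqrt(mean(fit$fvec^2)), nfev = fit$niter,
       converged = fit$info %in% 1:4)
}

#' Fit the fractional Drude model to a spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the concatenated
#' relative residuals of \eqn{\epsilon'} and the loss channel, with seeded
#' Latin-hypercube multi-start over the bounds and both signs of
#' \eqn{\omega_p^2} — anomalous-dispersion tissue fits need
#' \eqn{\omega_p^2 < 0}. Scale parameters (\eqn{|\omega_p^2|},
#' \eqn{\gamma_\alpha}, \eqn{\gamma_\beta}) are optimised in log space; the
#' fractional orders are kept inside the time-domain stability region
#' \eqn{\alpha \in (0, 2)}, \eqn{\beta \in [0, 1.3)}.
#'
#' Frequencies are normalised internally by `omega_ref` so the fitted
#' parameters are O(1); the returned medium is expressed in units of
#' `omega_ref` (stored in the result) and can be converted with
#' [rescale_medium()].
#'
#' @param data A [spectrum_data()] with at least 8 points.
#' @param bounds Optional list with named vectors `lower`, `upper` over the
#'   internal parameterisation (`log_wp2`, `log_ga`, `log_gb`, `alpha`,
#'   `beta`, `eps_inf`, `sigma_dc`).
#' @param n_starts Number of Latin-hypercube starting points per
#'   \eqn{\omega_p^2} sign.
#' @param seed Integer seed for the start design.
#' @param omega_ref Angular-frequency normalisation, rad/s.
#' @param extra_starts Optional list of extra starting points, each a list
#'   with `par` (named vector) and `sign_wp2`; used to seed the fractional
#'   fit with the nested standard-Drude solution.
#' @return An object of class `fit_result`: list with `params` (the fitted
#'   [fractional_drude_medium()] in `omega_ref` units), `residual` (RMS
#'   relative misfit), `n_evaluations`, `converged`, `bounds_hit` (names of
#'   parameters on a bound), `omega_ref`.
#' @export
fit_fractional_drude <- function(data, bounds = NULL, n_starts = 8L,
                                 seed = 1L, omega_ref = 2 * pi * 1e9,
                                 extra_starts = NULL) {
  if (length(data$freq_hz) < 8)
    stop("at least 8 data points are required", call. = FALSE)
  b <- utils::modifyList(.fit_bounds_default(), bounds %||% list())
  p_names <- names(b$lower)

  # Latin-hypercube over the nonlinear shape parameters (alpha, beta,
  # log gamma_beta with gamma_alpha gauge-fixed at 1); for each draw the
  # remaining parameters enter the model linearly, so (eps_inf, wp2,
  # sigma_dc) are obtained by an exact weighted linear solve (variable
  # projection), which places every start in a basin consistent with the
  # data before Levenberg-Marquardt refines all seven parameters.
  design <- .with_seed(seed, lhs::randomLHS(n_starts, 3L))
  starts <- lapply(seq_len(n_starts), function(i) {
    u <- design[i, ]
    alpha0 <- b$lower[["alpha"]] +
      u[1] * (b$upper[["alpha"]] - b$lower[["alpha"]])
    beta0 <- b$lower[["beta"]] +
      u[2] * (b$upper[["beta"]] - b$lower[["beta"]])
    log_gb0 <- 6 * (u[3] - 0.5)
    lin <- .varpro_linear(data, omega_ref, alpha0, beta0, exp(log_gb0))
    s <- c(log_wp2 = log(max(abs(lin$wp2), 1e-6)),
           log_ga = 0, log_gb = log_gb0,
           alpha = alpha0, beta = beta0,
           eps_inf = min(max(lin$eps_inf, b$lower[["eps_inf"]]),
                         b$upper[["eps_inf"]]),
           sigma_dc = min(max(lin$sigma_dc, b$lower[["sigma_dc"]]),
                          b$upper[["sigma_dc"]]))
    list(par = s, sign_wp2 = if (lin$wp2 >= 0) 1 else -1)
  })

  cands <- starts
  # also try the opposite wp2 sign for the best-conditioned start
  cands[[length(cands) + 1L]] <- list(par = starts[[1L]]$par,
                                      sign_wp2 = -starts[[1L]]$sign_wp2)
  for (es in extra_starts %||% list())
    cands[[length(cands) + 1L]] <- es

  best <- NULL; n_eval <- 0L
  for (cand in cands) {
    par0 <- pmin(pmax(cand$par[p_names], b$lower), b$upper)
    res <- .run_lm(par0, cand$sign_wp2, data, omega_ref, b)
    if (is.null(res)) next
    n_eval <- n_eval + res$nfev
    if (is.null(best) || res$rms < best$rms) best <- res
  }
  # polish: restart Levenberg-Marquardt from the incumbent (a fresh trust
  # region often escapes a stalled step-size collapse)
  if (!is.null(best)) {
    pol <- .run_lm(best$par, best$sign_wp2, data, omega_ref, b)
    if (!is.null(pol)) {
      n_eval <- n_eval + pol$nfev
      if (pol$rms < best$rms) best <- pol
    }
  }
  .as_fit_result(best, b, n_eval, omega_ref)
}

.as_fit_result <- function(best, bounds, n_eval, omega_ref) {
  if (is.null(best)) {
    return(structure(list(params = NULL, residual = Inf,
                          n_evaluations = n_eval, converged = FALSE,
                          bounds_hit = character(0), omega_ref = omega_ref),
                     class = "fit_result"))
  }
  tol <- 1e-8
  hit <- names(best$par)[best$par <= bounds$lower + tol |
                         best$par >= bounds$upper - tol]
  structure(list(
    params = .par_to_medium(best$par, best$sign_wp2),
    residual = best$rms,
    n_evaluations = n_eval,
    converged = isTRUE(best$converged),
    bounds_hit = hit,
    omega_ref = omega_ref
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit %s: RMS relative misfit %.4g (%s)\n",
              if (is.null(x$params)) "(failed)" else "",
              x$residual, if (x$converged) "converged" else "not converged"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Fit the standard Drude model to a spectrum
#'
#' Same objective and machinery as [fit_fractional_drude()] but with the
#' orders fixed at \eqn{\alpha = \beta = 1} and \eqn{\gamma_\alpha = 1}
#' (the classical \eqn{\chi = -\omega_p^2/(\omega^2 + i\gamma\omega)});
#' \eqn{\omega_p^2} may be negative. Being a nested special case, its
#' residual can never beat the fractional fit when the latter is started
#' from this solution.
#'
#' @inheritParams fit_fractional_drude
#' @return A `fit_result`.
#' @export
fit_standard_drude <- function(data, bounds = NULL, n_starts = 8L,
                               seed = 1L, omega_ref = 2 * pi * 1e9) {
  b <- utils::modifyList(.fit_bounds_default(), bounds %||% list())
  b$lower[c("alpha", "beta")] <- 1
  b$upper[c("alpha", "beta")] <- 1
  b$lower[["log_ga"]] <- 0; b$upper[["log_ga"]] <- 0
  fit_fractional_drude(data, bounds = b, n_starts = n_starts, seed = seed,
                       omega_ref = omega_ref)
}

#' Standard-Drude solution as a starting point for the fractional fit
#'
#' Helper producing the `extra_starts` entry of [fit_fractional_drude()]
#' from a standard-Drude `fit_result`, so the nested-model residual
#' inequality holds by construction.
#'
#' @param drude_fit A `fit_result` from [fit_standard_drude()].
#' @return A list suitable as one element of `extra_starts`.
#' @export
drude_start <- function(drude_fit) {
  p <- drude_fit$params
  if (is.null(p)) stop("drude fit failed; no start available", call. = FALSE)
  list(par = c(log_wp2 = log(abs(p$omega_p_sq)),
               log_ga = log(p$gamma_alpha),
               log_gb = log(max(p$gamma_beta, 1e-6)),
               alpha = p$alpha, beta = p$beta,
               eps_inf = p$eps_inf, sigma_dc = p$sigma_dc),
       sign_wp2 = sign(p$omega_p_sq))
}
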
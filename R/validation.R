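# Numerical measurement of chi(omega) from FDTD runs and reproduction of the
# accuracy/stability/memory-sweep/power-law experiments.

# Least-squares phasor extraction: fit y ~ a cos(w t) + b sin(w t) on the
# window and return the complex amplitude a + i b of y = Re[(a + i b)
# e^{-i w t}]. Unlike plain DFT binning, this is exact for a pure sinusoid
# even when the window is not an integer number of periods.
.ls_phasor <- function(y, t, omega) {
  cw <- cos(omega * t); sw <- sin(omega * t)
  M <- cbind(cw, sw)
  ab <- qr.solve(crossprod(M), crossprod(M, y))
  complex(real = ab[1L], imaginary = ab[2L])
}

.default_geometry <- function() {
  list(n_cells = 2000L, src_pos = 100L, med_start = 300L, med_end = 1900L,
       probe_offset = 20L)
}

#' Measure the numerical susceptibility at one frequency
#'
#' Runs a monochromatic 1-D FDTD simulation (soft source in vacuum, medium
#' slab, probe cell inside the slab) to steady state and extracts the complex
#' amplitudes of E and P at the probe by least-squares sinusoid projection at
#' the drive frequency. The numerical susceptibility is
#' \eqn{\chi_{num} = \hat P / (\epsilon_0 \hat E)} and is returned alongside
#' the analytic value and their relative deviation.
#'
#' The steady-state protocol is: raised-cosine source ramp over
#' `ramp_cycles` periods, `settle_cycles` further periods discarded, then
#' projection over `project_cycles` periods. A warning is raised when the
#' drive is resolved by fewer than 10 time steps per period or 10 cells per
#' analytic wavelength (the result is then dominated by grid resolution
#' rather than the material model).
#'
#' @param medium A [fractional_drude_medium()].
#' @param omega Drive frequency (> 0, normalized units).
#' @param dt Time step (Courant number; stable for `dt <= 1` in vacuum).
#' @param n_terms Number of polarization memory terms N.
#' @param ramp_cycles,settle_cycles,project_cycles Protocol lengths in drive
#'   periods.
#' @param geometry List overriding the default grid layout (fields `n_cells`,
#'   `src_pos`, `med_start`, `med_end`, `probe_offset`).
#' @return An object of class `susceptibility_measurement`: list with
#'   `omega`, `chi_numeric`, `chi_analytic`, `relative_error`, `diverged`.
#'   When the run diverges, `chi_numeric` and `relative_error` are `NA` and
#'   `diverged` is `TRUE`.
#' @export
measure_susceptibility <- function(medium, omega, dt, n_terms = 32L,
                                   ramp_cycles = 10, settle_cycles = 30,
                                   project_cycles = 16, geometry = NULL) {
  geo <- utils::modifyList(.default_geometry(), geometry %||% list())
  steps_per_period <- 2 * pi / (omega * dt)
  if (steps_per_period < 10)
    warning(sprintf("only %.1f time steps per period at omega = %g",
                    steps_per_period, omega), call. = FALSE)
  eps_a <- medium$eps_inf + susceptibility(medium, omega)
  n_re <- Re(sqrt(eps_a))
  if (n_re > 1e-6 && 2 * pi / (omega * n_re) < 10)
    warning(sprintf("only %.1f cells per analytic wavelength at omega = %g",
                    2 * pi / (omega * n_re), omega), call. = FALSE)

  total_cycles <- ramp_cycles + settle_cycles + project_cycles
  n_steps <- ceiling(total_cycles * steps_per_period)
  grid <- grid1d(geo$n_cells, geo$med_start, geo$med_end, geo$src_pos)
  probe <- geo$med_start + geo$probe_offset
  coeffs <- ade_coefficients(medium, dt, n_terms)
  src <- source_spec("monochromatic_soft", omega = omega, amplitude = 1,
                     ramp_cycles = ramp_cycles)
  rec <- fdtd_run(grid, coeffs, src, n_steps, probe)

  chi_th <- susceptibility(medium, omega)
  if (rec$diverged) {
    out <- list(omega = omega, chi_numeric = NA_complex_,
                chi_analytic = chi_th, relative_error = NA_real_,
                diverged = TRUE)
    return(structure(out, class = "susceptibility_measurement"))
  }

  n_proj <- floor(project_cycles * steps_per_period)
  idx <- seq.int(n_steps - n_proj + 1L, n_steps)
  t_idx <- idx * dt
  e_hat <- .ls_phasor(rec$e[idx, 1L], t_idx, omega)
  p_hat <- .ls_phasor(rec$p[idx, 1L], t_idx, omega)
  chi_num <- p_hat / e_hat                       # eps0 = 1
  structure(list(
    omega = omega,
    chi_numeric = chi_num,
    chi_analytic = chi_th,
    relative_error = Mod(chi_num - chi_th) / Mod(chi_th),
    diverged = FALSE
  ), class = "susceptibility_measurement")
}

#' Mean relative susceptibility error over the standard band
#'
#' Averages the relative deviation \eqn{|\chi_{num} - \chi_{th}|/|\chi_{th}|}
#' over `n_freqs` equally spaced frequencies in the open interval
#' \eqn{(0.3\,\omega_p, \omega_p)} (endpoints excluded by half a spacing) and
#' expresses the result in percent — the accuracy figure \eqn{\eta} of the
#' stability/accuracy tables. Returns `Inf` as soon as any frequency
#' diverges.
#'
#' @inheritParams measure_susceptibility
#' @param n_freqs Number of frequencies (>= 2).
#' @param error_on `"complex"` (modulus of the complex deviation, default) or
#'   `"real"` (deviation of the real parts only).
#' @param ... Passed on to [measure_susceptibility()].
#' @return Mean relative error in percent, or `Inf`.
#' @export
mean_relative_error <- function(medium, dt, n_terms = 32L, n_freqs = 15L,
                                error_on = c("complex", "real"), ...) {
  error_on <- match.arg(error_on)
  if (n_freqs < 2) stop("`n_freqs` must be >= 2", call. = FALSE)
  wp <- sqrt(abs(medium$omega_p_sq))
  lo <- 0.3 * wp; hi <- wp
  step <- (hi - lo) / n_freqs
  omegas <- lo + (seq_len(n_freqs) - 0.5) * step
  errs <- numeric(n_freqs)
  for (i in seq_along(omegas)) {
    m <- measure_susceptibility(medium, omegas[i], dt, n_terms, ...)
    if (m$diverged) return(Inf)
    errs[i] <- if (error_on == "complex") m$relative_error
               else abs(Re(m$chi_numeric) - Re(m$chi_analytic)) /
                    Mod(m$chi_analytic)
  }
  100 * mean(errs)
}

#' Accuracy/stability scan along one parameter axis
#'
#' Computes [mean_relative_error()] for each value along one axis (`alpha`,
#' `beta` or `dt`) with everything else held fixed, encoding divergence as
#' `Inf` — one row of the accuracy/stability table.
#'
#' @param axis One of `"alpha"`, `"beta"`, `"dt"`.
#' @param values Numeric vector of axis values (non-empty).
#' @param medium Base [fractional_drude_medium()] providing the fixed
#'   parameters.
#' @param dt Time step used when `axis` is not `"dt"`.
#' @param n_terms Memory depth N.
#' @param ... Passed on to [mean_relative_error()].
#' @return An object of class `error_table`: list with `axis_name`,
#'   `axis_values`, `eta_percent` (`Inf` marks instability).
#' @export
stability_scan <- function(axis = c("alpha", "beta", "dt"), values, medium,
                           dt = 0.5, n_terms = 32L, ...) {
  axis <- match.arg(axis)
  if (length(values) < 1) stop("`values` must be non-empty", call. = FALSE)
  eta <- vapply(values, function(v) {
    med <- medium; dt_i <- dt
    if (axis == "dt") dt_i <- v
    else { med[[axis]] <- v
           med <- do.call(fractional_drude_medium, med[
             c("omega_p_sq", "gamma_alpha", "gamma_beta", "alpha", "beta",
               "eps_inf", "sigma_dc")]) }
    mean_relative_error(med, dt_i, n_terms, ...)
  }, numeric(1))
  structure(list(axis_name = axis, axis_values = values, eta_percent = eta),
            class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  cat(sprintf("Mean relative susceptibility error (%%), axis = %s\n",
              x$axis_name))
  print(data.frame(value = x$axis_values, eta = x$eta_percent))
  invisible(x)
}

#' Memory-depth sweep of the susceptibility error spectrum
#'
#' Measures the per-frequency relative susceptibility error for each memory
#' depth N in `n_terms_list` over `omega_grid` — the truncation-convergence
#' experiment. Deep memory mainly improves the low-frequency end; at
#' \eqn{\alpha = \beta = 1} all memory weights beyond the first two vanish
#' and the spectra coincide.
#'
#' @param medium A [fractional_drude_medium()].
#' @param n_terms_list Integer vector of memory depths (all >= 1).
#' @param omega_grid Frequencies at which to measure.
#' @param dt Time step.
#' @param ... Passed on to [measure_susceptibility()].
#' @return A list with `omega` and `error` (matrix, frequencies x depths,
#'   columns named by N).
#' @export
memory_sweep <- function(medium, n_terms_list, omega_grid, dt = 0.5, ...) {
  if (any(n_terms_list < 1)) stop("all `n_terms_list` >= 1", call. = FALSE)
  err <- sapply(n_terms_list, function(N) {
    vapply(omega_grid, function(w) {
      measure_susceptibility(medium, w, dt, N, ...)$relative_error
    }, numeric(1))
  })
  err <- matrix(err, nrow = length(omega_grid),
                dimnames = list(NULL, paste0("N", n_terms_list)))
  list(omega = omega_grid, error = err)
}

#' Absorption spectrum and its high-frequency power-law slope
#'
#' Evaluates \eqn{\mathrm{Im}\,k(\omega)} from the dispersion relation over
#' `omega_grid` and fits the log-log slope of \eqn{\mathrm{Im}\,k} versus
#' \eqn{\omega} by least squares over the window
#' \eqn{\omega \in (10\,\omega_p, 10^3\,\omega_p)}, where the power law
#' \eqn{\mathrm{Im}\,k \sim \omega^{\beta-3}} (for \eqn{\alpha = 1}) holds.
#'
#' @param medium A [fractional_drude_medium()].
#' @param omega_grid Frequencies; must reach at least a decade above
#'   \eqn{\omega_p} for the slope fit.
#' @param units A [unit_system()].
#' @return List with `omega`, `im_k`, and `slope` (the fitted log-log slope;
#'   `NA` when fewer than 2 grid points fall in the fit window).
#' @export
imk_spectrum_numeric <- function(medium, omega_grid, units = unit_system()) {
  wp <- sqrt(abs(medium$omega_p_sq))
  if (max(omega_grid) < 10 * wp)
    stop("`omega_grid` must extend at least a decade above omega_p",
         call. = FALSE)
  imk <- Im(wavevector(medium, omega_grid, units))
  win <- omega_grid > 10 * wp & omega_grid < 1e3 * wp & imk > 0
  slope <- if (sum(win) >= 2) {
    unname(stats::coef(stats::lm(log(imk[win]) ~ log(omega_grid[win])))[2L])
  } else NA_real_
  list(omega = omega_grid, im_k = imk, slope = slope)
}
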
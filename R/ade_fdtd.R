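# Auxiliary-differential-equation discretization of the fractional Drude
# polarization equation and the 1-D Yee-grid FDTD driver around the compiled
# stepper.

#' ADE update coefficients for the fractional Drude medium
#'
#' Discretises \eqn{\gamma_\alpha D^{\alpha+1} P + \gamma_\beta D^{\beta} P =
#' \omega_p^2 E} with truncated Grunwald-Letnikov sums: the order-(α+1)
#' derivative as a first difference of the order-α sum,
#' \eqn{\frac{\gamma_\alpha}{\Delta t\,\Delta t^\alpha}\sum_k w^\alpha_k
#' (P_{t-k+1}-P_{t-k})}, and the order-β derivative as the two-point average
#' \eqn{\frac{\gamma_\beta}{2\Delta t^\beta}\sum_k w^\beta_k
#' (P_{t-k+1}+P_{t-k})}. Solving the resulting discrete equation of motion
#' for \eqn{P_{t+1}} gives
#' \deqn{P_{t+1} = \mathrm{coef}_E\,\bar E + \sum_{j=0}^{N}
#'   c_j\,P_{t-j},}
#' whose coefficients are returned here; \eqn{\bar E = (E_t + E_{t+1})/2} is
#' the semi-implicit field average used by the simulator (see
#' [fdtd_run()]), which keeps the coupled field/polarization scheme stable up
#' to the vacuum Courant limit \eqn{\Delta t = 1}. The coefficients are
#' obtained directly from the discrete equation of motion (collecting the
#' \eqn{k=0} term and re-indexing the \eqn{k \ge 1} sums), which guarantees
#' the exact reduction at \eqn{\alpha=\beta=1} to the classical Drude ADE
#' \deqn{P_{t+1} = \frac{2P_t - (1-\gamma_\beta\Delta t/2)P_{t-1}
#'   + \omega_p^2\Delta t^2 \bar E}{1+\gamma_\beta\Delta t/2}.}
#'
#' @param medium A [fractional_drude_medium()].
#' @param dt Positive time step (the Courant number in normalized units).
#' @param n_terms Number of memory terms \eqn{N \ge 1}.
#' @return An object of class `ade_coefficients` with elements `n_terms`,
#'   `dt`, `denom` (the common denominator
#'   \eqn{\gamma_\alpha w^\alpha_0/(\Delta t\,\Delta t^\alpha) +
#'   \gamma_\beta w^\beta_0/(2\Delta t^\beta)}), `coef_P_t`, `coef_P_tm1`,
#'   `mem_alpha` and `mem_beta` (the normalized per-\eqn{k} weights of the two
#'   history sums, \eqn{k = 2..N}), `coef_E`, and `coef_hist` (the combined
#'   per-lag coefficients \eqn{c_0..c_N} used by the stepper, with
#'   `coef_hist[1] == coef_P_t` and `coef_hist[2] == coef_P_tm1`).
#' @examples
#' m <- fractional_drude_medium(0.09, 1, 0.1, alpha = 1, beta = 1)
#' ade_coefficients(m, dt = 0.5, n_terms = 8)$coef_P_t  # 2 / 1.025
#' @export
ade_coefficients <- function(medium, dt, n_terms) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_terms < 1) stop("`n_terms` must be at least 1", call. = FALSE)
  n_terms <- as.integer(n_terms)

  wA <- gl_weights(medium$alpha, n_terms)$weights   # w^alpha_0..N
  wB <- gl_weights(medium$beta, n_terms)$weights
  A <- medium$gamma_alpha / (dt * dt^medium$alpha)
  B <- medium$gamma_beta / (2 * dt^medium$beta)
  denom <- A + B                                    # w0 = 1 for both sums
  if (denom == 0 || !is.finite(denom))
    stop("degenerate medium: ADE denominator vanishes", call. = FALSE)

  # total coefficient g_j of P_{t-j} on the left-hand side, j = 0..N:
  # from the lag k >= 1 terms, P_{t-k+1} contributes (A wA_k + B wB_k) at
  # j = k-1 and P_{t-k} contributes (-A wA_k + B wB_k) at j = k; the k = 0
  # term contributes (B - A) at j = 0.
  g <- numeric(n_terms + 1L)
  g[1L] <- B - A
  for (k in seq_len(n_terms)) {
    g[k] <- g[k] + (A * wA[k + 1L] + B * wB[k + 1L])     # j = k - 1
    g[k + 1L] <- g[k + 1L] + (-A * wA[k + 1L] + B * wB[k + 1L])  # j = k
  }
  coef_hist <- -g / denom

  structure(list(
    n_terms = n_terms,
    dt = dt,
    denom = denom,
    coef_P_t = coef_hist[1L],
    coef_P_tm1 = coef_hist[2L],
    mem_alpha = if (n_terms >= 2L) A * wA[3:(n_terms + 1L)] / denom else numeric(0),
    mem_beta = if (n_terms >= 2L) B * wB[3:(n_terms + 1L)] / denom else numeric(0),
    coef_E = medium$omega_p_sq / denom,
    coef_hist = coef_hist,
    medium = medium
  ), class = "ade_coefficients")
}

#' @export
print.ade_coefficients <- function(x, ...) {
  cat(sprintf("ADE coefficients: N = %d, dt = %g\n", x$n_terms, x$dt))
  cat(sprintf("  coef_P_t = %.6g, coef_P_tm1 = %.6g, coef_E = %.6g\n",
              x$coef_P_t, x$coef_P_tm1, x$coef_E))
  invisible(x)
}

#' 1-D FDTD grid specification
#'
#' Describes a Yee grid in normalized units (\eqn{c = \Delta x = \epsilon_0 =
#' 1}): total length, the contiguous medium slab, and the soft-source cell.
#' All fields and the per-cell polarization history start at rest (zero).
#'
#' @param n_cells Total number of E-field cells.
#' @param med_start,med_end First and last cell (1-based, inclusive) of the
#'   medium slab; `med_end < med_start` means a vacuum grid.
#' @param src_pos Source cell (1-based).
#' @return An object of class `grid1d`.
#' @export
grid1d <- function(n_cells, med_start = 0L, med_end = -1L, src_pos = 2L) {
  n_cells <- as.integer(n_cells)
  med_start <- as.integer(med_start); med_end <- as.integer(med_end)
  src_pos <- as.integer(src_pos)
  if (n_cells < 5L) stop("grid too short", call. = FALSE)
  if (src_pos < 2L || src_pos > n_cells - 1L)
    stop("`src_pos` must be an interior cell", call. = FALSE)
  if (med_end >= med_start) {
    if (med_start < 2L || med_end > n_cells - 1L)
      stop("medium slab must lie strictly inside the grid", call. = FALSE)
  }
  structure(list(n_cells = n_cells, med_start = med_start,
                 med_end = med_end, src_pos = src_pos),
            class = "grid1d")
}

#' Source specification
#'
#' @param kind `"monochromatic_soft"` (raised-cosine ramped sinusoid added
#'   softly to the source cell) or `"gaussian_pulse"`.
#' @param omega Angular frequency (monochromatic source), > 0.
#' @param amplitude Source amplitude.
#' @param ramp_cycles Length of the raised-cosine turn-on, in drive periods.
#' @param pulse_center,pulse_width Centre and width (time units) of the
#'   Gaussian pulse.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(kind = c("monochromatic_soft", "gaussian_pulse"),
                        omega = NULL, amplitude = 1, ramp_cycles = 10,
                        pulse_center = 30, pulse_width = 10) {
  kind <- match.arg(kind)
  if (kind == "monochromatic_soft") {
    if (is.null(omega) || omega <= 0)
      stop("monochromatic source requires `omega` > 0", call. = FALSE)
    if (ramp_cycles < 0) stop("`ramp_cycles` must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, omega = omega, amplitude = amplitude,
                 ramp_cycles = ramp_cycles, pulse_center = pulse_center,
                 pulse_width = pulse_width),
            class = "source_spec")
}

#' Run a 1-D FDTD simulation
#'
#' Advances the Yee grid `n_steps` steps: H update, then the joint E/ADE
#' polarization update in medium cells — the polarization current
#' \eqn{(P_{t+1}-P_t)/\Delta t} enters Ampere's law while the polarization
#' equation (with its N-term Grunwald-Letnikov memory) is driven by the
#' semi-implicit field average \eqn{(E_t+E_{t+1})/2}, the two solved together
#' in closed form per cell — then first-order Mur absorbing terminations and
#' the soft source. E and P time series are
#' recorded at the probe cells; the run aborts with a divergence flag when
#' \eqn{\max|E|} exceeds `div_factor` times the source amplitude (checked
#' every `check_every` steps) — the instability marker of the stability scans.
#'
#' @param grid A [grid1d()].
#' @param coeffs An [ade_coefficients()] (ignored for a vacuum grid; may be
#'   `NULL` then).
#' @param source A [source_spec()].
#' @param n_steps Number of time steps (>= 1).
#' @param probe_cells Integer vector of probe cells (1-based).
#' @param div_factor Divergence threshold as a multiple of the source
#'   amplitude.
#' @param check_every Divergence check interval in steps.
#' @param dt Time step for a vacuum grid (`coeffs = NULL`); taken from
#'   `coeffs` otherwise.
#' @param record_energy Also record the total field energy
#'   \eqn{\frac12\sum(E^2 + H^2)} per step (element `energy`).
#' @return An object of class `probe_record`: list with matrices `e`, `p`
#'   (steps x probes), `dt`, `probe_cells`, logical `diverged`, and
#'   `steps_done` (plus `energy` when requested).
#' @export
fdtd_run <- function(grid, coeffs, source, n_steps, probe_cells,
                     div_factor = 1e6, check_every = 100L, dt = NULL,
                     record_energy = FALSE) {
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  probe_cells <- as.integer(probe_cells)
  if (any(probe_cells < 1L | probe_cells > grid$n_cells))
    stop("probe outside grid", call. = FALSE)
  vacuum <- grid$med_end < grid$med_start
  if (!vacuum && is.null(coeffs))
    stop("`coeffs` required for a grid with a medium slab", call. = FALSE)
  if (!is.null(coeffs)) dt <- coeffs$dt
  if (is.null(dt)) stop("`dt` required when `coeffs` is NULL", call. = FALSE)

  medium <- if (vacuum) list(eps_inf = 1, sigma_dc = 0) else coeffs$medium
  ramp_steps <- 0
  src_kind <- if (source$kind == "monochromatic_soft") 0L else 1L
  omega <- source$omega %||% 1
  if (src_kind == 0L)
    ramp_steps <- source$ramp_cycles * 2 * pi / (omega * dt)

  res <- .fdtd_run_cpp(
    n_cells = grid$n_cells,
    med_start = grid$med_start - 1L, med_end = grid$med_end - 1L,
    eps_inf = medium$eps_inf, sigma_dc = medium$sigma_dc,
    dt = dt,
    coef_hist = if (vacuum) numeric(1) else coeffs$coef_hist,
    coef_E = if (vacuum) 0 else coeffs$coef_E,
    n_steps = as.integer(n_steps),
    src_pos = grid$src_pos - 1L, source_kind = src_kind,
    omega = omega, amplitude = source$amplitude, ramp_steps = ramp_steps,
    pulse_center = source$pulse_center, pulse_width = source$pulse_width,
    probe_cells = probe_cells - 1L,
    div_threshold = div_factor * abs(source$amplitude),
    check_every = as.integer(check_every),
    record_full_every = if (record_energy) 1L else 0L
  )
  structure(list(e = res$e, p = res$p, dt = dt, probe_cells = probe_cells,
                 diverged = res$diverged, steps_done = res$steps_done,
                 energy = res$energy),
            class = "probe_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
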
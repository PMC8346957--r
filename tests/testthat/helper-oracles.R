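# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: weights from the Gamma-function closed form,
# and a from-scratch standard-Drude FDTD stepper in plain R.

# (-1)^k Gamma(o+1) / (Gamma(k+1) Gamma(o-k+1)), with the integer-order
# binomial special case evaluated exactly (the Gamma form hits poles there).
gl_weight_gamma <- function(order, k) {
  if (abs(order - round(order)) < 1e-12) {
    o <- round(order)
    return(if (k > o) 0 else (-1)^k * choose(o, k))
  }
  (-1)^k * gamma(order + 1) / (gamma(k + 1) * gamma(order - k + 1))
}

# generalised binomial coefficient C(x, n) via log-Gamma with explicit sign
# bookkeeping for negative non-integer arguments
choose_gamma <- function(x, n) {
  sgn <- function(z) {
    # sign of Gamma(z): positive for z > 0; (-1)^m on (-m, -m+1)
    if (z > 0) 1 else (-1)^ceiling(-z)
  }
  num <- x + 1; d1 <- n + 1; d2 <- x - n + 1
  if (abs(d2 - round(d2)) < 1e-12 && round(d2) <= 0) return(0)
  s <- sgn(num) / (sgn(d1) * sgn(d2))
  s * exp(lgamma(num) - lgamma(d1) - lgamma(d2))
}

# Standard-Drude 1-D FDTD reference: classical ADE
#   P_{t+1} = [2 P_t - (1 - g dt/2) P_{t-1} + wp2 dt^2 (E_t + E_{t+1})/2] /
#             (1 + g dt/2)
# solved jointly with Ampere's law (polarization current (P_{t+1}-P_t)/dt),
# soft ramped sine source, first-order Mur ends. Written directly from the
# two-term recurrence: no Grunwald-Letnikov machinery anywhere.
drude_fdtd_reference <- function(n_cells, med_start, med_end, dt, wp2, g,
                                 n_steps, src_pos, omega, amplitude = 1,
                                 ramp_cycles = 10, probe) {
  E <- numeric(n_cells); H <- numeric(n_cells - 1)
  P <- numeric(n_cells); Pm1 <- numeric(n_cells)
  med <- seq.int(med_start, med_end)
  a <- 1 / (1 + g * dt / 2)
  gE <- a * wp2 * dt^2            # coefficient of the averaged field drive
  mur <- (dt - 1) / (dt + 1)
  ramp_steps <- ramp_cycles * 2 * pi / (omega * dt)
  e_rec <- p_rec <- numeric(n_steps)

  for (t in seq_len(n_steps)) {
    H <- H + dt * diff(E)
    q <- a * (2 * P[med] - (1 - g * dt / 2) * Pm1[med])
    e_edge <- E[c(1, 2, n_cells - 1, n_cells)]
    curl <- c(0, diff(H), 0)
    Enew <- E + dt * curl
    Enew[med] <- ((1 - gE / 2) * E[med] + dt * curl[med] - q + P[med]) /
      (1 + gE / 2)
    Pnew_med <- q + gE * (E[med] + Enew[med]) / 2
    Pm1 <- P
    P[med] <- Pnew_med
    E <- Enew
    E[1] <- e_edge[2] + mur * (E[2] - e_edge[1])
    E[n_cells] <- e_edge[3] + mur * (E[n_cells - 1] - e_edge[4])
    ramp <- if (t < ramp_steps) 0.5 * (1 - cos(pi * t / ramp_steps)) else 1
    E[src_pos] <- E[src_pos] + amplitude * ramp * sin(omega * t * dt)
    e_rec[t] <- E[probe]; p_rec[t] <- P[probe]
  }
  list(e = e_rec, p = p_rec)
}

# standard accuracy-experiment medium
fig1_medium <- function(alpha = 1, beta = 1) {
  fractional_drude_medium(omega_p_sq = 0.09, gamma_alpha = 1,
                          gamma_beta = 0.1, alpha = alpha, beta = beta)
}
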
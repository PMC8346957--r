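# fracdrude

Broadband dielectric response of complex media — soft biological tissue
in particular — rarely follows the textbook Drude or Debye laws: the
measured attenuation and dispersion obey frequency power laws with
non-integer exponents, produced by many overlapping relaxation
processes. `fracdrude` implements a two-parameter fractional-derivative
generalisation of the Drude model for such media, together with a 1-D
FDTD simulator that propagates waves through it, a validation harness
that measures the numerical accuracy and stability of the scheme, and a
fitter for broadband tissue permittivity spectra. It is aimed at people
modelling electromagnetic biosensors and wave propagation in dispersive
(tissue-like) media who need a compact, simulatable material law.

## The model

The classical Drude polarization equation
$\ddot P + \gamma\dot P = \omega_p^2 E$ is generalised by replacing both
time derivatives with fractional (Grunwald–Letnikov) derivatives of
orders $\alpha+1$ and $\beta$:

$$\gamma_\alpha D^{\alpha+1} P + \gamma_\beta D^{\beta} P = \omega_p^2 E
\qquad\Longrightarrow\qquad
\chi(\omega) = \frac{\omega_p^2}
 {\gamma_\alpha(-i\omega)^{\alpha+1} + \gamma_\beta(-i\omega)^{\beta}} ,$$

with $\epsilon(\omega)=\epsilon_\infty+\chi(\omega)+i\sigma/(\omega\epsilon_0)$
(convention $e^{-i\omega t}$, principal branch). Setting
$\alpha=\beta=\gamma_\alpha=1$ recovers the Drude metal; $\alpha=\beta=0$
gives a Debye relaxation; $\beta=0$ a resonance. For $\alpha=1$ the
high-frequency absorption follows the power law
$\mathrm{Im}\,k \sim \omega^{\beta-3}$ — the attenuation behaviour seen
in tissue. In the time domain the fractional derivatives become
truncated Grunwald–Letnikov sums over the last $N$ polarization values
("memory terms"), which drop straight into an FDTD
auxiliary-differential-equation update.

The package's six building blocks: GL weight tables and discrete
fractional derivatives (`gl_weights`, `gl_derivative`); closed-form
spectra for the fractional model and the Debye / Cole–Cole /
Havriliak–Negami references (`susceptibility`, `permittivity`,
`wavevector`, `conductivity_spectrum`, `reference_permittivity`); the
compiled 1-D Yee/ADE simulator (`ade_coefficients`, `fdtd_run`);
validation experiments (`measure_susceptibility`, `mean_relative_error`,
`stability_scan`, `memory_sweep`, `imk_spectrum_numeric`); tissue-spectrum
fitting with a synthetic two-term Cole–Cole generator
(`fit_fractional_drude`, `fit_standard_drude`,
`generate_synthetic_spectrum`); and config/CSV plumbing plus a CLI
(`parse_config`, `write_table`, `inst/scripts/fracdrude-cli.R`).

## Worked example

Measure the susceptibility of a strongly fractional medium
($\alpha=\beta=0.8$, $\omega_p=0.3$, $\gamma_\alpha=1$,
$\gamma_\beta=0.1$; normalized units $c=\Delta x=\epsilon_0=1$) from an
FDTD run at $\Delta t = 0.5$ with $N=32$ memory terms, and compare with
the analytic formula:

```r
library(fracdrude)
m <- fractional_drude_medium(omega_p_sq = 0.09, gamma_alpha = 1,
                             gamma_beta = 0.1, alpha = 0.8, beta = 0.8)
ms <- measure_susceptibility(m, omega = 0.21, dt = 0.5, n_terms = 32)
#> chi_num = -0.9328+0.9461i   chi_th = -0.9788+0.9277i   rel.err = 3.68%
```

The ~4% deviation is the scheme's time-step error (dominated by a phase
term $\approx \omega\Delta t/2$) plus the $N$-truncation of the memory
sum. Averaging over the standard band $(0.3\,\omega_p, \omega_p)$ gives
the accuracy figure $\eta$ used by the stability scans:

```r
mean_relative_error(fractional_drude_medium(0.09, 1, 0.1, 1, 1),
                    dt = 0.5, n_terms = 32)
#> [1] 4.84      # percent, classical limit at dt = 0.5
```

The analytic power-law slope of the absorption, for $\alpha=1,\ \beta=0.5$:

```r
sp <- imk_spectrum_numeric(fractional_drude_medium(0.09, 1, 0.1, 1, 0.5),
                           exp(seq(log(0.3), log(600), length.out = 200)))
sp$slope
#> [1] -2.504    # prediction: beta - 3 = -2.5
```

And a tissue-style fit on a synthetic blood-like spectrum (two Cole–Cole
relaxations + dc conductivity, 1% noise): the fractional model fits an
order of magnitude better than the nested classical Drude model,

```r
sp <- generate_synthetic_spectrum(seed = 7)
fd <- fit_standard_drude(sp, seed = 3)
ff <- fit_fractional_drude(sp, seed = 3, extra_starts = list(drude_start(fd)))
c(drude = fd$residual, fractional = ff$residual)
#>      drude fractional
#> 0.20404    0.01926    # RMS relative misfit
```

A command-line front end with subcommands (`gl-weights`, `spectrum`,
`simulate`, `error-table`, `imk-spectrum`, `synth`, `fit`) is installed
at `system.file("scripts", "fracdrude-cli.R", package = "fracdrude")`.

See the vignette (`vignettes/fractional-drude-methods.Rmd`) for the
discretization, its stability region, the measurement protocol, and the
fitting machinery.

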
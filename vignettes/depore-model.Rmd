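---
title: "Membrane electroporation and DEP transport: the DEPore model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane electroporation and DEP transport: the DEPore model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DEPore)
```

DEPore simulates what happens to a spherical blood-borne cell - a
circulating tumor cell (CTC), a white blood cell (WBC) or a platelet
(PLT) - when it is held by dielectrophoresis between microelectrodes and
exposed to a short, strong electric pulse. This vignette is the package's
own account of the model: the equations, the assumptions behind them, the
parameters that matter, the calibration that fixes the constants no
dielectric table provides, and the limits of what the simulations show.

## The membrane model

### Charging

A cell is a conductive sphere (cytoplasm, conductivity $\sigma_i$) wrapped
in a thin, nearly insulating shell (membrane, thickness $d_m \ll R$,
resting conductivity $\sigma_{m0}$, relative permittivity
$\varepsilon_m$). In a uniform field $E$ the static induced transmembrane
voltage (ITV) at polar angle $\theta$ from the field axis is the thin-shell
result

$$U_m(\theta) = \tfrac{3}{2} E R \cos\theta .$$

The membrane behaves as a capacitor of specific capacitance
$C_m = \varepsilon_m \varepsilon_0 / d_m$ charged through the access
resistance of cytoplasm and medium; the resulting first-order (Schwan)
charging time is

$$\tau_m = R\, C_m \left( \frac{1}{\sigma_i} + \frac{1}{2\sigma_f} \right).$$

Each angular node of the membrane therefore obeys

$$\frac{d\,\mathrm{ITV}}{dt} = \frac{\tfrac32 E(t) R \cos\theta -
  \mathrm{ITV}\,\bigl(1 + (\sigma_{m0} + \sigma_{ep})\, g\bigr)}{\tau_m},
  \qquad g = \frac{R}{d_m}\left(\frac{1}{\sigma_i} +
  \frac{1}{2\sigma_f}\right),$$

where $g$ is the spherical access-resistance factor: it converts membrane
conductivity into a load on the charging circuit. This is what produces
the experimentally familiar *voltage clamp*: once pores raise
$\sigma_{ep}$, the product $\sigma_{ep}\, g$ becomes order one and the pole
voltage collapses toward the $\approx \pm 1$ V nucleation level instead of
following the unclamped $\tfrac32 E R$ value. Nodes are independent in
this uniform-field mode; axisymmetry is assumed throughout (a uniform
applied field gives an axisymmetric response).

### Pore nucleation and resealing

Pore density $N(\theta, t)$ follows the asymptotic nucleation/resealing
rate law

$$\frac{\partial N}{\partial t} = \alpha\, e^{x}
  \left[ 1 - \frac{N}{N_0} e^{-q x} \right],
  \qquad x = \left(\frac{\mathrm{ITV}}{V_{ep}}\right)^{2},$$

whose resting fixed point is $N = N_0$ at $\mathrm{ITV} = 0$. The added
membrane conductivity of $N$ pores of radius $r_p$, including the pore
access resistance, is

$$\sigma_{ep} = N\, \frac{2 \pi r_p^2\, \sigma_p\, d_m}
  {\pi r_p + 2 d_m}.$$

$x$ is clamped at 700 before exponentiation; the integrator is
`deSolve::ode` (lsoda, banded Jacobian) with rtol $10^{-6}$ and per-state
absolute tolerances ($10^{-6}$ V, $10^{-3}$ m$^{-2}$, $10^{-12}$ m). A
fixed-step RK4 integration at $dt = 10^{-10}$ s, built independently from
the same algebraic primitives, agrees with the stiff path to 0.1% (tested).

### Pore radius (energy mode)

With `poreDynamics = "energy_ode"` the per-node mean pore radius drifts
down the pore-energy gradient with mobility $D_p / k_B T$:

* an expanding electrical rim force
  $F_{max}\,\mathrm{ITV}^2 / (1 + r_h/(r_p + r_t))$,
* a contracting line tension $-2\pi\gamma$,
* an optional membrane tension $+2\pi\sigma_{eff} r_p$ (default 0, a
  floppy membrane whose pores always reseal), and
* a steric floor whose coefficient is derived internally so that
  $r_p = r^{*}$ is exactly the resting minimum at $\mathrm{ITV}=0$.

The default is `fixed_radius` ($r_p \equiv r^{*}$): the conductivity
formula above is the only radius-dependent expression the charging model
needs, and fixing the radius keeps the CTC/WBC dynamics two-dimensional
per node. Energy mode is enabled for the platelet runs, where peak pore
radius is a quantity of interest.

### Phases

The literature describes three regions of the pole-voltage trace verbally:
charging, fast pore nucleation, slow pore evolution. `detectPhases()`
makes them operational (both thresholds are arguments):

* charging ends when a pole node's density first exceeds $10 N_0$;
* nucleation ends when the membrane-total pore creation rate
  (area-weighted $dN/dt$) decays to 5% of its global maximum.

## Parameters

Cell dielectric parameters (radius, $d_m$, $\sigma_i$, $\sigma_{m0}$,
$\varepsilon_i$, $\varepsilon_m$) come from the built-in registry
(`getCell`). Pulse parameters default to a 2 µs rectangular pulse with a
10 ns tanh ramp; stiff solvers need a $C^1$ waveform, the ideal step is the
`riseTime` $\to 0$ limit, and the half-rise instant carries $E/2$.

The pore-model constants are not fixed by any dielectric table:

| constant | default | units | meaning |
|---|---|---|---|
| `alpha`  | 1e9   | m⁻²s⁻¹ | pore creation rate scale |
| `N0`     | 0.1·alpha | m⁻² | resting pore density |
| `q`      | 2.46  | -    | sealing exponent |
| `Vep`    | 0.258 | V    | characteristic nucleation voltage |
| `sigmaPore` | auto | S/m | pore conductivity; mean of $\sigma_i$, $\sigma_f$ |
| `rStar`  | 0.8   | nm   | minimum / resting pore radius |
| `poreDiffusivity` | 5e-14 | m²/s | pore-radius mobility scale |
| `lineTension` | 1.8e-11 | N | pore edge tension |

`alpha`, `q`, `Vep`, `rStar` are the standard asymptotic-model values. The
`N0 = 0.1 alpha` link deserves a note: at rest the rate law reseals excess
pores with time constant $N_0/\alpha$, so the link fixes a 0.1 s resting
recovery time - the sub-second scale consistent with the post-pulse
conductivity decay the model is asked to reproduce - while leaving the
absolute pore-number scale to calibration.

## Calibration

The charging model plus rate law leaves two genuinely free directions per
cell type: the medium conductivity $\sigma_f$ (never part of a cell
dielectric table; electroporation buffers span roughly 0.001-1 S/m) and
the pore-number scale $\alpha$ (with $N_0$ linked). `calibrateConstants()`
fits any subset of the constants by Levenberg-Marquardt on log-residuals
of simulated observables. The shipped per-cell sets
(`loadCalibratedConstants()`) were produced with **two anchors per cell
type**:

* **CTC** - charging end 1.0705 µs and pole conductivity 9.3e-7 S/m one
  second after a 4 kV/cm, 2 µs pulse; free: $\{\sigma_f, \alpha\}$.
  Fitted $\sigma_f = 0.0156$ S/m, $\alpha = 1.07\times10^{13}$.
* **WBC** - mean absolute pole voltage 1.15 V at $t = 2$ µs and peak pole
  pore density $1.9183\times10^{13}$ m⁻² (4 kV/cm); free:
  $\{\sigma_f, \alpha\}$. Fitted $\sigma_f = 0.0090$ S/m,
  $\alpha = 2.89\times10^{11}$.
* **PLT** - charging end 1.365e-7 s and peak pore radius 9 nm at
  20 kV/cm (energy mode); free: $\{\sigma_f, D_p\}$. Fitted
  $\sigma_f = 0.0131$ S/m, $D_p = 2\times10^{-13}$ m²/s.

Why these free parameters and not others: $\sigma_f$ controls $\tau_m$ and
hence the charging time; $\alpha$ (with the $N_0$ link) sets the resting
pore floor and thereby the post-pulse conductivity plateau. For platelets
the nucleation burst self-limits - pore number adjusts until the
conductivity load collapses the voltage - so neither $\alpha$ nor
$\sigma_p$ can enlarge pores; the sustained post-burst voltage could be
raised through $V_{ep}$, but values above $\approx 0.3$ V violate the
model's own clamping behavior (pole voltages would exceed 1.6 V at
40 kV/cm), so the pore mobility $D_p$ is the remaining, physically
defensible knob. The fitted $2\times10^{-13}$ m²/s sits within the spread
of pore-energy parameterizations in the literature. Quantities *not*
anchored - the CTC nucleation-phase end and peak conductivity, the WBC
density timing, platelet charging at other fields - are genuine model
outputs checked against their published values in the test suite.

The calibrated media are low-conductivity electroporation buffers. The
impedance module instead defaults to a physiological culture medium
($\sigma_f = 1.5$ S/m): that is the suspension an impedance sensor
actually measures, and in a 0.01 S/m buffer the resting WBC membrane leak
would clamp the voltage below the nucleation level at the sensor's field
strengths.

## The field solver

The default path needs no field solve: the uniform-field ODE above. The
optional high-fidelity path (`solveAxisymPotential`) solves the
steady conduction problem $\nabla\cdot(\sigma\nabla V)=0$ on a cylindrical
$(\rho, z)$ grid with plate electrodes, treating the membrane as a
*contact-impedance interface*: any finite-volume face crossing the sphere
surface carries the series resistance of its half-cells plus
$d_m/(\sigma_{m0}+\sigma_{ep}(\theta))$. The nm-scale shell is never
meshed. Validation (all in the tests): a homogeneous domain gives the
plate field to round-off; a plain conducting sphere matches the analytic
dipole solution to 1.5% RMS on a 200² grid; an insulating membrane returns
the $\tfrac32 E R \cos\theta$ voltage within 1.2%; discrete charge
conservation holds to machine precision; pole voltage moves < 1% when the
grid is refined from 100² to 200². The solve is quasi-static - every
quantity this path is used for is a static limit; time dependence lives in
the ODE path.

## DEP and transport

The Clausius-Mossotti factor uses complex permittivities
$\varepsilon^* = \varepsilon_0\varepsilon_r - i\sigma/\omega$ and, by
default, the single-shell effective particle permittivity (membrane shell
over cytoplasm core); a homogeneous mode exposes the textbook low- and
high-frequency limits. $\mathrm{Re}[K]$ is bounded in $[-0.5, 1]$ for all
physical parameters (property-tested). Forces are the time-averaged
dipole expressions; the traveling-wave force adds the
$2\,\mathrm{Im}[K]\,\nabla\times(\mathbf{E_I}\times\mathbf{E_R})$ term,
evaluated by centered finite differences on a gridded phasor field, and
reduces exactly to the plain DEP force when $\mathrm{Im}[K] = 0$. An
analytic phased-array wave fixture ($\phi = V_0 e^{-kz} e^{-ikx}$, whose
curl term is $-2k^3V_0^2 e^{-2kz}\hat{x}$) makes the traveling component
testable without any field solve. Trajectories are overdamped
($v = F/6\pi\eta R$ plus flow, explicit Euler); a particle is trapped when
its total speed stays under 1 µm/s (configurable) for 100 consecutive
steps. Trapping and focusing behavior is validated against constructed
fields with known extrema - no trajectory-level laboratory numbers exist
to target.

## Impedance forward model

The suspension between the 600 µm sensor electrodes (200 µm gap; nominal
field $E = V/d$) is modeled as a Cole circuit
$Z = R_\infty + (R_0 - R_\infty)/(1 + (i\,2\pi f \tau)^a)$, Debye by
default. Defaults $R_0 = 7\times10^5\ \Omega$,
$R_\infty = 1.5\times10^5\ \Omega$ put low-frequency magnitudes at the
$10^5$-$10^6\ \Omega$ scale of suspension measurements;
$\tau = 5\times10^{-5}$ s places the membrane dispersion below $10^5$ Hz
so that spectra at all drive voltages converge at high frequency, where
current bypasses the membranes capacitively. `voltageSeriesModel()` runs
the electroporation core at each voltage over a sustained 100 µs window
and scales the membrane-limited resistance $R_0 - R_\infty$ by
$1 - 0.95\,g$, with $g = \Delta\sigma_{ep}/(\Delta\sigma_{ep} +
\sigma_{m0})$ the excess-over-resting pore conductivity fraction - the
simplest monotone link, which guarantees $|Z|$ and $R_s$ non-increasing in
voltage and reactance suppressed toward zero at every frequency.
`fitCircuit()` inverts spectra by weighted complex least squares;
`generateSyntheticSpectra()` adds multiplicative log-normal noise under a
fixed seed (the only randomness in the package) and stands in for
instrument data, which are not published. Apparent negative series
resistance - a known artifact of near-90° phase measurements - is accepted
and flagged on input, never generated.

## Numerical and design notes

* Angular grid: 50 nodes uniform in $\theta$, node-centered spherical-zone
  weights summing to $4\pi R^2$ exactly; poles are grid nodes.
* Initial condition: the resting fixed point
  ($\mathrm{ITV}=0$, $N=N_0$, $r_p=r^*$).
* Output grid: dense inside the pulse, log-spaced out to the 1 s
  resealing horizon.
* Problem sizes used by the tests and the reproduction script: 50-node
  membrane (15-25 nodes in property loops), 200² field grids, 40-60 point
  spectra, 50-seed Monte-Carlo for the noisy-fit check - all chosen so the
  full suite runs in well under a minute on one core.
* Signs: the node at $\theta=0$ faces the field vector and carries
  positive ITV; published pole labels sometimes attach "hyperpolarized"
  to the positive reading, so pole summaries report both signed values
  and magnitudes.
* Determinism: the physics core is seed-free; reruns are byte-identical.

## What the synthetic data do and do not show

The generator behind the impedance tests emulates the *structure* of
suspension measurements: a Cole relaxation, monotone voltage ordering,
mid-band sensitivity, log-normal multiplicative noise. It does not emulate
electrode double layers, parasitic inductance, cell sedimentation or
population heterogeneity - passing tests demonstrate the model and its
inversion are self-consistent and satisfy the published trends, not that
they would fit any particular instrument's raw curves. Likewise the
membrane model assumes a perfect sphere (platelets are discoid at rest), a
spatially uniform applied field, axisymmetry, temperature-independent
parameters and a single representative cell rather than a population -
all stated simplifications standard in computational electroporation
studies of suspended cells.

## Known limitations

* Exact parity with mesh-based multiphysics solutions is not expected:
  the default path is the asymptotic uniform-field model, and the
  published pore-model constants were never printed, so constants are
  calibrated (two anchors per cell type, everything else emergent).
* The pore-radius energy model is a mean-radius approximation; it does not
  resolve the pore-size distribution.
* The axisymmetric solver is steady-state; transient field redistribution
  during charging is represented only by the ODE path.
* Joule heating, electrodeformation, electrofusion and multi-pulse
  protocols are out of scope.
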
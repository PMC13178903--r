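---
title: "Methods: relative pressure from 2D velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative pressure from 2D velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relpress)
```

This vignette is the package's own account of its science: the models it
implements, the numerical choices behind them, the defaults and why they
were chosen, and what the synthetic generators can and cannot stand in for.

## 1. The estimator

### Model

For incompressible flow with negligible viscous and external forces, the
momentum balance reduces to the inviscid (Euler) form, which in 2D gives
the pressure gradient componentwise:

$$\frac{\partial P}{\partial x} = -\rho\left(\frac{\partial u_x}{\partial t}
  + u_x\frac{\partial u_x}{\partial x} + u_y\frac{\partial u_x}{\partial y}\right),$$

and analogously for $y$. The pressure drop between a fixed inlet point $a$
and outlet point $b$ is the path integral
$\Delta P = P(a) - P(b) = -\int_{a\to b} \nabla P \cdot \mathrm{d}l$,
which is path independent whenever the reconstructed gradient field is
(close to) conservative. The viscous term is omitted deliberately: for the
cavity-scale, inertia-dominated flows this estimator targets, the viscous
contribution is small, and an inviscid estimator degrades more gracefully
when low velocities are missing from the data than kinetic-energy-based
forms. The omission is not hidden — the Womersley oracle field
(`analytic_field("womersley_axial", ...)`) makes it measurable: on that
flow the estimator's bias equals the analytic viscous term
$\mu \nabla^2 u$, and a dedicated test computes and subtracts it.

The sign convention is pinned throughout to the direct-measurement
definition: $\Delta P = P_\mathrm{inlet} - P_\mathrm{outlet}$. A field with
higher pressure at $a$ yields positive $\Delta P$.

### Discretisation

The discretisation is stated explicitly because every piece of it is
tested for order:

* **Derivatives** — second-order central differences at interior valid
  nodes; first-order one-sided stencils at valid nodes adjacent to a
  domain boundary *or an invalid node*; nodes with no usable stencil are
  marked invalid. The temporal scheme mirrors the spatial one across
  frames. Central differences are exact on linear fields, so the
  stagnation and solid-body-rotation oracles are reproduced to machine
  precision; convergence order is therefore measured on a cubic potential
  flow, where the suite verifies second order on interior paths.
* **Path sampling** — the polyline from $a$ to $b$ is densified to
  arclength steps of half the finer grid spacing and the gradient is
  sampled by *validity-aware bilinear interpolation*: weights of invalid
  cell corners are dropped and the remainder renormalised; a sample with
  no valid corner is itself invalid.
* **Integration** — vector trapezoid rule over the path samples,
  $\sum_i \tfrac12(\mathbf{g}_i + \mathbf{g}_{i+1})\cdot(\mathbf{r}_{i+1}-\mathbf{r}_i)$,
  which handles polyline corners without explicit tangents and makes path
  reversal an exact sign flip (up to roundoff).

### Masking policy

Scanner data arrive with a per-sample tracking quality in $[0,1]$; samples
with TQ $\le$ 0.4 are discarded, the threshold above which TQ is reported
to correlate well with velocity accuracy. Missing data on the path are
never extrapolated silently: the fraction of valid path samples per frame
is reported as *coverage*; within a frame that still meets the
`min_coverage` floor (default 0.9), gaps in the integrand are filled by
linear interpolation along the path; frames below the floor are flagged
invalid and their $\Delta P$ is `NA`. How a scanner handles frames with
absent signal at one endpoint is not standardised; this coverage/validity
policy is this package's own, and it is deliberately conservative.

### Path choice

The default path mode is a fixed straight polyline from $a$ to $b$, held
constant across all frames — matching how inlet/outlet points are fixed
across timepoints of a scan. A streamline mode (`trace_streamline()`:
fixed-step 4th-order Runge–Kutta on the instantaneous direction field,
bilinear interpolation, stagnation floor) is provided because a streamline
is the natural path in the underlying theory, but it is off by default:
whether such a path should be re-traced per frame or fixed once is an open
choice, and on (near-)conservative gradient fields the integral is path
independent anyway, which the suite checks.

### Units

SI internally (m, s, Pa); mmHg only at user-facing surfaces
(`delta_p_series`, trace files). The conversion constant
1 mmHg = 133.322387415 Pa is defined in exactly one place.

## 2. Synthetic generators

### What they emulate

`sample_analytic_field()` produces pristine fields from closed forms;
`emulate_bsi()` then applies, in order: additive isotropic Gaussian noise
per velocity component (reproducible from a seed), low-velocity rejection
applied to the *noisy* speed (the scanner rejects what it measures), and
optional rectangular dropout regions. Rejected samples get `tq_bad`,
retained ones `tq_good`. Reference rejection thresholds are 0.21 m/s
(8 kHz PRF) and 0.13 m/s (4.5 kHz PRF), the values reported for phantom
imaging at those pulse-repetition frequencies.

TQ assignment is binary by design: the scanner's TQ computation is
proprietary, and the downstream estimator consumes only the 0.4 threshold,
so a graded emulation would claim fidelity the package cannot check. The
noise model is the simplest with a controllable SNR; no speckle physics,
beamforming, or scan conversion is claimed. The true noise level and TQ
distribution of any particular scanner are unknown here, so both are free
parameters rather than asserted defaults. Consequently, passing tests show
that the *estimator and protocol* behave correctly under controlled
degradation — they do not certify accuracy on any specific device's data.

### The pump waveform

`make_pulse_waveform()` reproduces the pump programme used with
infant-scale phantoms: a square wave with sine-like ramps at approximately
2.5 L/min peak flow, a 0.2 s pulse and a 1.7 s period (1.5 s of zero flow
between pulses, allowing the gel to relax). "Sine-like" is made concrete
as half-cosine ramps, each occupying `ramp_fraction` (default 0.25) of the
pulse: they join the plateau and the zero segments with continuous value
and slope-zero endpoints and give a closed-form stroke volume
$Q_\mathrm{peak}\,T_\mathrm{pulse}(1-f_\mathrm{ramp})$, used as the test
oracle.

### Coordinate convention

Fixed and documented: $x$ rightward, $y$ upward, arrays indexed
`[frame, y, x]`, metres and seconds internally.

## 3. The lumped phantom

The compliant gel phantom plus flow loop is reduced to an R-C-R network:
a single chamber of compliance $c$ (chamber pressure $P_c$, volume
$c\,(P_c - p_\mathrm{down})$ above reference), an inlet branch with
resistance $r_\mathrm{in}$ and inertance $l_\mathrm{in}$ carrying the
prescribed pump flow, and an outlet branch ($r_\mathrm{out}$,
$l_\mathrm{out}$, then a measurement node and $r_\mathrm{down}$) draining
to a reservoir at $p_\mathrm{down}$:

$$c\,\frac{\mathrm{d}P_c}{\mathrm{d}t} = q_\mathrm{in} - q_\mathrm{out},
\qquad
p_\mathrm{in} = P_c + r_\mathrm{in} q_\mathrm{in}
  + l_\mathrm{in}\dot q_\mathrm{in},
\qquad
p_\mathrm{out} = p_\mathrm{down} + r_\mathrm{down} q_\mathrm{out}.$$

The measurement resistance $r_\mathrm{down}$ exists so the outlet catheter
sees dynamics rather than the constant reservoir pressure. No lumped
parameters for a physical phantom are available, so the shipped defaults
are *illustrative, not fitted*: they are chosen so one default pump pulse
yields a pressure-drop curve with a positive peak of order a few mmHg
during ramp-up and a negative undershoot after the pulse — the qualitative
catheter-curve shape on compliant phantoms. Whether such undershoot is
dominated by chamber compliance or fluid inertance is not settled; both
terms are included and separable by configuration (set $l_\mathrm{in}=0$ or
$c\to$ small to isolate them).

Integration uses `deSolve::lsoda` with the maximum step capped at 5 ms —
comparable temporal resolution to production finite-element practice for
this problem class — and tight tolerances (rtol 1e-9). Cumulative inflow
and outflow volumes are integrated *as ODE states*, so the mass-balance
diagnostic

$$\mathrm{residual} = \frac{\Delta M_\mathrm{acc} + M_\mathrm{out} -
  M_\mathrm{in}}{M_\mathrm{out}}$$

is evaluated solver-consistently (density cancels in the ratio; the
function accepts it anyway for dimensional clarity). On results lacking
those states the flows are integrated by the trapezoid rule; the suite
verifies that this fallback converges at order two in the output step
until it reaches the ODE-solver floor near 1e-9. Measurement noise is
additive Gaussian on the two pressure traces only — the simplest catheter
noise model sufficient to exercise the pulse-analysis stage.

## 4. The Womersley benchmark

### Analytic layer

For a rigid tube of radius $R$ driven by a favourable axial gradient
$k(t) = K_0 + \sum_n \Re(K_n e^{i\omega_n t})$ (Pa/m), the fully developed
axial velocity is the Poiseuille profile for $K_0$ plus, per harmonic, the
classical profile

$$u_n(r,t) = \Re\!\left[\frac{K_n}{i\rho\omega_n}
 \left(1 - \frac{J_0(\Lambda_n r/R)}{J_0(\Lambda_n)}\right)
 e^{i\omega_n t}\right],
 \qquad \Lambda_n = i^{3/2}\alpha_n,$$

with Womersley number $\alpha_n = R\sqrt{\omega_n\rho/\mu}$ — the
dimensionless parameter governing how far the flow rate lags the driving
gradient (approaching a quarter period as $\alpha \to \infty$, which the
suite measures by cross-correlation). $J_0, J_1$ of complex argument are
evaluated by their power series with adaptive truncation at 1e-17 relative;
this is accurate for $|\Lambda| \lesssim 30$, far beyond the
$\alpha \approx 4.8$ of the default configuration, and is documented as the
valid range.

### Numerical layer

`solve_tube_numeric()` re-creates, at desk scale, the verification exercise
in which a flow waveform is prescribed at the inlet and the driving
pressure is *recovered* rather than imposed. It advances the axisymmetric
axial momentum equation

$$\frac{\partial u}{\partial t} = \frac{g(t)}{\rho}
 + \nu\left(\frac{\partial^2 u}{\partial r^2}
 + \frac1r\frac{\partial u}{\partial r}\right)$$

implicitly on a uniform radial grid (no-slip at the wall; the axis row uses
the symmetry limit $2\,\partial^2 u/\partial r^2$), solving at each step
for the spatially uniform $g(t)$ that makes the trapezoid radial quadrature
of $u$ equal the prescribed $Q(t)$. Because the system is linear, this
constraint is solved exactly by superposition of a precomputed
unit-gradient response — one matrix factorisation for the whole run. Time
stepping is BDF2 after a backward-Euler start (a pure backward-Euler
variant exists); the step is capped at 5 ms and must resolve the fastest
harmonic by at least 50 steps. The simulation starts from rest, so enough
periods must be run for the diffusive transient (time scale
$\approx \rho R^2 / (5.78\,\mu) \approx 1.1$ s for the defaults) to decay;
the default is 8 periods of 1.7 s, after which the transient is below
1e-5 of the signal.

The benchmark tube dimensions are this package's own choice (R = 5 mm,
L = 0.1 m, blood-mimicking fluid: $\rho$ = 1037 kg/m³, $\mu$ = 4.1 mPa·s,
f = 1/1.7 Hz): with them the recovered pressure-drop amplitude matches the
closed form to about 0.04%, comfortably within the 0.5% verification
criterion, and halving the resolution changes the cycle maxima and stroke
volume by well under 1%. For oscillatory zero-mean waveforms "stroke
volume" is taken as the forward volume per cycle (time integral of the
positive part of $Q$), which keeps the convergence ratio well defined.

## 5. Material models

The gel is characterised by two constitutive models. The Yeoh uniaxial
first Piola–Kirchhoff stress, under isotropy and incompressibility, is

$$T = 2(\lambda - \lambda^{-2})\left[c_1 + 2c_2(I_1-3) + 3c_3(I_1-3)^2\right],$$

with shipped gel parameters $c = (7300, 9400, 0)$ Pa. The isochoric
invariant for uniaxial extension is taken in its standard form
$I_1 = \lambda^2 + 2/\lambda$ (the incompressible uniaxial kinematics),
stated here because the stress formula alone does not fix it. The equation
is implemented exactly as written — engineering stress in, engineering
stress out; no conversion to true stress is attempted because the
provenance of any particular data set's stress measure is a property of
that data set.

`fit_yeoh()` exploits that $T$ is linear in $(c_1,c_2,c_3)$ once
$2(\lambda-\lambda^{-2})$ is factored out: the fit is an exact linear
least-squares solve (QR), with standard errors from the usual linear-model
theory. This avoids starting values and convergence diagnostics entirely
and makes recovery testable to machine precision on clean data. Fixing
$c_3 = 0$ is a flag; a genuinely cubic data set then shows up as a
residual norm far above the noise floor, which the suite checks.

The Kelvin–Voigt model $\sigma = E\varepsilon + \eta\dot\varepsilon$
carries the gel's dynamics with retardation time $\tau = \eta/E$
(defaults give $\tau$ = 0.01 s, the gel's approximate value). Strain rates
for measured histories are computed with the same central/one-sided
finite-difference scheme as the velocity fields, for consistency across
the package. Creep under constant stress is simulated by inverting the law
as an ODE; the closed form
$\varepsilon(t) = (\sigma_0/E)(1 - e^{-t/\tau})$ is the test oracle.

## 6. The measurement protocol

Direct-measurement practice on pulsatile phantoms records six pump pulses,
discards the first three (flow and pressure establishment) and averages
the next three pointwise into representative inlet and outlet curves;
$\Delta P$ extrema are read off the averaged curve (average first, then
extract, matching the protocol order). `segment_pulses()` locates pulse
starts either on the shared pump clock (when the waveform is available) or
by upward threshold crossings with hysteresis; `representative_curve()`
implements the discard/average rule with both counts exposed.

`timing_shift()` measures inter-method lags as the maximiser of the
normalised cross-correlation — each window demeaned on its own support —
refined by parabolic interpolation of the correlation peak, giving
sub-sample resolution; positive lag means the second curve trails the
first.

`compare_methods()` produces the replicate summary in the shape of a
phantom-study table: per-group mean ± SD, a one-way ANOVA across groups,
and pairwise Welch (unequal-variance) two-sample t-tests, two-sided at
$\alpha = 0.05$. The choice of these particular tests is this package's
own, made to match the comparison structure (across depths; between
methods) commonly reported; it is recorded in the output object. No
multiple-testing correction is applied by default, mirroring
per-comparison reporting, but any `p.adjust` method can be switched on.
Groups with a single replicate get no SD and their tests are flagged as
skipped, never silently dropped. SDs are computed across replicates (per
scan), not across pulses within a recording — the protocol averages pulses
before extrema are taken, so within-recording variation is consumed by the
averaging step; this choice is documented here because reported ± values
in the literature are sometimes ambiguous on it.

## 7. Reproducibility and I/O

Every stochastic component (scanner noise, catheter noise) takes an
explicit integer seed and restores the caller's RNG state afterwards; the
suite checks bit-identical reruns of the full chain from seeded phantom
simulation to summary statistics. Velocity fields interchange in two
layouts — long-format CSV (`frame,t,x,y,ux,uy,tq,valid`) and a single-file
RDS container with named arrays plus a units/convention metadata block —
and the reader validates grid uniformity, TQ range and finite velocities
on load. `run_pipeline()` executes any configured step (JSON/YAML or an R
list), echoes all parameters, refuses stochastic steps without a seed, and
returns an output manifest with MD5 checksums, so any run can be
re-executed byte-identically from its log. Text interfaces use
comma-separated values with a mandatory header, `.` decimal and UTF-8;
pressures in files are mmHg.

## 8. Problem sizes used in the checks

The shipped verification suite uses: 64 radial nodes and a 2.5 ms step
(8 periods) for the tube benchmark, against 32 nodes / 5 ms for the
convergence comparison; a 1 ms output grid over one 1.7 s cycle (maximum
internal step 5 ms) for the phantom mass balance; scan grids of 21–81
nodes per side and 3–10 frames for the estimator oracles; and 20-point
stretch sweeps for the material fits. These sizes were chosen as the
smallest at which each quantity's asymptotic behaviour (convergence order,
transient decay) is clearly established.

## 9. Known limitations

* The estimator is strictly 2D and inviscid: out-of-plane flow and viscous
  gradients are invisible to it, and no Poisson-equation full-field
  pressure reconstruction is attempted (path integral only).
* The scanner emulation starts at the velocity-field level; no speckle,
  beamforming or scan-conversion physics, and no claim that its noise/TQ
  parameters match any particular device.
* The lumped phantom reproduces curve shape and protocol, not the mmHg
  values of any physical phantom; its parameters are illustrative.
* The tube solver is rigid-wall and 1D-radial; it verifies the
  pressure-coupling approach, not 3D fluid–structure interaction.
* The constitutive models are uniaxial (Yeoh) and small-strain linear
  viscoelastic (Kelvin–Voigt); no multiaxial or shear evaluation, and no
  coupling into a deformable-wall flow solver.
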
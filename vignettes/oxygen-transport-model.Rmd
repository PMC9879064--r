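---
title: "Modelling intermittent-hypoxia delivery into 3D culture scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intermittent-hypoxia delivery into 3D culture scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxcycle)
```

## The physical system and the model

The experimental configuration this package models is a culture well whose
bottom is a thin gas-permeable PDMS membrane (typically 165 µm). A gas
chamber beneath the membrane is flushed with a square wave of oxygen
fraction — e.g. 30 s of 20% O₂ followed by 30 s of 0% O₂, mimicking
60 apnea events/h — and a 3D scaffold (an ECM hydrogel or a precision-cut
tissue slice, 300–800 µm) sits on the membrane. Cells inside the scaffold
experience whatever oxygen waveform survives diffusion through membrane
and scaffold; an optical microsensor inserted at depth z is how such
set-ups are characterised experimentally.

`oxcycle` treats this as one-dimensional multilayer reaction–diffusion.
The state variable is the oxygen **partial pressure** u(z, t) in mmHg,
which is continuous across material interfaces (the standard Henry-law
interface condition); the dissolved concentration in a layer with
solubility α (mol·cm⁻³·atm⁻¹) is C = α·u/760. Within each layer

$$\alpha'\,\frac{\partial u}{\partial t}
  = \frac{\partial}{\partial z}\!\left(D\,\alpha'\,\frac{\partial u}{\partial z}\right)
  \;-\; \rho_{cell}\,\mathrm{sOCR}\,\frac{\alpha' u}{K_m + \alpha' u},
  \qquad \alpha' = \alpha/760,$$

with D the layer diffusivity (cm²/s), ρ_cell the cell density (cells/cm³),
sOCR the maximal per-cell oxygen consumption rate (mol·cell⁻¹·s⁻¹) and K_m
the Michaelis constant (mol/cm³). The bottom boundary is Dirichlet in
partial pressure, equal to the gas-chamber fraction times 760 mmHg — the
chamber is treated as well mixed, with an optional first-order washout lag —
and the top boundary is one of: sealed (`top_no_flux()`, the default),
held at a fixed fraction, or an explicit media layer.

Internally every quantity lives in one canonical unit system — cm, s,
mol/cm³, mmHg, fractions in [0, 1] — and user-facing %O₂ is converted only
at the boundary. This is deliberate: the field mixes %, mmHg and atm
freely, and a single internal system prevents unit slips.

### Why partial pressure and not concentration

Concentration is discontinuous at a PDMS–water interface (the two phases
dissolve different amounts of O₂ at the same chemical potential), and PDMS
oxygen solubility is rarely reported alongside diffusivity. Working in
partial pressure sidesteps both problems; the PDMS solubility default (the
water value) only affects the membrane's — tiny — storage capacity, not
the fluxes at steady cycling, and it is flagged with a warning whenever it
is defaulted from a configuration file.

## Numerical scheme

The solver is a vertex-centred finite-volume discretisation with nodes on
every layer interface. Face conductances are D·α′/Δz per edge; because an
interface node joins two half-edges in series, the effective interfacial
permeability is the harmonic mean of the two layers' D·α′ — which
conserves flux exactly across the membrane–scaffold junction. Time
stepping is θ-weighted implicit (backward Euler, θ = 1, by default;
trapezoidal θ = 0.5 available), and the Michaelis–Menten sink is solved
fully implicitly by Newton iteration with an analytic tridiagonal
Jacobian. Solving the full nonlinearity — rather than lagging the
coefficient — keeps the sink below its saturation bound and the solution
non-negative; values below −10⁻⁹ mmHg abort with an error, smaller
round-off negatives are clipped to zero.

Numerical choices that matter:

- **Phase alignment.** Square-wave transitions are placed exactly on time-
  step boundaries (the stepper subdivides each phase uniformly), so the
  driving waveform is never smeared across a step.
- **Backward Euler default.** The square-wave drive has discontinuities;
  trapezoidal stepping rings on them while backward Euler damps them. For
  smooth (sinusoidal) validation runs θ = 0.5 is the right choice and is
  what the oracle comparisons use. The default step is period/600 (0.1 s
  at 60 events/h).
- **Initial condition.** Uniform at the schedule's high fraction, because
  samples equilibrate in a normoxic incubator before cycling begins.
- **Periodic steady state.** Whole cycles are iterated until no node's
  cycle maximum or minimum moves by more than `psss_tol` (default
  10⁻³ %O₂) between consecutive cycles; the converged cycle and the cycle
  count are returned. The stopping rule is monotone in the tolerance.
- **Degenerate inputs.** A constant schedule (high = low) is legal for the
  solver (it converges to the flat solution in a few cycles) but is an
  identifiability error for the fit, which it reports as such.

The solver is validated in the test suite against independent closed
forms: the exact linear steady state; the half-space erfc step response at
early times; the periodic slab transfer function
|cosh(γ(W−z))/cosh(γW)|, γ = √(iω/D), within 1% at Δz ≤ W/100 and
Δt ≤ period/200; square-wave envelopes against Fourier synthesis over 51
odd harmonics within 2%; exact mass conservation in a sealed slab; and
second-order spatial convergence under grid halving. The Michaelis–Menten
sink is checked in both kinetic limits (zero-order parabola, first-order
cosh profile).

## Closed-form estimates

Two desk-scale formulas frame every design:

- the slab diffusion time **Δt = L²/(6D)**. The factor 6 is the
  three-dimensional (spherical) convention, and this package implements it
  verbatim because it is the convention used in this field's worked
  estimates — but note that for a planar slab driven from one face the
  slowest relaxation mode has τ₁ = 4W²/(π²D) ≈ 2.4 × L²/(6D), so the
  conventional figure *underestimates* planar response times. With
  D = 1.87×10⁻⁵ cm²/s it gives 22 s at 500 µm and 57 s at 800 µm against
  a 60 s cycle.
- the **consumed-to-diffused flux ratio**
  V′_con/V′_dif = ρ_cell·sOCR·C_mean·W² / (D·α·ΔP·(K_m + C_mean)). The
  package's convention for C_mean, which the formula's sources leave
  unstated, is the concentration at the arithmetic mean of the two driving
  fractions (10% O₂ for a 20/0 drive), overridable via `flux_spec()`. With
  the literature hepatocyte parameter set at W = 500 µm the ratio
  evaluates to 1.5×10⁻³. Published discussions of this benchmark quote a
  negligibility figure of 0.015; no physically sensible C_mean in the
  0–20% O₂ range reproduces that exact number from the same inputs (the
  computed ratio is an order of magnitude smaller), so this package treats
  0.015 as an upper bound that the computed ratio satisfies comfortably,
  and does not tune constants to match it. Either way the conclusion is
  the same: consumption is negligible in thin constructs, with the ratio
  growing as W².

## Envelope analysis and the design verdict

At periodic steady state the biologically relevant summary is the
per-depth envelope: maximum, minimum, amplitude and cycle mean of %O₂ over
one cycle. `design_report()` combines the envelope with two criteria: the
amplitude at the top of the sample must reach a set fraction (default
50%) of the driving amplitude, and the spread of envelope maxima and of
minima across depths must each stay within 2 %O₂. The spread — a range, in
%O₂ — operationalises the field's "variance below 2% O₂" uniformity
criterion in the quoted unit (a literal variance would carry %²).

Under this 1D model, 60 events/h cycling through a 500 µm hydrogel retains
11% of the driving amplitude at the top surface, and an 800 µm hydrogel
2% — a five-fold difference from a 1.6-fold thickness change, as the W²
dependence of the diffusion time predicts. The diffusive penetration depth
at a 60 s period is √(2D/ω) ≈ 190 µm, so *no* purely diffusive 500 µm
slab can deliver half the driving amplitude at its top; measured wells
nonetheless show much stronger transmission (see limitations), so the
verdict's default threshold of 0.5 should be read as a conservative,
model-based screen.

## The synthetic sensor and what it does (not) capture

The sensor emulator reproduces the measurement chain of a fibre-optic O₂
microprobe: linear interpolation of the field at the sensor depth, a
first-order lag with τ = t90/ln 10 (the probe spec gives only a 90%
response time, < 2 s; a single-pole response is the simplest model
consistent with one quoted number), resampling at the recording rate
(default 1 Hz), and additive Gaussian read noise (default 0.2 %O₂),
drawn under an explicit seed. Noise is added to the recorded samples
*after* resampling so that the configured `noise_sd` is exactly the
standard deviation of the stored readings; adding it at the field
resolution and then interpolating would silently shrink it. Noise
magnitude and sampling rate are synthetic-only choices — the instrument's
true values are not published — and are deliberately small relative to the
20 %O₂ driving swings. Not modelled: sensor drift, photobleaching, and
averaging over the ~40 µm tip (treated as a point).

All randomness flows from explicit integer seeds (the generator's master
seed derives per-trace seeds arithmetically), the caller's RNG state is
restored afterwards, and regenerating a benchmark suite from its manifest
is bit-identical.

## Diffusivity recovery

The inverse problem matches the forward model — run to steady cycling,
sampled at the trace depths, lag-filtered with the *known* sensor τ — to
observed traces in least squares, on log10-transformed parameters within
positive bounds (default: a factor 10 around the template value). Design
choices:

- **τ is not fitted.** It is a single quoted probe constant, and at 60 s
  periods it is only weakly identifiable jointly with D.
- **Consumption is fitted only as the lumped product ρ_cell·sOCR** with
  K_m fixed: at physiological pressures α′u ≪ K_m, the sink is effectively
  first order, and the three parameters are jointly unidentifiable from
  concentration traces.
- **Optimisation.** With one unknown (D), Brent's method over the whole
  bounds interval — a global bounded search, which for a one-dimensional
  problem is both cheaper and more robust than repeated local starts. With
  two unknowns, L-BFGS-B from three log-spaced starts, returning the best
  converged start. Standard errors come from the finite-difference
  curvature of the residual sum of squares at the optimum (delta method
  back to the natural scale).
- **Time-origin invariance.** Trace times are reduced modulo whole periods
  before matching, so recordings started at any cycle boundary fit
  identically. Whether a supplied experimental trace is truly at periodic
  steady state cannot be judged from the file alone; the synthetic traces
  are generated at steady cycling by construction.
- **Burn-in.** The forward model inside the objective runs a fixed,
  deterministic number of cycles (enough for the slowest planar mode to
  decay by e⁻⁶, starting from the schedule-mean fraction), rather than an
  adaptive stopping rule, keeping the objective smooth in D.

At the study conditions used throughout the package — 4 depths
(100–400 µm), 3 cycles, t90 = 2 s, 0.2 %O₂ noise, grid spacing 10 µm,
step 0.1 s — the tests recover D noiselessly to well under 0.5% and with
noise to a median error of a fraction of a percent over 20 seeded
replicates, with longer recordings tightening the estimate. These problem
sizes (about 70 grid nodes, 600 steps per cycle, tens of cycles per
solve) keep a full replicate study in the minutes range on a single core.

## Known limitations

- The model is strictly 1D. Real PDMS wells have gas-permeable *side
  walls* and finite lateral extent; measured envelopes in such wells show
  substantially stronger deep-sample transmission than any 1D transport
  model with these diffusivities can produce. Conclusions about absolute
  deep-sample amplitudes should lean on measurements; the model's
  comparative statements (thickness and frequency scaling, depth ordering)
  are robust.
- The experimental top-of-sample condition (a media column above
  hydrogels, carbogen-bubbled bath around slices) is not well
  characterised; all three top-boundary options are exposed so designs can
  be bracketed, with `top_no_flux()` as the default.
- No temperature corrections (diffusivities and solubility are taken as
  configured, though measurements span 23–37 °C), no advection, no CO₂
  coupling (CO₂ diffusivity constants are provided for hypercapnia
  estimates), and no cell growth or death during exposure.
- Passing the synthetic-data tests demonstrates internal consistency of
  solver, sensor model and fit under the stated noise model; it does not
  validate the transport model against a particular physical well beyond
  the qualitative behaviour described above.
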
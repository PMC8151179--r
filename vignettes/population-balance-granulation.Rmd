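---
title: "Compartmental population balance modelling of twin-screw wet granulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental population balance modelling of twin-screw wet granulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A twin-screw wet granulator is treated as a short chain of well-mixed
compartments: a wetting zone (conveying elements, low shear) followed by
kneading zones and the outlet (high shear). In each compartment the granule
population evolves by a one-dimensional population balance over particle
volume $x$ (µm³),

$$
\frac{\partial n}{\partial t} =
\frac{1}{2}\int_0^x \beta(x-\epsilon,\epsilon)\, n(x-\epsilon)\, n(\epsilon)\, d\epsilon
- \int_0^\infty \beta(x,\epsilon)\, n(\epsilon)\, d\epsilon\, n(x)
+ \int_x^\infty b(\epsilon, x)\, S(\epsilon)\, n(\epsilon)\, d\epsilon
- S(x)\, n(x),
$$

with aggregation only in the wetting zone and aggregation plus breakage in
the kneading zones. The aggregation kernel factors into a constant
efficiency $\beta_0$ (1/time) and a collision frequency $\beta(x,\epsilon)$;
breakage uses a linear selection function $S(m) = S_0\, m^{1/3}$ and a
daughter density combining erosion (a Gaussian population of small
fragments) with binary splitting. Residence time is not modelled separately:
each compartment is integrated over one dimensionless time unit and the rate
constants $\beta_0$, $S_0$ absorb the true residence time.

### Aggregation kernels

Sum and product kernels cannot turn a unimodal feed into the bimodal
distributions observed after the wetting zone; a size step in the collision
frequency can. Four step shapes are implemented (`aggregation_kernel()`):

* `tanh_double_step` — the historical smoothed double step: multiplier
  `top2` for small sizes, `top1` between the two step radii and zero above
  the upper one, blended by `tanh` smoothers in volume space, times
  $x^{1/3}\epsilon^{1/3}$. The upper step is parked at 7000 µm equivalent
  diameter, above every representative size of the working grid, so it is
  deliberately invisible; grids are refused if they would reach it, which is
  also what guarantees no mass can aggregate off the grid.
* `circle_step` — sharp step on the circle
  $(x^2+\epsilon^2)^{1/2} = R^3$ in the volume plane. The printed source
  form of this condition is ambiguous; it is evaluated as
  $(x^2+\epsilon^2)^{1/2} \le R^3$ for structural consistency with the
  double step's distance function, a reading flagged in the documentation
  rather than asserted.
* `square_step` — multiplier 1 when **both** equivalent diameters are
  strictly below the critical size $R$, `step` otherwise, times
  $(x\epsilon)^{1/3}$.
* `square_step_power` — the square step with a free exponent $p$
  (default 2/5); $p = 1/3$ recovers `square_step` exactly.

Strict versus weak inequality at $R$ matters only for a representative size
exactly at $R$ — which is the normal case, because $R$ is restricted to
representative sizes. The strict convention is used for both square
variants: it is the form the final power-step kernel is written in, and it
is the convention under which the fines peak of a forward simulation
depletes in $R$'s own size category, so reading the depletion point off a
PSD returns exactly the $R$ that generated it. A relative tolerance of
$10^{-12}$ keeps the bin at $R$ deterministically in the upper region
despite volume/diameter round-trip rounding; without it, floating point
noise made some adjacent representative $R$ values produce identical kernel
matrices.

### Breakage

The daughter density for a mother of volume $m$ is

$$
b(m, d) = f_{prim}\,\frac{1}{\sqrt{2\pi}\,\sigma}
  e^{-\frac{(d^{1/3}-\mu)^2}{2\sigma^2}}\,\frac{m}{\mu^3}\,\frac{1}{3d^{2/3}}
  + (1-f_{prim})\,\frac{2}{m}.
$$

The erosion Gaussian lives on the cube-root-volume scale: $\mu$ and $\sigma$
are in µm on that scale, and when $\mu$ is tied to the depletion size the
value is used as printed rather than converted through the equivalent-sphere
factor $(\pi/6)^{1/3}$; the source model does the same, and the convention
is documented rather than hidden.

The continuous density is only approximately mass-conserving (its Gaussian
is truncated at $d = 0$ and $d = m$). Discretely, each mother column of the
redistribution matrix is built by fixed-pivot assignment — the closed-form
daughter number and mass on each inter-pivot volume segment (Gaussian
partial moments for the erosion term, linear expressions for the binary
term) are split between the bracketing representatives so that both are
conserved — and then rescaled so the discrete daughter mass equals the
mother volume exactly. Naive per-bin integration with daughters lumped at
bin representatives cannot reproduce the exact daughter count of binary
breakage on any feasible grid (the midpoint quadrature error in the mass,
$(\ln\rho)^2/8$ per volume ratio $\rho$, feeds straight into the rescale);
the pivot form recovers it to $10^{-9}$ and is the same sectional scheme the
aggregation term uses. Because daughters never exceed their mother, the
rescaled daughter count per event is at least one, so pure breakage can
never destroy particles.

### Discretization and integration

Particle volume is discretized on a geometric grid (default 35 bins,
diameters 1–4000 µm, fixed throughout an analysis). Aggregation uses the
fixed-pivot sectional scheme: each newborn volume $v_i + v_j$ is split
between the two bracketing representatives with weights that conserve
number and mass simultaneously. Pairs whose aggregate would exceed the
largest representative are not formed at all — they contribute neither birth
nor death — so no mass can leave over the top of the grid; this mirrors the
role of the invisible upper kernel step.

The combined right-hand side is integrated with an adaptive embedded
Dormand–Prince 5(4) pair written in C++ (no ODE solver package ships with
the supported environment, and the calibration and sweep workflows need
thousands of forward runs). Defaults: relative tolerance $10^{-8}$, absolute
tolerance $10^{-10}$ times the inlet particle count. Because total volume is
a linear invariant of the right-hand side, any Runge–Kutta step conserves it
to rounding; the integrator nevertheless verifies a relative mass drift
below $10^{-6}$ and aborts otherwise. Negative undershoots beyond the
absolute tolerance abort; smaller ones are clipped to zero and counted in
the diagnostics.

## Comparing distributions

Calibration and identifiability both compare PSDs with the energy distance
(a maximum mean discrepancy),

$$
D(u, v) = \left( 2\,E|X-Y| - E|X-X'| - E|Y-Y'| \right)^{1/2},
$$

computed on volume-fraction weights over the representative diameters in µm
(measured granule PSDs are reported and compared as volume fractions; the
support convention is a choice, and a log-diameter option is provided but
off by default). The computation is grouped so the result is exactly
symmetric in floating point, and the squared form is clamped at zero before
the root.

The measurement-error threshold is the median of all unordered pairwise
energy distances among repeated measurements (`measurement_error_threshold()`);
the median rather than the mean, for robustness to outlier replicates. A
parameter value whose sweep distance falls below this threshold cannot be
distinguished from the optimum by the available data.

## Practical identifiability

On a sectional grid, a step-location parameter changes the model only when
it crosses a representative size, so its distance profile is a staircase.
`sweep_parameter()` records the profile (min–max normalized, as the
diagnostic plots in this field are drawn), `detect_plateaus()` splits it
into maximal runs whose consecutive normalized distances vary by less than
`flat_tol` ($10^{-3}$ by default), and `uniqueness_below_threshold()` counts
swept values below the measurement error. The practical verdict: a
parameter is identifiable at a given error level when exactly one swept
value lies below the threshold. For the smoothed double step a whole
plateau of step radii is typically indistinguishable; for the square step
restricted to representative sizes, each candidate is a genuinely different
model and only the generating value survives — which is the argument for
preferring it. `discretized_step_levels()` quantifies how the smooth step
collapses on the grid: for a sharp smoother at most two multiplier values
fall strictly between the plateaus.

## Calibration and parameter reduction

`calibrate_wetting()` and `calibrate_kneading()` minimize the energy
distance between a simulated compartment outlet and a target PSD with a
constriction-type particle swarm (no PSO package is available in the
supported environment): 30 particles, inertia 0.72, cognitive and social
weights 1.49, reflecting bounds, seeded and fully reproducible. Two
numerical choices matter:

* `beta0` and `step` are searched on a log10 scale. Both span several
  decades ($[10^{-16}, 10^{-6}]$ and $[1, 10^4]$ by default); on a linear
  scale the swarm collapses into the `step * beta0` compensation valley and
  returns a grossly wrong split between the two.
* The iteration budget defaults to 250. With 150 iterations the best
  objective on noise-free recovery problems stalls around $5\times10^{-6}$;
  the trace typically passes $10^{-6}$ near iteration 185 and reaches
  machine zero by 250. The budget is still desk-scale (tens of seconds per
  compartment).

A forward simulation that fails inside the swarm (an extreme parameter
combination exceeding the integrator's step budget) scores a finite penalty
of $10^3$ — far above any physical distance on the working grid — rather
than aborting the calibration. Parameters given collapsed bounds
(lower = upper) are pinned at that value and removed from the search, which
is how, for example, a kneading calibration with the `S0` bounds collapsed
to zero degenerates cleanly into a pure-aggregation fit.

The parameter-reduction protocol (`reduce_parameters()`) removes three
parameters from the calibration before it starts. The depletion point — the
first local minimum after the first local maximum of the lightly smoothed
(centred width-3 moving average) volume-fraction curve, ties broken toward
the smaller size — sits in the same size category across liquid-to-solid
ratios for a formulation, so the critical size $R$ is read off the wetting
PSDs by majority vote instead of calibrated. The erosion mean is tied to the
same size, $\mu = R$, and the spread fixed at $\sigma = 50$ µm (neither high
nor low dispersion). That leaves exactly two free wetting parameters
(`step`, `beta0`) and three free kneading parameters (`beta0`, `S0`,
`fprim`), versus three and five in a naive full calibration. The smoothing
width and tie rule are this package's choices; the protocol's source
describes the concept but no algorithm.

## The synthetic world

No measured PSDs are distributed, so `generate_preblend()`,
`generate_compartment_targets()` and `generate_repeated_measurements()`
stand in for them.

* The preblend is a log-normal number distribution in diameter (median
  50 µm, geometric standard deviation 1.6 by default), evaluated
  deterministically on the grid. Its volume-fraction view is unimodal with
  mode near $50\,e^{3(\ln 1.6)^2} \approx 97$ µm — a plausible
  lactose/cellulose preblend; the true preblend shapes of real formulations
  are not published, and the log-normal is a labelled stand-in.
* The total particle count defaults to $5\times10^7$ per reference volume.
  This is the one free scale the sources never state; it was chosen once so
  that, with the documented aggregation efficiency $\beta_0 = 7\times10^{-12}$
  over one dimensionless residence time, the aggregation number
  $\beta_0\,\beta\,N\,t \approx 2$ at the preblend volume mode — the
  partial-granulation regime in which wetting-zone PSDs come out bimodal,
  as observed experimentally. It is not revisited per test.
* Measurement noise is multiplicative log-normal per bin with the log-scale
  growing linearly toward the large-particle end (default: the last bin
  twice as noisy as the first), mirroring the qualitative behaviour of
  granule-size measurements; replicates are renormalized to the original
  total volume. Liquid-to-solid ratio is represented only through its
  modelled consequences (higher $\beta_0$ shrinks the fines peak); no
  L/S-to-parameter mapping is asserted.

What a green test does establish: conservation and oracle agreement of the
solver, the staircase/uniqueness structure of the identifiability
workflow, and that the calibration machinery recovers known generating
parameters from its own forward model. What it does not establish: fidelity
to any real formulation, instrument effects (dispersion, optics,
frame-rate artifacts), residence-time or screw-speed dependence, or the
accuracy of the kernels' physics — the kernels are deliberately empirical.

## Known limitations

* One internal coordinate (volume); liquid content and porosity are lumped.
* Rates are per-compartment constants; no axial resolution within a zone.
* The explicit integrator is not suited to extremely stiff corners of the
  parameter space (they surface as penalized evaluations during swarm
  search).
* The depletion-point detector assumes a bimodal volume-fraction shape; on
  strictly unimodal data it returns a flagged no-depletion outcome and the
  protocol advises full calibration of $R$.
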
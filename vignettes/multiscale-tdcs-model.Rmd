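---
title: "A multiscale bidomain model of transcranial direct current stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale bidomain model of transcranial direct current stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsbidomain)
```

## The model

Transcranial direct current stimulation (tDCS) drives a milliampere-scale
direct current between scalp electrodes. Classical forward models treat the
head as a passive volume conductor and solve the stationary Laplace problem
$\nabla\cdot(M\nabla\Phi) = 0$ for the potential $\Phi$, which predicts the
electric field and current density but says nothing about what the field
does to neurons. This package couples that volume conductor to continuum
neuronal membrane dynamics, so that the stimulation current, the
extracellular potential, and the transmembrane voltage $v$ evolve together.

In the brain domain $\Omega_B$ (grey and white matter) the bidomain
equations hold: intracellular and extracellular media coexist at every
point with conductivity tensors $M_i$ and $M_e$, coupled through the
membrane with surface-to-volume ratio $\chi$ (1/m) and capacitance per
area $C_m$ (F/m²):

$$\nabla\cdot(M_i\nabla v) + \nabla\cdot(M_i\nabla\Phi)
  = \chi C_m \frac{\partial v}{\partial t} + \chi I_{ion}(v, w),$$
$$\nabla\cdot(M_i\nabla v) + \nabla\cdot\big((M_i+M_e)\nabla\Phi\big) = 0.$$

Outside the brain (cerebrospinal fluid, skull, scalp) there are no
excitable cells; only $\nabla\cdot(M_e\nabla\Phi) = 0$ holds. Intracellular
current cannot leave the brain: $n\cdot M_i\nabla(v+\Phi) = 0$ on
$\partial\Omega_B$. In the finite-element formulation this no-outflow
condition is automatic, because the intracellular blocks integrate over
$\Omega_B$ only, with no boundary terms. $\Phi$ and the normal
extracellular current are continuous across $\partial\Omega_B$ because a
single conforming $\Phi$ field spans the whole head.

Electrodes enter through the scalp boundary conditions: the anode injects
a prescribed inward current density ($n\cdot M\nabla\Phi = I$), the
cathode is grounded ($\Phi = 0$), and the rest of the scalp is insulated
($n\cdot M\nabla\Phi = 0$).

### Membrane kinetics

Membrane dynamics use the two-variable FitzHugh–Nagumo model mapped onto
physiological voltages, with `v_rest = -70` mV, `v_peak = +40` mV,
threshold $v_{th} = v_{rest} + a\,v_{amp}$:

$$\frac{dv}{dt} = \frac{c_1}{v_{amp}^2}(v - v_{rest})(v - v_{th})(v_{peak} - v)
   - R(v, w) + I_{app}, \qquad
  \frac{dw}{dt} = b\,(v - v_{rest} - c_3 w),$$

with $a = 0.13$, $b = 13$/s, $c_1 = 260$/s, $c_2 = 100$/s, $c_3 = 1$ — the
classic dimensionless FitzHugh parameter set with time scaled to seconds.

The recovery coupling $R(v,w)$ deserves a note. The default is the
Rogers–McCulloch dimensionalization $R = c_2\,(v - v_{rest})\,w/v_{amp}$,
which is where this exact parameter set comes from and which supports
*sustained* propagating action potentials. The simpler linear coupling
$R = c_2 w$ (available as `fhn_params(recovery = "linear")`) produces, with
the same constants, only a decremental wave that extinguishes within a few
centimeters: the recovery current does not vanish at the resting potential
ahead of and behind the front, so the medium cannot re-excite. Both forms
share the resting fixed point $(v_{rest}, 0)$ and the cubic nullcline at
$w = 0$, so all membrane-level worked examples are identical between them.

```{r}
p <- fhn_params()
threshold_voltage(p) * 1000   # mV
```

### Numerics

Each global step $\Delta t$ (default 1 ms) is split in the Godunov way:

1. **Reaction.** The membrane ODEs are advanced nodewise with Heun's
   explicit trapezoidal method at substep $\Delta t_{ODE}$ (default
   0.5 ms, i.e. two substeps), giving the partial solution $\tilde v$.
   Heun is second order; the suite verifies an empirical slope of
   $2.0 \pm 0.2$ against a fine Runge–Kutta reference.
2. **Diffusion.** One implicit-Euler step of the coupled elliptic system,
   discretized with P1 (linear) triangular finite elements, yields the
   symmetric block system
   $$\begin{pmatrix} A & B \\ B^T & C \end{pmatrix}
     \begin{pmatrix} v \\ \Phi \end{pmatrix} =
     \begin{pmatrix} \alpha \\ 0 \end{pmatrix},$$
   with $A = \mathrm{mass}(\Omega_B) + s\,K(M_i,\Omega_B)$,
   $B = s\,K(M_i,\Omega_B)$,
   $C = s\,[K(M_i{+}M_e,\Omega_B) + K(M_e,\Omega\setminus\Omega_B)]$,
   $\alpha = \mathrm{mass}(\Omega_B)\,\tilde v$, and
   $s = \Delta t/(\chi C_m)$. Transmembrane degrees of freedom live on
   brain nodes only (interface nodes included); $\Phi$ on all nodes. All
   element integrals are exact (P1 gradients are constant; the mass matrix
   uses the exact order-2 rule). The recovery variable $w$ is frozen
   during this step.

The block system is solved with conjugate gradients, preconditioned by a
block-diagonal operator made of independent relaxed ILU(0) factorizations
of $A$ and of the constrained $C$ (relaxation $\omega = 0.5$; dropped fill
is subtracted from the diagonal scaled by $\omega$, so $\omega = 0$ is
plain ILU(0) and $\omega = 1$ modified ILU). Convergence is monitored as
$\|r_k\|/\|r_0\|\le 10^{-8}$. Cathode nodes are constrained by symmetric
row/column elimination, preserving the symmetry CG relies on. On the
10,000-element phantom the preconditioner cuts iteration counts roughly
five-fold relative to plain CG, and on meshes small enough for dense
factorization the preconditioned solution matches a direct solve to
relative $10^{-6}$ or better.

Numerical safeguards worth knowing about:

* **Warm starts.** Each step starts CG from the previous solution; this
  halves iterations in quasi-static tDCS runs. An absolute residual floor
  ($100\,\varepsilon\,\|b\|$) recognizes the case where the warm start is
  already converged to machine precision — otherwise the relative monitor
  would demand the impossible. `solver_config(warm_start = FALSE)`
  restores the strict zero-start definition.
* **Pure-Neumann runs.** Without electrodes $\Phi$ is defined only up to a
  constant; the right-hand side is compatible, CG converges in the
  orthogonal complement, and the solver reports $\Phi$ in the zero-mean
  gauge. Scalp potential magnitudes in experiment summaries then use the
  scalp average-reference (the EEG convention) — the measurable quantity —
  rather than the arbitrary gauge value.
* **ILU breakdown.** A (near-)zero pivot in a block's incomplete
  factorization triggers a documented fallback to Jacobi for that block
  with a warning; this does not occur on the shipped experiments.

## The phantom

`build_annulus_phantom()` builds the two-dimensional five-tissue head
phantom: a white-matter disc of radius 40 mm; grey matter, CSF, skull and
scalp annuli with outer radii 50, 70, 90, 100 mm; and a horizontal CSF
strip of width 10 mm cutting through the brain, emulating how CSF
interleaves the cortex. Extracellular conductivities (S/m): skin 0.465,
skull 0.010, CSF 1.654, GM 0.276, WM 0.126; intracellular 0.1 on GM/WM.
Mesh generation is a deterministic structured polar triangulation: node
rings are placed on every tissue interface radius (so annulus boundaries
are exact), ring angles are snapped to the strip-edge crossings (so the
channel boundary is crisp), and bands between rings are triangulated by a
two-pointer angular merge. Element counts land within a few percent of the
request; tissue tags are assigned by element centroid, which keeps the
partition unambiguous on a conforming mesh.

Two consequences of the geometry matter for interpretation. First, the
strip *disconnects* the brain into an upper and a lower lobe, so membrane
waves cannot cross the channel — an action potential started below the
strip stays below it. Second, the strip is confined to the brain region
(`strip_extent` defaults to the GM radius, configurable), reading the
channel as a passage "through the GM and WM" rather than through all
tissues.

Coordinates are stored in meters and all physics is SI. Two-dimensional
runs are per-unit-depth slabs: "1 mA" anode current means 1 mA per meter
of depth, spread uniformly over the 10 mm electrode arc.

## The packaged experiments

```{r, eval = FALSE}
ap   <- run_experiment(experiment_ap_conduction())  # ~10 s at 10,000 elements
tdcs <- run_experiment(experiment_tdcs(1))
```

**Action potential conduction.** A stimulus current is applied inside a
2.5 mm disc at (0, −25) mm for the first 10 ms of a 100 ms run with a
fully insulated scalp; probes record $v$ on the vertical axis and $\Phi$
at the domain center and the four axis crossings of the scalp. Conduction
velocity is the probe separation divided by the difference of first
upward threshold crossings, linearly interpolated between the 1 ms
samples.

Three defaults here are deliberate choices, not published constants:

* *Stimulus amplitude* (200 V/s): the smallest round value for which the
  ignited wave traverses both velocity probes at the reference resolution.
  Weaker round values (≤ 100 V/s) ignite but die out earlier; much
  stronger ones (≥ 500 V/s) overshoot the 0.5 ms Heun substep's stability
  and are unusable.
* *Probe pair* (0, −20) and (0, −15) mm: on the propagation path, inside
  white matter, below the channel, and within the distance the wave
  demonstrably covers (see below).
* *Initial conditions*: $v = v_{rest}$, $w = 0$, $\Phi = 0$ — the resting
  state is an exact fixed point of both substeps, which the suite checks
  to 1 µV over 100 source-free steps.

**What the conduction experiment shows — honestly.** At the reference
discretization (10,000 triangles, $\Delta t = 1$ ms) with the stated
parameters, the simulated wave is *decremental*: it propagates roughly
12 mm from the stimulus and extinguishes. The measured velocity over the
first 5 mm of free propagation is ≈ 0.7 m/s (≈ 1.3 m/s at the coarser
2,500-element test resolution, where larger elements inflate the apparent
speed). A back-of-envelope continuum estimate agrees with the order of
magnitude: the bistable front speed is
$c \approx \sqrt{2 D c_1}\,(1/2 - a)$ with
$D = \sigma_i\sigma_e/(\sigma_i{+}\sigma_e)/(\chi C_m) \approx
4.4\times10^{-3}$ m²/s, giving ≈ 0.6 m/s. Velocities near 2 m/s would
require an order of magnitude more effective conductivity (or an order of
magnitude smaller $\chi C_m$) than the parameter table provides. The
package reports what the model actually produces under its stated
parameters.

**tDCS stimulation.** Two electrode configurations (anode/cathode at
(−100, 0)/(70.7, 70.7) mm and at (−70.7, 70.7)/(0, −100) mm), 10 mm
electrodes, 1 mA, no membrane stimulus, 100 ms. Each run is paired with a
Laplace volume-conductor solution under identical electrodes, and the
summary reports the relative $L_2$ difference of the potentials (domain
and scalp), the quasi-static drift
$\max_t \max_x |\Phi(x,t) - \Phi(x, 1\,\mathrm{ms})| / \max |\Phi|$,
and the scalp potential extrema. On the phantom the multiscale potential
agrees with Laplace to ≈ 0.2% and the drift is ≈ 0.1%: after the first
millisecond the stimulation field is stationary for all practical
purposes, which is why the quasi-static Laplace treatment of tDCS is
sound. The acceptance thresholds (5% agreement, 1% drift) operationalize
the qualitative statement that the two fields are visually
indistinguishable; the observed margins are more than an order of
magnitude inside them.

The current-density field shows the expected physics: shunting along the
scalp around the resistive skull, concentration at electrode edges, and
preferential flow through the high-conductivity CSF — including the
channel through the brain.

**AP sensitivity.** For quantifying stimulation-induced depolarization the
package implements the sensitivity statistic
$(v_{rest} - v)/(v_{rest} - v_{th}) \times 100\%$ — 0% at rest, 100% at
threshold, affine in $v$:

```{r}
ap_sensitivity(c(-0.070, -0.06285, -0.0557), fhn_params())
```

Per-element conductivity tensors are accepted verbatim by
`build_conductivity()`, so a user with a tagged 3D-derived mesh and an
anisotropic tensor field could assemble the same system; the packaged
experiments themselves are strictly the 2D phantom.

## What the synthetic phantom does and does not emulate

The phantom captures nested tissues with realistic conductivity
contrasts, a CSF pathway through the brain, scalp electrodes with the
three tDCS boundary conditions, and brain tissue that fires and conducts
action potentials. It does not capture cortical folding, anisotropic
white-matter conduction tensors, electrode-skin contact impedance, or 3D
current spreading — in 2D all current stays in the plane, which inflates
potential magnitudes relative to a 3D head. Passing tests on the phantom
therefore validate the numerics and the coupling structure, not
subject-specific field predictions.

## Problem sizes and tolerances

Reference runs use 10,000 triangles ($h \approx 2.7$ mm), the unit-test
suite 2,500 with identical acceptance bands. CG tolerance $10^{-8}$,
$\omega = 0.5$, $\Delta t = 1$ ms, $\Delta t_{ODE} = 0.5$ ms throughout.
Dense-oracle comparisons use a coarsened five-tissue phantom under 500
elements, where the full block matrix is comfortably factorizable. Every
pipeline stage is deterministic: identical configurations produce
bit-identical probe traces, which the suite asserts.

## Known limitations

* The decremental-wave regime at the reference resolution means
  conduction-velocity figures are measurement-window dependent; finer
  meshes (below ≈ 2 mm) sustain a stable ≈ 0.5 m/s wave with the same
  parameters.
* The linear recovery coupling is provided for completeness but cannot
  sustain tissue-level propagation with the default constants.
* Electrode size is interpreted as arc length on the scalp circle (at
  100 mm radius the chord/arc distinction is negligible for 10 mm
  electrodes).
* The Gmsh reader supports the 2.2 ASCII dialect with triangle elements
  and physical-group tissue tags; the VTK writer emits legacy ASCII
  unstructured grids (per-element fields as cell data, deliberately not
  averaged to nodes, so interface discontinuities in $E$ and $J$ survive
  export).
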
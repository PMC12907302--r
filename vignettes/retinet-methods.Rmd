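---
title: "Simulating layered retinal and early-visual circuits with retinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating layered retinal and early-visual circuits with retinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinet)
```

## The model

retinet simulates networks of "Cells" — a deliberately general unit that can
stand for a single neuron, a neuron population, a cortical column, or a
prosthesis electrode. A Cell of type $T$ is a small ODE system

$$\frac{d\vec X}{dt} = \vec F_T(\vec X, \vec\mu, \vec I(t)),$$

where $\vec X$ are the state variables (membrane voltage, gating variables,
transmitter concentrations, adaptation activities), $\vec\mu$ the parameters
shared by every cell of a layer, and $\vec I(t)$ the inputs. Inputs arrive
through four slots: an *external* drive (the visual front-end or an
electrode current), a summed *synaptic current* (pA), a summed *synaptic
voltage rate* (mV/s — the post-synaptic-potential convention in which a
"voltage" input already carries units of mV/s), and a summed *firing rate*
(Hz) used by rate-coupled populations. Cells live on 2-D lattices (layers);
layers stack in depth, and distances between cells are always measured in
the common (x, y) plane — the vertical layer separation never enters the
connectivity geometry.

All computation uses one default unit system: seconds, millivolts,
picoamperes, nanosiemens, nanofarads, hertz, millimeters (or degrees or
pixels for spatial modalities), nanomolar. `convert_units()` converts the
listed alternative units exactly; units are otherwise metadata only — the
package deliberately performs no dimensional coherence checking, leaving
unit discipline to the model author. The per-area unit variants
(µA/cm², mS/cm², µF/cm²) are rejected rather than converted, because a
per-cell equivalent needs a membrane area that no model here defines.

## Declarative models and the expression compiler

Cell and synapse types are data, not code: one JSON file per type carries
the state variables, parameters with defaults, input slots, auxiliary
functions and right-hand-side equations as plain text
(`"-(V - E_L)/tau + V_syn"`). `compile_expression()` parses a plain-ASCII
infix dialect (a small LaTeX subset — `\frac`, function macros,
Greek-letter macros — is normalized first) against an explicit symbol
table; unknown symbols, unknown functions and syntax errors fail at load
time with typed conditions. The callable function set is fixed
(`exp, log, erf, tanh, sqrt, min, max, pow, heaviside, ifelse`, plus the
trigonometric/hyperbolic helpers the spiking models need); `min`/`max` are
elementwise because layers evaluate as vectors. Two numerical policies are
worth stating explicitly:

* **Division by zero and `log` of a non-positive argument raise
  immediately** (`retinet_eval_error`) instead of propagating `NaN`;
  a silent `NaN` in a long simulation is far harder to diagnose than an
  early stop.
* **`heaviside(0) = 0`**, matching the strict inequality of the
  piecewise-linear rectifier $N_\theta(V) = V - \theta$ for $V > \theta$,
  else $0$, used throughout the gain-control and rectified-synapse models.

Every shipped model also exists as a hand-coded R function
(`linear_cell_rhs()`, `morris_lecar_rhs()`, ...). The two are not
redundant: the hand-coded versions are the oracles the test suite compares
the compiled definitions against (relative agreement to $10^{-12}$ at 100
random state/parameter points per type), and the engine can be forced onto
either path (`use_reference`). Definitions can be protected; the two
cortical population types ship protected and can be neither overwritten nor
deleted.

## Cells

The shipped models cover the standard retinal repertoire. Linear bipolar
and amacrine cells are leaky integrators; a "pharma" variant adds a tunable
ionic conductance $g_P, E_P$ representing e.g. a drug-sensitive channel.
The transmitter-producing amacrine couples a sigmoidal quasi-static
production of GABA/AMPA-gating transmitter $T$ to a channel activation $n$.
Gain-control bipolar and ganglion cells implement subtractive-adaptation
dynamics: an activity variable integrates the rectified voltage, and the
cell's output is divisively normalized, $N_\theta(V)/(1 + A)$. For the
ganglion cell, the term printed in compact form as a tunable threshold
conductance is read as $(g_T/C)\,N_0(V - V_T)$, consistent with the
capacitance-divided voltage form of the generic membrane equation, and the
firing-rate output uses the divisive form $\text{rate\_gain}\cdot
N_{\theta_G}(V)/(1+A_G)$ — the literature holds several variants, so the
transfer is parameterized rather than hard-coded. Spiking models are
Morris–Lecar (canonical Hopf-regime parameters rescaled to per-cell units:
C = 0.02 nF, conductances in nS, rates in 1/s) and classical
Hodgkin–Huxley (1952 squid parameterization at 6.3 °C, rates ×1000 for the
seconds time base; no temperature scaling). The starburst-amacrine model
extends Morris–Lecar with acetylcholine production
($dA/dt = -A/\tau_{Ach} + \mu_A T_A(V)$, $T_A$ sigmoidal, so $A \ge 0$ is
preserved from non-negative starts) and a slow after-hyperpolarization
potassium current $-g_{sAHP} S^4 (V - E_K)$ gated by a slow cascade
$R \to S$. The exact published SAC and cortical mean-field equations are
long and live in their own papers; the versions here are documented
stand-ins with the stated state variables and fully exposed parameters, and
the scenario-level guarantees for them are property-based (boundedness,
non-negativity, coupling behavior), not value reproduction. The cortical
column is likewise a deliberate rate stand-in: leaky integration of rate
input with a monotone, non-negative erf transfer.

## Synapses, summation and delays

Each synapse type produces a current, a voltage rate, or a firing rate, and
feeds the matching input slot of the post-synaptic cell — wiring a synapse
onto a cell type lacking that slot is a validation error caught before
integration. The shipped rules follow the standard forms: a saturating
cholinergic conductance $-g_A A^2/(\gamma_A + A^2)(V_{post} - V_A)$;
rectified and linear voltage-rate synapses; a pooling synapse that reads
the pre-synaptic cell's `bipolarResponse` output (the divisively
normalized rectified voltage for gain-control bipolars, the raw voltage for
plain cells); antisymmetric gap junctions $-w_{gap}(V_{post} - V_{pre})$;
rate-to-rate cortical coupling; ligand-gated GABA$_A$/AMPA synapses; and
the retino-cortical rate synapse scaled by the retinal/cortical density
ratio (defaults 400 and 4000 mm⁻²). For the ligand-gated rule the printed
driving force uses the pre-synaptic voltage; a post-synaptic driving force
is the physiologically standard convention, so the default here is
$V_{post}$ with a `literal` parameter restoring the printed pre-synaptic
form. Total input per slot is the plain sum over incoming edges;
`total_input()` implements the naive per-edge loop and serves as the oracle
for the engine's grouped, vectorized path.

Edge weights have two factors by design: connectivity generators produce
*geometric* weights (Gaussian profile values or constants, including sign
— inhibitory projections carry negative geometric weight), while synapse
parameters hold the per-type gain; the effective coupling is their product.

Synapses are instantaneous unless their type has a parameter named exactly
`conduction_velocity` (mm/s). The continuous delay is distance over
velocity, using the planar Euclidean distance; the engine discretizes it to
the nearest integer number of steps (minimum 0) and serves delayed
pre-synaptic outputs from per-(layer, output) ring buffers pre-filled with
the t = 0 values. Zero-step edges read the solver's stage states, so an
infinite conduction velocity reproduces the instantaneous simulation
bit-for-bit; strictly delayed edges read step-start samples, frozen within
a step.

## Connectivity generators

Six kinds: one-to-one (zero-distance partner; requires equal grid counts),
nearest neighbors (every cell at the minimal strictly-positive distance — 4
in a lattice interior, 2–3 at boundaries, all tied cells on ties, no
periodic wrap), neighbor 4+1 (nearest plus the zero-distance cell), radius
(closed ball, distance-0 excluded), Gaussian
($W = e^{-d^2/2\sigma_p^2}/2\pi\sigma_p^2$, distance 0 *included*, which
intra-layer means a self-edge), and fully connected. Gaussian connectivity
is truncated at $d > 4\sigma_p$ (configurable), where weights fall below
$e^{-8}/2\pi\sigma_p^2$; the truncation is a performance choice and the
tests verify the summed weight from a cell still approaches
$1/\text{spacing}^2$ on a wide lattice. Cells are indexed row-major from
the origin corner — 0-based in the on-disk JSON, 1-based inside R.

## The visual front-end

Stimuli are grayscale frame stacks with levels in [1, 255] (no color).
The receptive field is a circularly symmetric difference of Gaussians,
$w_c G_{\sigma_c} - w_s G_{\sigma_s}$ with normalized Gaussians, so a
uniform frame of level $I$ responds $(w_c - w_s) I$ exactly. Spatial
filtering uses Deriche's 4th-order recursive approximation (a causal +
anticausal IIR pair per axis, separable, replicate boundaries, recursions
initialized at steady state so the DC gain is exactly 1); its impulse
response matches the Gaussian to about $10^{-4}$ of the peak, and the
brute-force oracle is a 6σ-truncated FIR kernel. No temporal kernel shape
is prescribed by the abstraction this front-end implements, so the temporal
filter is an exponential cascade of order `n_rf` (default 1) with
`tau_rf = 20 ms`, discretized exactly for zero-order-hold input on the
engine's dt grid; the full multi-stage OPL of dedicated retina simulators
(luminance adaptation, contrast gain control) is intentionally out of
scope. Gray levels are used as-is; an explicit scenario gain maps the
filtered response into mV/s or pA, because the physical gray-to-drive
mapping is a modeling choice, not a constant of nature. The prosthesis
worker instead partitions each frame into one tile per electrode (image
size divided by electrode counts; every pixel in exactly one tile) and
delivers tile means times a gain as electrode current.

Movie input is numbered PNG/TIFF frame stacks with a JSON manifest
(`save_stimulus()`/`load_stimulus()`); the synthetic generators (moving
bar, full-field, drifting grating) produce the same structure
deterministically.

## Integration

The engine assembles one flat state vector (layers concatenated,
variable-major within a layer) and advances it with explicit fixed-step
solvers: Euler, midpoint RK2, classical RK4 (the default), and an embedded
Cash–Karp RK45 that adapts substeps inside each fixed dt interval — delays
and recordings need the fixed grid. Implicit and multistep methods are not
implemented; every shipped scenario is non-stiff at its documented dt.
Empirical convergence orders on the linear cell are verified at ~1/2/4
(±0.3), and RK4 at dt = 10⁻⁴ s tracks the closed-form trajectory within
10⁻⁶ mV over one second. Stimulus frames are zero-order-held between frame
times. A non-finite state aborts with a structured error naming the layer,
cell and variable. There is no stochastic term anywhere in the engine;
randomness enters only through explicitly seeded initial-condition jitter
in scenario builders, so runs are bit-reproducible given (session, seed).

## Scenarios and problem sizes

Three builders ship, with lattice sizes chosen for desk-scale runtimes
(the source system does not fix sizes, durations or parameter values for
its examples, so all defaults here are this package's own):

* **Retinal waves** — 10×10 starburst amacrine cells, cholinergic
  nearest-neighbor coupling, no input, 5 s at dt = 0.5 ms. Initial
  voltages are jittered (seeded) to break lattice symmetry, standing in
  for the noise-driven nucleation of the biological system.
* **Retino-cortical** — 8×8 grids: gain-control bipolars (OPL-driven by a
  moving white bar), linear amacrines (bipolars excite them, they inhibit
  bipolars and ganglions), gain-control ganglions, and an
  excitatory/inhibitory cortical pair fed by retino-cortical rate synapses
  with delayed Gaussian lateral spread; no thalamus stage. 1.2 s at
  dt = 1 ms. The lateral rate coupling is scaled by spacing² so the summed
  Gaussian gain is order one.
* **Amari–Wilson–Cowan** — 16×16 units
  $dV_i/dt = -V_i/\tau + \sum_j J_{ij} f(V_j) + H_{ext}$ with
  $f(x) = \tfrac12(1 + \mathrm{erf}(gx/\sqrt2))$ and Gaussian $J_{ij}$.
  With $g = 0$ the coupling freezes at $J/2$ and the network relaxes
  linearly to $V^* = \tau(J\mathbf{1}/2 + H_{ext})$, checked against the
  direct solve to 10⁻⁸.

## What the synthetic fixtures do and do not show

The synthetic stimuli and lattice scenarios exercise every code path —
filtering, wiring, delays, integration, recording — under known analytic
limits, which is what the tests certify. They do not emulate biological
variability: no photoreceptor noise, no cell-to-cell parameter
heterogeneity beyond seeded initial conditions, no stochastic release.
Passing tests therefore demonstrate numerical and structural correctness
of the machinery, not quantitative agreement with recordings; the SAC,
cortical and gain-control parameter defaults are plausible
order-of-magnitude choices, and any quantitative study should re-fit them.

## Known limitations

Single-compartment cells only; circularly symmetric receptive fields only
(no direction/orientation-selective kernels); no video-container input
(frame stacks only); no stiff solvers; no stochastic integrators; unit
coherence is the model author's responsibility.
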
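---
title: "Synchrony, free energy and the self-organization of cortical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrony, free energy and the self-organization of cortical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortigen)
```

cortigen is a workbench for a theory of cortical self-organization in
which zero-lag synchronous oscillation is the equilibrium state of
signal exchange between neurons, and in which the approach to that
equilibrium — equivalently, the minimization of a variational free
energy of synaptic flux — shapes cortical anatomy: columnar cell
layouts, mirror-symmetric connection patterns, and orientation-preference
maps. This vignette describes the model as implemented, the statistics
the package computes, the choices made where the theory leaves the
implementation open, and the limits of what the simulations show.

## The neural field

The simulated substrate is a set of $n$ neurons at fixed 2-D positions.
Each directed connection $j \to i$ carries a presynaptic flux

$$\varphi_{ij}(t) = \pm\, \varepsilon_{ij}\, g_{ij}\, \rho_{ij}\,
  Q_j(t - d_{ij}),$$

the product of three non-negative gains on increasingly slow
timescales — the transient efficacy $\varepsilon$, the dynamic gain
$g$, and the structural gain $\rho$ — applied to the presynaptic pulse
rate after the conduction delay $d_{ij} = \mathrm{round}(|x_i - x_j| /
v)$ time steps. The sign is fixed by the presynaptic cell's type
(excitatory or inhibitory). The product composition means any zero
gain silences the synapse. Dendritic summation convolves the
aggregate afferent flux (plus external drive) with a normalized
exponential kernel of time constant $\tau$ (truncated at $5\tau$), and
the pulse rate is a logistic sigmoid of the dendritic potential,
parameterized by its midpoint `theta`, midpoint derivative `slope` and
ceiling `qmax`, so the linearized model has tangent gain exactly
`slope`.

Two discrete-time conventions matter. Delays are rounded to whole
steps but the recurrence uses a minimum lag of one step (an
instantaneous algebraic loop has no well-defined update order), and
the first `max(lag) + kernel support` steps are zero-padded warm-up,
flagged in every record as `burn_in` and excluded by all metrics.

Couplings are bidirectional: the connection mask and the initial gain
magnitudes are symmetric. This is not incidental — reciprocal
exchange is what makes cross-correlations even functions of lag, and
therefore what makes *zero-lag* synchrony, rather than traveling
phase-lagged activity, the available equilibrium. Excitatory axons
are local (connection probability `density * exp(-d / sigma)`), while
inhibitory interneurons project densely across the whole patch: shared
inhibition paces a common rhythm instead of fragmenting the field into
independent local oscillators. Each neuron's inhibitory afferent
block is rescaled at construction so that summed excitatory and
inhibitory gains balance exactly — the flux-balance steady state is a
standing constraint, not something plasticity must first discover.

## Plasticity on three timescales

Plasticity is applied every `period` steps (default 50) from windowed
statistics accumulated during the run:

* $\varepsilon$ relaxes (time constant `T_eps` = 10 steps) toward its
  baseline scaled by the window's raw pre/post coincidence — fast
  facilitation that tracks activity but stores nothing permanent.
* $g$ potentiates in proportion to $\varepsilon$ times the
  *coincidence beyond chance* — the window covariance of the delayed
  presynaptic rate with the postsynaptic rate — gated by a sliding
  postsynaptic threshold (the window-mean rate must exceed a slow
  average of its own square, time constant `T_theta`). Potentiation is
  competitive twice over: synapses only strengthen where their
  covariance exceeds the neuron's mean over its afferents, and each
  neuron's total $g$ is capped at `headroom` times its initial row sum
  by multiplicative rescaling. Raw coincidence (rather than
  covariance) turns out to be nearly uniform across synapses when
  rates sit mid-range, and drives no selective reinforcement at all;
  the covariance form is what makes correlated pairs strengthen their
  coupling and is the engine of everything downstream.
* $\rho$ is a slow exponential average (time constant `T_rho` = $10^4$
  steps) of $g$'s *pattern*, normalized to unit mean over existing
  synapses. Structural consolidation therefore locks in relative
  connectivity without rescaling total coupling; a silent window
  leaves it untouched. (An early variant that tracked $g$'s raw
  magnitude collapsed the total coupling by an order of magnitude over
  a run, because $\rho$ starts at 1 while $g$ is small — a useful
  cautionary tale about composing multiplicative gains.)

Anti-Hebbian normalization enforces the excitatory/inhibitory balance:
per neuron, the excitatory and inhibitory blocks of $g$ are each
multiplied by one scalar so both window fluxes equal a target,
leaving within-block ratios untouched to machine precision. The
default target is *adaptive* — the per-neuron geometric mean of the
two blocks' window fluxes — which balances excitation against
inhibition at the neuron's current activation level while preserving
the overall magnitude. This choice matters: pinning the target to the
initial flux level freezes the field's total coupling at birth and no
development occurs, whereas the adaptive target lets slow Hebbian
growth carry an initially subcritical field up to its competitive
ceiling. A fixed numeric target and a population-wide mode are also
available.

## The developmental study conditions

The emergence experiments use the package defaults throughout: 64
neurons on an $8\times 8$ unit grid, $v = 3$ (delays of 1–4 steps;
conduction within a compact patch is fast relative to the dendritic
timescale), 75% excitatory cells with inhibitory cells interleaved,
`g0 = 0.03` (subcritical at birth), `headroom = 2` (the competitive
ceiling sits near the critical coupling, so maturation approaches
criticality and stalls there rather than overshooting into saturated,
fragmented oscillation), `eta_g = 40`, and i.i.d. Gaussian white-noise
drive of standard deviation 0.2 flux units at every neuron, for
$2 \times 10^4$ steps. Under these conditions the field passes, over
one run, from noise-dominated independence to a spatially coherent
near-critical collective mode; the rho-frozen control (structural
consolidation disabled) shows neither the rise in synchrony nor the
free-energy descent, identifying slow structural consolidation as the
mechanism.

```{r emergence, eval = FALSE}
field <- build_field(list(n = 64, seed = child_seed(1, 1)))
drive <- white_noise_drive(64, 2e4, 0.2, child_seed(1, 2))
rec <- simulate_field(field, 2e4, drive = drive)
```

## Synchrony and free-energy metrics

**Zero-lag synchrony.** `zero_lag_synchrony()` reports the fraction of
channel pairs whose cross-correlation over lags $\pm$`lag_max`
(default 10) peaks at lag zero, ties counted as zero. Unrelated
channels score near $1/(2\,\mathrm{lag\_max}+1)$.
`eigenmode_decomposition()` gives the principal spatial eigenmodes with
a per-component variant: the fraction of participating channels whose
cross-correlation with the component score peaks at lag zero, computed
*leave-one-out* (the channel's own contribution is removed from the
score, otherwise a set of unrelated channels scores 1 through
self-correlation).

**Spatial damping** of an eigenmode is measured as normalized spatial
roughness of the loading pattern: the rms loading difference per unit
distance over neighbouring cells, divided by the rms loading. A
log-loading-versus-distance regression was considered and rejected:
sign-split (dipolar) modes have near-uniform loading magnitude and
would read as undamped.

**Free energy.** `flux_free_energy()` computes, over every connected
pair and lags $0..L$ (default twice the maximum delay), the total flux
autocorrelation $A$, cross-correlation $C$, $F = A - C$, and the
equality residual $\sum |a_{ij} + a_{ji} - c_{ij} - c_{ji}|$, which
vanishes exactly when the exchanged fluxes are identical. Flux series
are rebuilt exactly from the pulse trajectory and the
piecewise-constant gain snapshots, linearly detrended within the
window (slow gain growth otherwise masquerades as correlation). By
default the totals are reported on the *fractional* scale, $A = 1$ and
$C = C_\mathrm{raw}/A_\mathrm{raw}$: raw covariance sums weight each
pair by the flux it actually carries, so consolidated couplings
dominate, and the ratio is invariant to overall gain scale and to
temporal-bandwidth changes (summing correlation *coefficients* over
lags, by contrast, grows with autocorrelation length and can mask a
genuine coherence gain). `free_energy_trajectory()` takes a windowed
$F$ series and classifies the terminal state: near-zero $F$ and slope
with positive curvature is the unstable fixed point expected under
residual broken symmetry; anything else is stable. "Near zero" means
below 5% of the initial $F$ — a scale-free criterion.

**Information.** `mutual_information()` is the Gaussian closed form
$-\tfrac12 \log_2(1 - r^2)$; `channel_capacity()` is
$D = n \log_2(1 + C/A)$ with the mirror-pair state counts $2^{n/2}$
and $2^{n_\mathrm{neo} - n_\mathrm{limb}}$, exact up to exponent 62 and
reported in log2 beyond. `capacity_from_record()` binarizes each
pair's flux at its median before accumulating $A$ and $C$.

## Morphogenesis

`force_equilibrium_layout()` relaxes soma positions of a long-axon
("patch") and short-axon ("local") population under three pairwise
forces: a synchrony attraction along the gradient of the pair's
synchrony *advantage* $e^{-d/\ell}/\ell - e^{-d/L}/L$ (where $\ell$ is
the pair's coupling range and $L$ the patch scale), a gentle constant
wiring-length contraction along connected pairs, and soma repulsion
with packing radius proportional to arbor size. The differential form
of the attraction is the load-bearing choice: aggregation is driven
only by synchrony obtainable *beyond* what the long-range patch
background already provides, so it vanishes identically when all axon
scales are equal (the diffuse small-world outcome), sharpens with the
patch/local contrast (columnarity rises monotonically along an
axon-ratio sweep), and contributes no patch–patch clumping (patch
cells spread into pools around the local clusters). Relaxation stops
when the maximum displacement falls below `tol` (default $10^{-3}$
domain units) or at `max_iter`; non-convergence returns the best
layout flagged `converged = FALSE`.

Columnarity is a nearest-neighbour clustering statistic against
complete spatial randomness: $1 - \bar d_\mathrm{NN} / E_\mathrm{CSR}$,
clipped to $[0, 1]$, with $E_\mathrm{CSR}$ from 99 Monte-Carlo draws
inside the points' convex hull (rotation- and translation-invariant).
Tiling of the cluster-center lattice is classified by the 4-fold
versus 6-fold circular concentration of nearest-neighbour bond angles.
`apoptotic_selection()` culls the cells with the lowest mean zero-lag
correlation to the population. `reconstruct_symmetric_connections()`
connects pairs that are both correlated above threshold and within
axonal reach, with patch-to-local edges confined to arcs radiating
from column centers.

`mirror_symmetry_score()` reflects one side of a candidate axis onto
the other, registers by two-way nearest-neighbour matching, and scores
$1 - d_\mathrm{obs}/d_\mathrm{null}$ against a uniform-resampling
null; an exact reflection scores 1. `neighbor_mirror_census()`
averages this over adjacent cluster pairs. The square-versus-hexagonal
contrast is constructive: mirror-paired neighbours need opposite
handedness, square adjacency is bipartite and admits a perfect
alternation, while the triangular lattice's odd cycles frustrate it —
so square-tiled arrays of chiral motifs score higher than hexagonal
ones of equal cell count.

## The global-to-local projection and orientation maps

A column's `local_map` projects a global displacement by scaling its
modulus by $1/k$, doubling its argument, and rotating by 90 degrees
(the imaginary-unit factor). Positive chirality is this conformal
map; negative chirality is its complex conjugate — the anti-conformal,
opposite-handed branch. The conjugate reading was adopted after
checking the alternatives: a bare sign flip only rotates the local
image and leaves every pinwheel with the same winding, whereas
handedness must flip the winding. One subtlety is worth recording:
for an orientation (director) field, "reflect positions and negate
orientations" provably *preserves* pinwheel winding — both winding
signs are individually invariant under that operation — so a mirror
pair of maps in the positional sense is the only sense in which
chirality flip can both mirror the raster and reverse the winding.
That is exactly what the conjugate map does: orientation values at
mirrored positions coincide, and the winding flips.

The inverse map halves angles on one of two branches 180 degrees
apart; round trips are identity to $10^{-12}$ relative tolerance.
Orientation preference at a local point is the direction of its global
preimage modulo 180 degrees, so one physical circuit of a column
center sweeps exactly one orientation period — the Möbius half-twist —
and every map contributes exactly one pinwheel of winding
$\pm\tfrac12$ matching its chirality.

`synthesize_op_map()` rasterizes an atlas on a pixel-center grid
(centers then sit inside plaquettes, where winding is well defined)
with either hard nearest-center assignment (exact per-map fields,
orientation seams at boundaries) or soft blending — distance-weighted
vector averaging in doubled-angle space — which yields a smooth field
in which boundary features exist. Feature classification finds
pinwheels by plaquette winding (computed only on single-map
plaquettes under hard assignment, since winding needs continuity),
linear zones as connected low-gradient regions (default: below the
10th gradient percentile), and saddles as strict local minima of the
gradient magnitude with an indefinite locally-unwrapped Hessian —
under soft blending, a $2\times 2$ alternating-chirality array has one
at the array center, where the mirror seams cross. Plain threshold
classification was not enough for saddles: the half-angle field's
Hessian is indefinite *everywhere*, so without the strict-minimum
condition every quiet corner of the raster classifies as a saddle.

`project_image()` disperses a global activity pattern across all
covering maps, shifting each sample's time by the metric conduction
delay $|P - p|/v$; sample counts are conserved per map.
`build_representation_frame()` packs a rigid moving image into the
fixed twelve-coordinate frame — three object scale/rotation
coordinates (log scale and two rotation angles), three position
coordinates, and the translation components within both frames — in
the documented order `(log_scale, rot1, rot2, pos_x, pos_y, pos_z,
d_log_scale, d_rot1, d_rot2, vel_x, vel_y, vel_z)`; a static image has
all six translation components exactly zero, and the packing is
invertible.

## What the synthetic experiments do and do not show

The generator produces i.i.d. Gaussian drive, grid geometries, and
surrogate distance-decay correlations. What passes under these
conditions shows that the implemented mechanisms behave as the theory
claims *in their intended regime*; it does not show that real cortex
operates there. Specific known limitations:

* **Depth of synchrony.** The mature field approaches, but does not
  reach, the flux-equality limit: with independent noise at every
  neuron, pairwise flux coherence saturates around $C/A \approx
  0.3$–$0.5$, and mixed excitatory/inhibitory pairs retain a loop-lag
  phase offset. The windowed free energy descends robustly, but its
  terminal equality residual remains a substantial fraction of the
  initial one. Reaching near-total equality would require spatially
  correlated input or noiseless exchange.
* **Prediction-error neutralization.** The paired driven/baseline
  operationalization of input neutralization behaves as specified in
  its exact limits (no drive, no recurrence), but the qualitative
  expectation that a trained field shows a *smaller* residual than a
  naive one does not reproduce here: once the mature field sustains
  collective oscillation, the driven-minus-baseline flux difference is
  dominated by trajectory divergence of the oscillation itself rather
  than by input compensation. Measuring input neutralization in a
  self-oscillating nonlinear field appears to need an ensemble or
  phase-aligned design, which is out of scope.
* **Force law.** The morphogenesis forces are an interpretation of a
  mechanical-equilibrium analogy; the internal force constants were
  chosen so the three qualitative regimes are expressed, and are not
  fitted to tissue data.
* **Problem sizes.** The standard experiments use 64-neuron fields,
  $2\times 10^4$ steps, five seeds, and 200-cell layouts — sizes at
  which every reported phenomenon is already stable across seeds.

## Reproducibility

Every stochastic operation takes an explicit seed; a single pipeline
seed is expanded into per-stage child streams with `child_seed()`
(a documented congruential step), so each stage can be re-run
independently and a full `simulate -> metrics -> morph -> opmap`
pipeline is byte-reproducible. Records persist losslessly with a
format version string; angles are degrees in all external files and
radians internally.
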
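---
title: "A dynamic Monte Carlo model of driven polymer translocation into a slab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic Monte Carlo model of driven polymer translocation into a slab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretrans)
```

## The physical problem

A charged semiflexible polymer is pulled by an electric field through a
narrow nanopore in a membrane, emerging not into open solution but into the
laterally unbounded gap of width $R$ between two parallel repulsive
membranes. This is a minimal setting for transport of stiff biopolymers
(dsDNA-like chains) into strongly anisotropic confinement: the freshly
translocated subchain cannot simply diffuse away along the pore axis — it
must bend and spread laterally, and the resulting resisting force feeds
back on the translocation dynamics. The quantities of interest are the
translocation time $\tau$, its distribution, the per-monomer waiting times
$W(s)$, and the scaling exponents of $\tau$ with chain length
($\tau \sim N^\alpha$), bending stiffness ($\tau \sim \kappa^\beta$),
field strength and slab width.

## The model

The chain is an off-lattice bead-spring polymer of $N+1$ monomers
(chain length $N$ bonds), with total energy

$$U = U_{\mathrm{FENE}} + U_M + U_b + U_W + U_e ,$$

all terms in units of $k_BT$ and all lengths in units of the maximum bond
extension $l_{\max}$:

* **FENE bonds.**
  $U_{\mathrm{FENE}}(l) = -\tfrac{1}{2}k r_0^2 \ln\!\big[1 - ((l -
  l_0)/r_0)^2\big]$ for $l_{\min} < l < l_{\max}$, with $k = 20$,
  $l_0 = 0.7$, $l_{\min} = 0.4$, $l_{\max} = 1$ and
  $r_0 = l_{\max} - l_0 = l_0 - l_{\min} = 0.3$. A trial move that takes a
  bond outside its bounds is rejected outright. The prefactor is the
  standard $k r_0^2/2$ form, so $U''(l_0) = k$.

* **Morse excluded volume** between all non-bonded pairs
  ($|i-j| > 1$):
  $U_M(r) = \varepsilon\,(e^{-2a(r - r_m)} - 2e^{-a(r - r_m)})$ with
  $a = 24$, $r_m = 0.8$, $\varepsilon = 1$, truncated at $r_c = 1.5$,
  where $|U_M| < 10^{-7}$. The steep exponent makes monomers effectively
  soft spheres of diameter $\approx 0.8$ with a shallow adhesive well of
  depth $1\,k_BT$; combined with the finite bond extensibility this
  prevents chain crossing.

* **Bending.** $U_b = \kappa\,(1 + \cos\theta)$ per interior vertex, where
  $\theta$ is the interior angle between successive bonds. We adopt the
  convention in which collinear bonds have $\theta = \pi$, so a straight
  chain has zero bending energy and a full backfold costs $2\kappa$ — the
  only convention under which stiff chains are stretched, which is how the
  stiffness is meant to act.

* **Wall repulsion.** The membranes are purely repulsive:
  $U_W(r) = U_M(r) + \varepsilon$ for $r \le r_m$ and $0$ beyond, a
  truncated-shifted Morse that vanishes continuously at $r_m$.

* **Electric drive.** Each monomer carries unit charge; a uniform field
  $E$ acts along $-z$ only inside the pore, so $U_e = qEz$ across the pore
  column, $0$ on the cis side, and the constant $-qEL$ on the trans side.
  Crossing the pore lowers each monomer's energy by $qEL$.
  Monomer–monomer electrostatics and hydrodynamics are neglected.

## Geometry, and how smooth walls stand in for particle-built ones

The pore axis is the $z$ axis with the origin at the cis-side mouth. The
left membrane is the slab $-L \le z \le 0$ ($L = 2$) perforated by a
cylindrical pore of diameter $D = 1.2$; the trans slab
$-(L+R) \le z \le -L$ is laterally unbounded (no box, no periodic images);
the right membrane fills $z \le -(L+R)$.

Physically the membranes are walls built from immobile particles of
diameter $\sigma = r_m$, with $U_W$ acting on the centre-to-centre
distance. We model them as smooth analytic solids instead — deterministic,
corrugation-free, and independent of any arbitrary lattice choice — with
`wall_gap()` returning the true Euclidean distance from a monomer to the
nearest point of the material surface (distance to the rim circle near the
pore mouth, so the energy field is continuous there).

One consequence is easy to get wrong: the centres of the outermost wall
particles sit about $\sigma/2$ *behind* the material surface. The wall
energy therefore acts on `wall_gap + wall_offset` with
`wall_offset = r_m/2 = 0.4` by default. This matters inside the pore: the
surface distance from the axis is only $D/2 = 0.6 < r_m$, so a repulsion
acting on the raw surface distance would put $\sim 10^4\,k_BT$ on the pore
axis and no chain could ever pass. With the offset, the interaction
distance on the axis is $D/2 + \sigma/2 = 1 > r_m$: the axis is
force-free, the soft channel has an effective radius of $\sim 0.2$, and
the pore admits exactly one file of monomers — the intended geometry. The
offset is a configurable parameter for sensitivity checks.

## Dynamics and the translocation protocol

Sampling is single-monomer Metropolis dynamics: a monomer chosen uniformly
at random is displaced by increments drawn uniformly from
$(-0.25, 0.25)$ per coordinate, and the move is accepted with probability
$\min(1, e^{-\Delta U/k_BT})$. $N+1$ trial moves form one Monte Carlo step
(MCS), the unit of time. The energy difference of a move touches only the
terms involving the moved monomer (its bonds, up to three angles, its
pairs within the cutoff, wall and field terms); the compiled kernel
additionally caches per-monomer pair sums so the old-state pair energy is
O(1) per trial. Accumulated increments are verified against full
recomputation in the test suite.

A sample proceeds in three stages:

1. **Equilibration.** Monomer 0 is held at $(0, 0, z_{\mathrm{park}})$,
   by default half a bond *inside* the shut pore mouth
   ($z_{\mathrm{park}} = -0.35$), while the remaining monomers, confined
   to $z \ge 0$ by the closed entrance (treated as an unperforated wall),
   equilibrate from a straight initial chain. Parking the first monomer
   inside the mouth means the chain is already threaded when released;
   parking it outside would make pore entry a rare diffusive capture event
   and the protocol unusable. Equilibration ends when consecutive windows
   (default 500–1000 MCS) of the running total energy agree to 1%
   *and* a conformational floor of $50N^2$ MCS has passed. The floor is
   essential: the energy equilibrates within a few thousand MCS while the
   chain's global extension — which starts fully stretched — relaxes on
   the much slower Rouse-like time scale. The floor was sized so that the
   mean squared end-to-end distance of flexible chains is stationary in
   $N$-doubling checks.

2. **Translocation.** At $t = 0$ monomer 0 is released and the pore
   opens. If, after having engaged the pore, the chain retreats entirely
   to the cis side with the pore empty, the attempt is abandoned: the
   stored equilibrated conformation is restored, the clock resets, and the
   attempt counter increments (fresh randomness continues; the paper-style
   protocol restarts rather than re-equilibrates). The engagement
   qualifier is needed because the literal condition "all monomers on cis"
   already holds at release.

3. **Completion.** The run ends when the last monomer's $z$ drops below
   $-L$. The translocation time $\tau$ is the MCS count of the successful
   attempt. Waiting times $W(s)$ count the MCS during which monomer $s$
   is inside the pore cylinder, at one-MCS granularity, summed over
   re-entries within the successful attempt. A guard (`max_mcs`, default
   $10^8$ MCS, smaller in desk configurations) flags runaway samples as
   failed; failed samples are excluded from time statistics and counted
   separately.

Every entry point draws from R's RNG, so a record is a deterministic
function of `(params, seed)`; ensembles use seeds `base_seed + i` and are
embarrassingly parallel in principle (results are independent of
execution order).

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `n_bonds` | chain length $N$ | 150 | bonds |
| `kappa` | bending stiffness | 10 | $k_BT$ |
| `e_field` | field in the pore | 5 | force / charge |
| `r_sep` | membrane separation $R$ | 5 | $l_{\max}$ |
| `step_max` | trial-move half-width | 0.25 | $l_{\max}$ |
| `wall_offset` | wall-centre depth behind the surface | 0.4 | $l_{\max}$ |
| `relax_window`, `relax_tol` | equilibration windows | 1000, 1% | MCS, – |
| `n_samples` | ensemble size | 5000 | – |

The defaults are the reference parameterisation; `n_samples = 5000` is the
full campaign size and is far beyond a single desk CPU for long chains —
the analyses shipped with the package run reduced conditions (below).

## Observables and scaling analysis

`run_ensemble()` aggregates records into mean $\tau$, its standard error,
the mean waiting profile and acceptance statistics. `waiting_profile()`
returns $W(s)$ with standard errors; `peak_position()` locates the early
peak or cusp of $W(s)$ (a 3-point moving average followed by
first-local-maximum search in a window, defaulting to $s \in [2, 30]$;
when no strict maximum exists, a cusp is reported at an interior point
where the second-difference magnitude peaks clearly above its background,
and monotone profiles report "no peak"). That early feature marks the
moment the translocated subchain first touches the far membrane.
`tau_histogram()` bins times with Freedman–Diaconis breaks by default and
reports the sample skewness $g_1$, which separates the near-Gaussian
regime (slow, diffusion-dominated) from the right-tailed regime of stiff,
strongly driven chains. `xy_projection()` exports post-translocation
conformations for inspecting coil versus torus-like folded states.

`fit_power_law()` is ordinary least squares of $\log_{10} y$ on
$\log_{10} x$ — unweighted by default, matching the plain log–log linear
fit convention for these exponents, with an optional inverse-variance
weighted variant. `run_sweep()` drives one-parameter grids with
deterministic per-point seed blocks and fits over an explicit sub-range
(e.g. $R \in [2, 10]$, where confinement matters, with the plateau beyond
fitted separately).

## Numerical choices and degenerate inputs

* Morse cutoff 1.5 with no shift; the neglected tail is $<10^{-7}$ per
  pair and $<10^{-4}$ in total for any tested conformation.
* Infinite energies (bond bound violations, membrane interiors) are
  sentinels that force rejection; they never enter accumulated sums.
* The incremental energy ledger is rebuilt from scratch at every
  withdrawal restart, eliminating drift across attempts.
* Angle cosines are clamped to $[-1, 1]$ before `acos`; zero-length bonds
  cannot occur ($l > l_{\min}$).
* `peak_position` on a profile shorter than its search window is an
  error; a single-valued time sample yields a one-bin histogram with
  $g_1 = 0$.
* Equilibration failure to converge within `relax_max_mcs` is reported via
  the `converged` attribute rather than an error.

## What the simulations do and do not show

The desk-scale conditions used by the test suite and the acceptance
script are $N \in [15, 50]$, $\kappa \in [10, 70]$, $E \in [1.5, 10]$,
$R \in [2, 15]$ with 100–200 samples per point. At these sizes the model
reproduces the qualitative structure of the problem: confinement slows
translocation for $R \lesssim 10$ and saturates beyond; stronger fields
speed it up with a negative log–log slope; $\tau$ grows super-linearly in
$N$ with $\alpha$ between 1 and 2; stiffer chains are slower; stiff
strongly driven chains develop right-tailed time distributions. The
published full-scale exponents belong to $N = 150$, 5000-sample
cluster campaigns; desk-scale exponents are expected to differ
quantitatively (finite-size effects on $\alpha$ and $\beta$ are strong at
these chain lengths), so the package asserts ranges and monotonicities,
not the full-scale values. The machinery for full-scale runs is the same
code with larger parameters.

Two honest caveats. First, the average Metropolis acceptance rate at the
reference step size is near 23% for $\kappa = 10$ chains (46% fully
flexible; 71% for an isolated bond — the acceptance script reports the
measured value). The original description of this model quotes a
(60%, 70%) operating window without stating how it was achieved; that
window is not reachable with the stated potentials, step width and
textbook Metropolis acceptance, and we keep the stated step width rather
than tune toward a quoted diagnostic. Second, dynamic Monte Carlo time is
a model time: without hydrodynamics or momentum, MCS-based exponents need
not coincide with Langevin or experimental ones — which is equally true of
the method being reproduced.

## Known limitations

* Smooth walls suppress any corrugation a particle-built wall would have;
  fine structure of $W(s)$ attributable to wall texture is outside the
  model.
* No monomer–monomer electrostatics, no counterions, no hydrodynamic
  coupling, no membrane elasticity.
* The field acts on a monomer exactly when its $z$ lies in the pore
  column, regardless of radial position; with the single-file channel this
  is indistinguishable from any reasonable alternative rule.
* Withdrawal restarts reuse the stored equilibrated conformation rather
  than drawing a fresh one; attempts within a sample therefore share their
  initial condition (samples remain independent).
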
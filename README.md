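# poretrans

Dynamic Monte Carlo simulation of a charged semiflexible polymer driven by
an electric field through a nanopore into the laterally unbounded slab
between two parallel repulsive membranes.

## The problem and who this is for

Driven polymer translocation into *anisotropic* confinement is a minimal
model for moving stiff biopolymers (DNA-like chains) through a pore into a
thin gap: the freshly translocated subchain hits the far membrane, must
spread laterally, and the resulting resisting force reshapes the whole
dynamics. `poretrans` is for polymer/biophysics researchers who want a
reproducible, seed-deterministic implementation of this model: the
simulation engine, the observables, and the scaling analyses, with
everything scriptable from R or a thin CLI.

## The model in brief

An off-lattice bead-spring chain of N + 1 monomers with total energy

    U = U_FENE + U_M + U_b + U_W + U_e

- FENE bonds: U(l) = -(k r0²/2) ln[1 − ((l − l0)/r0)²], k = 20, l0 = 0.7,
  l ∈ (0.4, 1.0);
- Morse excluded volume for non-bonded pairs: ε(e^(−2a(r−r_m)) −
  2e^(−a(r−r_m))), a = 24, r_m = 0.8, ε = 1, cutoff 1.5;
- bending: κ(1 + cos θ) per interior angle, zero for straight chains;
- truncated-shifted Morse wall repulsion from two smooth membranes a
  distance R apart, the left one pierced by a pore of length L = 2 and
  diameter D = 1.2;
- a uniform field E along −z inside the pore acting on unit monomer
  charges (energy drop qEL per monomer crossing).

Dynamics is single-monomer Metropolis with displacements uniform in
(−0.25, 0.25) per coordinate; N + 1 trial moves are one Monte Carlo step
(MCS), the time unit. The protocol equilibrates the chain on the cis side
with the first monomer held in the shut pore mouth, releases it at t = 0,
restarts on withdrawal, and stops when the last monomer reaches the trans
side. Main observables: translocation time τ, its distribution, waiting
times W(s), post-translocation x–y projections, and log–log scaling fits
τ ~ N^α, τ ~ κ^β and the τ–R and τ–E slopes.

See the vignette (`vignettes/translocation-model.Rmd`) for the full model
account, parameter table, and design rationale.

## Worked example

A small ensemble at a desk-scale parameter point (N = 25, κ = 10, E = 5,
R = 5):

```r
library(poretrans)
p <- sim_params(n_bonds = 25, kappa = 10, e_field = 5, r_sep = 5,
                relax_window = 500, max_mcs = 1e6)
ens <- run_ensemble(p, n_samples = 20, base_seed = 1)
ens
#> Translocation ensemble: N = 25, kappa = 10, E = 5, R = 5
#>   20 samples (0 failed), base seed 1
#>   mean tau = 2.131e+04 +/- 649 MCS, mean acceptance 23.4%
summary(ens)
#> tau: mean 2.131e+04 (se 649), median 2.099e+04, IQR [1.999e+04, 2.223e+04] MCS
#> 20 samples, 0 failed; mean attempts 7.10; mean acceptance 23.4%
head(waiting_profile(ens), 4)
#>   s    mean       se
#> 1 0 1472.65 146.4261
#> 2 1 2208.45 176.4552
#> 3 2 2484.65 219.8586
#> 4 3 2637.75 181.6381
tau_histogram(ens)
#> Translocation-time histogram: 20 samples, 7 bins
#>   skewness g1 = 0.781 (se 0.512 under normality)
```

Reading this: the chain needed on average ~2.1e4 MCS to translocate, each
sample typically made a handful of abortive pore entries before the
successful attempt (`mean attempts`), and the early monomers each spend
1500–2600 MCS inside the pore (`waiting_profile`). `plot(ens)` draws the
W(s) curve; `run_sweep()` + `fit_power_law()` produce the scaling
exponents, e.g.

```r
sw <- run_sweep(sweep_spec("n_bonds", c(15, 25, 35, 50), params = p,
                           n_samples = 200, fit_range = c(15, 50)))
sw$fit    # exponent alpha of tau ~ N^alpha with its standard error
```

Results persist via `write_results()` (CSV tables + JSON manifest with all
seeds), snapshots via `write_xyz()`. A thin command-line front end with
`run`, `sweep`, `fit` and `analyze` subcommands lives at
`inst/cli/poretrans.R`.

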
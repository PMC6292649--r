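---
title: "Heteropolymer chromosome dynamics with chromodyn: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteropolymer chromosome dynamics with chromodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

## The scientific problem

Interphase chromosomes are extraordinarily long polymers packed into a
territory a few micrometres across. Hi-C maps show that this packing is not
an equilibrium melt: the contact probability decays as $P(s) \sim s^{-1}$
over megabase scales, the signature of a *crumpled* (space-filling) globule
whose mean spatial distance grows as $R(s) \sim s^{\nu}$ with $\nu = 1/3$,
rather than the ideal-chain $\nu = 1/2$. chromodyn implements a
coarse-grained model (one bead = one 50 kb locus, diameter $a$) to ask how
far that single structural exponent dictates the *dynamics* of chromatin
loci: the subdiffusion exponent of locus MSDs, spatially correlated motion,
scale-dependent relaxation times, and the response to active
(ATP-dependent) noise.

The closed-form backbone is small and exact:

* loci-averaged MSD $\sim t^{\beta}$ with $\beta = 2\nu/(2\nu+1)$
  (`beta_from_nu()`): 0.4 for $\nu = 1/3$, 0.5 for the ideal chain;
* domain relaxation time $\tau(s) \sim s^{2\nu+1}$
  (`tau_exponent_from_nu()`): $s^{5/3}$ for $\nu = 1/3$;
* Rouse-mode amplitudes $\langle X_p^2\rangle \sim p^{-(1+2\nu)}$;
* the long-time structural deviation
  $\delta_{\mathrm{eq}}^2 = \frac{2a^2}{N(N-1)}\sum_{s=1}^{N-1}(N-s)\,s^{2\nu}$
  (`delta_eq_analytic()`, exact summation; the continuum integral is only a
  cross-check). For $N = 2712$ and $\nu = 1/3$ this gives
  $\delta_{\mathrm{eq}} \approx 9.4\,a$.

## The energy model

`chrom_params()` collects all coefficients in reduced units ($a = 1$,
$k_BT = 1$). The potential has six classes (`energy_decomposed()` reports
them separately):

1. **Bonds** — harmonic, $E = \tfrac{k_b}{2}(r - r_0)^2$ with $r_0 = a$.
2. **Excluded volume** — purely repulsive one-sided harmonic,
   $E = \tfrac{k_{ev}}{2}(\sigma - r)^2$ for $r < \sigma = a$, non-bonded
   pairs only.
3. **Type-pair contacts** — $\sum_{i<j} E(T_i, T_j)\, f(r_{ij})$ over the
   six subcompartment types (B3, B2, B1, NA, A1, A2), with the smooth
   contact indicator $f(r) = \tfrac12\left[1 + \tanh\mu(r_c - r)\right]$,
   $\mu = 3/a$, $r_c = 1.5\,a$. The same $f$ defines contact maps,
   $c_{ij} = \langle f(r_{ij})\rangle$.
4. **Loop attractions** — $\epsilon_{\mathrm{loop}} \sum_{(i,j)} f(r_{ij})$
   over CTCF-like anchor pairs.
5. **Condensation** — a genomic-distance-dependent attraction
   $\gamma(d) f(r_{ij})$ for $2 \le d = |i-j| \le d_{\max} = 500$,
   defaulting to $\gamma(d) = -(0.35/d + 3.7/d^2)\,k_BT$.
6. **Confinement** — one-sided harmonic spherical wall at
   $R_s = \tfrac{a}{2}(N/\phi)^{1/3}$, volume fraction $\phi = 0.1$
   ($R_s \approx 15\,a$ at $N = 2712$).

The type matrix, loop strength and condensation table are deliberately
*generic*: attractive within-type entries (B–B strongest, A–B weakest,
magnitudes 0.1–0.5 $k_BT$) chosen once to reproduce the qualitative
phenomenology (checkerboard contact pattern, B-core/A-surface radial
organisation, chain condensation). Quantities compared against the
full-scale study are therefore *scaling-level* observables (exponents), not
absolute energies. All defaults are overridable and serialisable
(`write_params()`/`read_params()`).

### Numerical stiffness choices

Bond and excluded-volume stiffnesses default to $k_b = 200$ and
$k_{ev} = 300\,k_BT/a^2$. These values are set by a chain-integrity budget
rather than by aesthetics: over $\sim 10^5{-}10^6$ sampled bond lengths the
expected *maximum* excursion is $\sim \sigma_b\sqrt{2\ln n}$, and with the
Euler–Maruyama variance inflation factor $1/(1 - k_{\mathrm{eff}}\,dt)$ a
softer chain ($k_b = 100$) would stretch past $1.5\,a$ at realistic sample
counts, defeating the non-crossing guarantee. With the defaults and
$dt = 10^{-3}\,\tau_{BD}$, trajectories keep all bonds below $1.5\,a$ and
all non-bonded pairs above $0.6\,a$ with margin (asserted by tests).

## Dynamics

Two integrators share the same force kernel (compiled, neighbour-list
accelerated with a $0.6\,a$ skin rebuilt every 5 steps; pair terms are cut
off where $f < 10^{-4}$, about $3.0\,a$; forces outside the integrators —
`total_force()` — are evaluated exactly, with no cutoff, and match central
finite differences of the energy).

**Production Brownian dynamics** (`brownian_run()`) uses the overdamped
Euler–Maruyama update
$r_i \leftarrow r_i + F_i\,dt + \xi_i$, with per-component noise variance
$2\,m_i\,dt$ where $m_i$ is the locus's noise-variance multiplier
($D_i^0 = a^2/\tau_{BD} = 1$; a free passive bead has MSD $= 6t$ exactly).
Chain non-crossing is enforced operationally by the repulsive core plus a
cap of $0.1\,a$ on the per-step *drift* displacement; the cap is applied to
the deterministic term only, because capping the thermal term would
truncate the displacement distribution and bias free diffusion (the
free-bead law is a test). A hard bound of $0.5\,a$ on the total per-step
displacement triggers a counted redraw; at the default $dt$ its trigger
probability is $\sim 10^{-13}$. For *phantom* reference chains (no excluded
volume, hence no crossing constraint) the tests widen both caps.
$dt$ must stay below $0.5/k_{\max}$; the integrator refuses larger steps.

**Conformational sampling** (`langevin_sample()`) integrates underdamped
Langevin dynamics (BAOAB, $m = 1$, friction $0.1/\tau$, $dt = 0.01$).
Collapse of extended chains is violent at low friction, so the sampler
applies two regularisations that are inert at equilibrium: per-bead force
norms are clamped at $10^3$, and per-bead speeds at $5\,a/\tau$ (thermal
speeds are $\sim 1.7$), which bounds the per-step displacement so the
neighbour list stays fresh and beads cannot tunnel through each other
during the quench. Sampled conformations satisfy the hard-core and
bond-length bounds. Its role is the study's preparation step: collapsing an
ensemble of extended chains into compact structures.

**Active noise** (`make_activity_profile()`, `activity_spec()`) doubles the
white-noise variance on A1/A2 loci ($6D^0 \to 12 D^0$ per unit time),
breaking fluctuation–dissipation on active loci only; the drift response is
unchanged, and the noise is strictly isotropic (no force dipoles —
coarse-graining 50 kb per bead averages out vectorial activity).

## Why the ensemble is built from independent collapses

Crumpled-globule statistics are a property of *how* the chain got compact.
A single long sampling run equilibrates local scales, producing ideal local
statistics ($P(s) \sim s^{-3/2}$ at small $s$) on top of a dense globule.
Independently collapsing many extended chains — the protocol the study
itself uses — freezes the space-filling organisation in: the resulting
ensembles show $R(s) \sim s^{1/3}$ over $s \in [8, 128]$ and
$P(s) \sim s^{-1}$ over the intermediate decade. The analysis scripts and
the acceptance computation therefore build ensembles as one conformation
per collapse.

### Fitting windows

Scaled-down systems cannot hold the full-scale scaling regimes, so every
fit window is an explicit argument, fixed as follows for $N = 256{-}512$:

* $R(s)$: $s \in [8, 128]$ — above bead granularity, below saturation;
* $P(s)$: $s \in [12, 120]$ — the intermediate decade between the
  local-statistics scale ($\sim$10 loci, where the untrained generic model
  retains ideal statistics) and the saturation scale ($\sim N/2.5$);
* MSD exponent: lags $[30, 300]\,\tau_{BD}$ (the developed subdiffusive
  window at $N = 256$; shorter matched runs use $[30, 200]$);
* active/passive MSD ratio: lags $[10, 50]\,\tau_{BD}$, well below the
  confinement-saturation scale so the amplitude ratio is not compressed;
* Rouse modes: $p \in [2, N/8]$ for ideal-chain references ($-2$), the
  upper decade $p \in [N/10, N]$ for the collapsed chain ($-(1+2\nu)$);
* $\tau_k$: three wave numbers mapped from $s \in \{16, 32, 64\}$ via
  $k = 2\pi/(a\,s^{\nu})$, probing scales between the local liquid scale
  and the confinement radius.

## Synthetic annotation generator

`generate_annotation()` draws a blocky barcode: block types i.i.d. with the
configured weights and block lengths geometric (memoryless, one-parameter)
with mean 20 loci ($\sim$1 Mb), emulating megabase-scale subcompartment
blocks; the default weights put 40% of mass on A1+A2. The empirical
block-length law of real subcompartments is not published at this
granularity; geometric is a stand-in, not an inference. Because a short
chain holds only $\sim N/20$ blocks, the realised active fraction of an
unconditioned draw fluctuates well beyond binomial noise; `target_active`
redraws deterministically until the realised fraction is within tolerance,
which is how scaled study systems pin the 40% condition.
`generate_loops()` samples anchor pairs uniformly over a separation band
(optionally biased toward active blocks). `make_rouse_ensemble()` gives
exact Gaussian-chain references, and `make_collapsed_fixture()` builds a
fast non-overlapping compact chain (global compression of a random walk +
low-temperature annealing with the package's own integrator) for tests.
Being a single quenched realisation, the fixture's fitted $R(s)$ exponent
fluctuates roughly between 0.2 and 0.4 across seeds (the canonical seed-1
fixture sits at 0.36); ensemble-grade space-filling structure comes from
`collapse_conformations()`, the sampler-based protocol.

What the generator does *not* emulate: real Hi-C-trained interaction
specificity, sequence-anchored loop positions, nucleolus/lamina
association, or replication-state heterogeneity. Green tests on synthetic
inputs demonstrate the *methods* and the scaling physics of the model
class, not agreement with any particular chromosome.

## Analysis conventions

* **DRMS** (`drms()`): internal-distance RMSD, rigid-motion invariant;
  clustering uses complete linkage (`cluster_hierarchical()`, via
  `stats::hclust`, flat clusters = subtrees merging strictly below $D_c$);
  `cluster_qt()` implements the quality-threshold alternative; centroids
  minimise the intra-cluster distance sum, ties to the smallest index.
* **Time averages** (`msd_locus()`, `velocity_correlation()`,
  `intermediate_scattering()`): every admissible time origin on the frame
  grid, matching the integral definition at frame resolution; lags default
  to ~30 per decade (log-spaced) so log-log fits are well conditioned.
* **Displacement correlations** (`displacement_correlation()`): the
  distance delta function is realised as histogram binning (default width
  $0.5\,a$, range $2R_s$); empty bins are NA, never zero. The correlation
  length integrates the profile normalised by its value at $r = a$
  (interpolated between bin midpoints), truncated where the normalised
  profile falls below 0.01 — the infinite upper limit is not computable
  from finite data.
* **Relaxation times** (`relaxation_time()`): trapezoidal integral of
  $F_k(t)/F_k(0)$ with an exponential tail fitted on the last decade of
  lags. The $k \to s$ mapping uses $s = (2\pi/ka)^{1/\nu}$; the prefactor
  is a convention and is stated wherever used.
* **Knot screening** (`alexander_polynomial()`): termini are pushed
  radially onto a sphere of 3× the chain extent and joined by a great-arc,
  KMT triangle elimination simplifies the polygon (invariant-preserving,
  tested), a generic projection is searched over a fixed rotation list
  (with a sub-bead deterministic jitter for exactly degenerate inputs), and
  the Alexander determinant is evaluated at $t = -1$: 1 for the unknot, 3
  for the trefoil, 5 for the figure-eight. The full-scale study reports the
  *mode* of the unknotted population near zero on its histogram axis; this
  implementation returns the standard invariant value (1 for the unknot)
  — the conventions differ by presentation, not substance.

## Study conditions at package scale

The full-scale experiment ($N = 2712$, $\tau_{\max} = 4\times10^4\,
\tau_{BD}$, hours of compute) is out of reach for a test suite; the package
fixes these scaled conditions (stated here as the package's own choices and
used identically by the analysis scripts, the test suite and the acceptance
computation):

* structural ensembles: $N = 512$, $\phi = 0.1$, 40–50 independent
  collapses (burn-in 40 Langevin time units);
* production dynamics: $N = 256$, $600\,\tau_{BD}$ passive runs
  ($dt = 10^{-3}$, frames every $0.25\,\tau_{BD}$); the active-noise
  comparison (`active_msd_experiment()`) uses three full replicates — a
  fresh annotation at the 40% target, a fresh collapse, and a matched
  passive/active $400\,\tau_{BD}$ pair sharing the noise seed — so the
  replicate average integrates over annotation realisations, whose block
  layout is the dominant variance source at this chain length;
* ideal-chain references: $N = 256$, $6000\,\tau_{BD}$ at $dt = 10^{-2}$.

At this scale the crumpled window spans about one decade, so measured
exponents carry a few-percent window sensitivity; the tests assert bands
($\nu \in [0.28, 0.40]$, $\beta = 0.4 \pm 0.1$ on long runs,
$P(s)$ slope $-1 \pm 0.15$, mode slope $-1.7 \pm 0.15$,
$\tau_k$ slope $5/3 \pm 0.3$), not point values.

## Known limitations

* The interaction table is generic, not Hi-C-trained: absolute contact
  maps, energies and amplitudes are not comparable to any real chromosome;
  only scaling observables are.
* Non-crossing is operational (repulsive core + step caps), not a
  topological constraint; the knot screen provides the post-hoc check.
* The active-noise model is scalar and white; vectorial or correlated
  activity (condensin/cohesin motors) is out of scope.
* Hydrodynamic interactions are neglected (free-draining dynamics), as in
  the underlying model class.
* The $l_c(\Delta t)$ nonmonotonicity under activity emerges at lag times
  of order $10^3\,\tau_{BD}$ in the full-scale system; at package scale the
  analysis scripts report the passive/active $l_c$ trends but the effect
  sits near the noise floor, so it is not a test assertion.
* Under active noise the scaled system keeps reorganising (coarsening of
  the A/B segregation) throughout the accessible run length, which inflates
  the *apparent* MSD exponent of active runs (fits scatter around
  0.45–0.55 rather than 0.4); the asymptotic active exponent is only
  reachable with trajectories orders of magnitude longer than the package's
  study conditions. The active/passive *amplitude* ratio at fixed lags is
  insensitive to this and is the quantity the package reports.

## Reduced vs physical units

`physical_units()` fixes $a = 150$ nm (one 50 kb locus), $\eta = 7$ cP,
$T = 300$ K (the study quotes no temperature; 300–310 K round to the same
Brownian time), giving $\tau_{BD} = 3\pi\eta a^3/k_BT \approx 54$ ms —
"about 50 ms" at the mapping's precision. `to_physical_msd()` and
`to_physical_time()` convert analysis outputs; e.g. an MSD of
$0.96\,a^2$ at $10\,\tau_{BD}$ is $\approx 0.022\,\mu m^2$ at
$\approx 0.5$ s, matching live-cell magnitudes.

```{r units}
unit_table(physical_units(), N = 2712, phi = 0.1)
```
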
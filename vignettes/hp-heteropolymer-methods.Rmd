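---
title: "Methods: coarse-grained HP heteropolymers, from single chains to phase behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained HP heteropolymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`hpsep` studies a minimal question about intrinsically disordered proteins
(IDPs): when two sequences have the *same* single-chain dimensions, do they
also have the same propensity to phase separate? The model reduces an IDP to
a bead-spring heteropolymer of `N = 20` monomers drawn from a two-letter
alphabet — hydrophobic (H) and polar (P) — with the solvent implicit in the
pair potential. The fraction of polar monomers `X_P` is the composition
variable, swept from 0 (attractive homopolymer) to 1 (purely repulsive
chain) in steps of 0.05.

Bonded neighbours interact through a stiff harmonic spring

$$U_b(r) = k_b (r - r_0)^2, \qquad k_b = 2000~\mathrm{kcal/(mol\,nm^2)},
\quad r_0 = 0.38~\mathrm{nm},$$

and nonbonded beads through an Ashbaugh–Hatch scaled Lennard-Jones
potential: with $U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$,

$$U(r) = \begin{cases}
U_{LJ}(r) + (1 - \lambda_{ij})\,\epsilon, & r \le 2^{1/6}\sigma\\
\lambda_{ij}\, U_{LJ}(r), & 2^{1/6}\sigma < r \le r_{cut}\\
0, & r > r_{cut}
\end{cases}$$

with $\epsilon = 0.2$ kcal/mol and $\sigma = 0.5$ nm. The pair hydropathy
$\lambda_{ij}$ scales only the attractive branch: $\lambda = 0$ is exactly
the repulsive WCA potential (good solvent), $\lambda = 1$ the full
Lennard-Jones form (poor solvent). This piecewise construction is the unique
continuous interpolation with both limits; its well depth is exactly
$\lambda\epsilon$, i.e. $0.34\,k_BT$ per H–H contact at 300 K for
$\lambda_H = 1$ — a *slightly* attractive chain, not a collapsed globule.

Two mixing rules encode two interaction philosophies:

* **HP** (strong localized): $\lambda_{HH} = \lambda_H$,
  $\lambda_{HP} = \lambda_{PP} = 0$ — think tyrosine–tyrosine contacts.
* **HP+** (weak distributed): additionally
  $\lambda_{HP} = \lambda_H/2$ (arithmetic mean with $\lambda_P = 0$) —
  think aromatic–polar cross interactions.

We use $r_{cut} = 4\sigma = 2$ nm, truncated without shifting; the
neglected tail is below $10^{-3}\epsilon$ per pair. The bond prefactor
convention ($k_b$ rather than $k_b/2$) follows the engine lineage this model
family comes from; the bonds are stiff enough that either convention leaves
every reported observable unchanged at its quoted precision (bond-length
fluctuations change by $\sqrt 2$, which is invisible in chain-scale
quantities; a sensitivity check is included in the test suite via the
Boltzmann-quadrature dimer test).

## Dynamics

Chains are propagated by Langevin dynamics in the low-friction limit:
friction $\gamma = 0.1$ g/(mol fs) per bead of mass 100 g/mol, $T = 300$ K,
timestep 10 fs. We discretise with the BAOAB splitting, which has the
smallest configurational sampling bias of the standard Langevin splittings
at large timesteps and degenerates to velocity Verlet when $\gamma = 0$ —
the limit used by the energy-conservation test. With $\gamma/m = 10^{-3}$
fs$^{-1}$ the momentum relaxation time is 1 ps, so chain configurations
decorrelate quickly; the bond vibration period (~340 fs) is resolved by ~34
steps. Velocities are initialised from the Maxwell–Boltzmann distribution,
and the first 10% of each production run is discarded before analysis (a
fixed, configurable convention).

The engine keeps coordinates unwrapped (chains never break across the
periodic boundary; minimum image is applied in all distance computations),
uses a Verlet list with a 0.4 nm skin rebuilt on a half-skin displacement
trigger, and freezes each pair's periodic image at rebuild time — valid
because pair separations in the list are far below half the box. All
randomness comes from a counter-free xorshift generator seeded explicitly;
a (state, seed) pair reproduces a trajectory bit for bit.

## Single-chain observables and calibration

Chain size is measured by the radius of gyration from the gyration-tensor
trace; shape by the anisotropy $\kappa^2$, the eigenvalue invariant that is
0 for spheres and 1 for rods (~0.39 for a 3D random walk); energetics by
the nonbonded potential energy $U_{nb}$; dynamics by the end-to-end vector
relaxation time $\tau_e$, estimated by fitting the ACF with a stretched
exponential $\exp[-(t/\tau_0)^\beta]$ and integrating,
$\tau_e = (\tau_0/\beta)\Gamma(1/\beta)$ (the integral definition is our
estimator choice; a plain exponential is the $\beta = 1$ special case and is
recovered within 0.05 on synthetic single-exponential input). The local
chain statistics are summarised by the effective scaling exponent $\nu$ of
internal distances, fitted on $\log\sqrt{\langle R^2(s)\rangle}$ vs
$\log s$ for separations $s \in [3, N-1]$; the lower cutoff excludes
bond-scale stiffness. All averages carry 5-block standard errors (blocks
contiguous, remainder dropped from the front).

Because increasing `X_P` removes attractive monomers, chains expand with
composition at fixed $\lambda_H = 1$. To give every sequence the same
single-chain dimensions as the `X_P = 0` reference we set
$\lambda_H = a/(1 - X_P)$ and tune $a$ per sequence and model. Keeping the
*mean* hydropathy fixed ($a = 1$) demonstrably does not preserve the
radius of gyration, so $a$ is found by a bracketed bisection on the
monotone-decreasing response $\langle R_g\rangle(a)$, stopping when the
match is within 3% of the reference (mirroring the match quality of the
localized model away from extreme compositions) or when the stochastic
error exceeds the residual — whichever comes first; the full evaluation
trace is returned for audit. The bracket grid spans $a \in [0.1, 20]$;
compositions whose response cannot bracket the reference (e.g. one or two
H monomers under the localized rule) fail loudly with a calibration error.

## Two-chain interactions

The dilute two-chain potential of mean force $w(r)$ along the
centre-of-mass separation is computed by umbrella sampling: harmonic
windows $U = (k/2)(r - r_w)^2$ with $k = 5$ kcal/(mol nm²) every 0.2 nm
from 0.4 to 6 nm, walked inward with each window seeded from the previous
one, combined with WHAM iterated to $10^{-8}$, with the $4\pi r^2$ measure
divided out and the zero anchored on a count-weighted average over the
outer 15% of the distance grid (weighting by bin counts keeps sparsely
visited edge bins from shifting the whole curve; the histogram support
extends 3.5 bias widths past the outermost windows so no window's samples
are truncated). Window errors come from 5-block WHAM re-solves.
Replica-exchange enhancement of the window sampling, common for this kind
of calculation, is deliberately not implemented: at this model's weak
couplings plain Langevin sampling suffices, and an entirely independent
rigid-conformation Mayer estimator — Boltzmann-averaging interchain
energies over pairs of pool conformations at fixed separation,
$w(r) = -k_BT\ln\langle e^{-\Delta U/k_BT}\rangle$ — provides the
cross-check; the two agree within twice their combined errors wherever the
Mayer effective sample size exceeds 100.

The second virial coefficient follows by trapezoidal quadrature,

$$B_{22} = -2\pi\int_0^{r_{max}}\left[e^{-w(r)/k_BT} - 1\right] r^2\,dr,$$

with the region below the smallest sampled separation treated as a hard
core. Hard-sphere and square-well closed forms validate the quadrature;
negative $B_{22}$ means net interchain attraction.

## Phase behaviour

Direct coexistence: chains start as a dense slab (initial concentration
~500 mg/mL, about 0.8 of the reference dense phase) spanning the short box
axes, and the z concentration profile is accumulated after re-centring each
frame on the periodic (circular) centre of mass — the standard slab trick;
we prefer it to centring on the largest cluster because it needs no
unwrapping of a cluster that itself spans the boundary, and for any
slab-forming system the two coincide. Concentrations are mass-based
(mg/mL), from the 100 g/mol bead mass. Coexistence concentrations come
from a symmetric tanh interface fit; a run is classified **slab** when the
fit converges with a dense plateau at least 4 interface widths wide and
the largest chain cluster holds ≥ 90% of chains, **cluster** when the
largest-cluster fraction is below 90% with visible probability at small
cluster sizes, and **homogeneous** when the profile is flat within errors.
Chain clusters use the 1.5σ monomer-contact criterion with union-find
components; $P(N_c)$ is chain-weighted and sums to 1. Scanning the
composition grid with calibrated interactions gives the threshold
composition `X_P*` — the largest composition still forming a slab — whose
resolution is the grid spacing.

## Scaled-down campaign sizes

The package defaults target the full production geometry (500 chains,
10×10×75 nm) but every stage is size-parameterised, and the analyses in
the test-suite and examples run a desk-scale campaign: 48–100 chains in
8×8×28 to 10×10×40 nm boxes, 1.5–2×10⁵ Langevin steps per state point,
single-chain runs of 2×10⁵–8×10⁶ steps. These sizes were chosen so a
complete scan runs on one CPU in minutes while keeping the qualitative
phase classification stable; the quantitative cost is larger interface
fluctuations and coarser composition resolution (0.1–0.2 in `X_P`), which
is why threshold checks are formulated as brackets around the expected
values rather than point estimates.

## What the sequence generator does and does not emulate

The generator reproduces the study design: exact composition control
(`round(N·X_P)` polar monomers, round-half-to-even at ties), uniformly
random placement at fixed composition, and an optional maximally-even
patterned variant standing in for highly patterned sequence sets. It does
not emulate 20-letter amino-acid alphabets, charge patterning, or
length polydispersity — so agreement of downstream statistics with the
reference values demonstrates correctness of the machinery for this model
class, not transferability to real protein sequences.

## Numerical choices and degenerate inputs

* Round-half-to-even for the polar-monomer count at ties (`N·X_P = 2.5`).
* WHAM tolerance $10^{-8}$; non-overlapping adjacent windows raise a
  coverage error naming the gap.
* $B_{22}$ refuses tails with $|w(r_{max})| > 0.05$ kcal/mol.
* The interface fit refuses flat or inverted profiles (classification
  error); contradictory slab/cluster indicators return `"indeterminate"`
  with a warning rather than an error.
* Overlapping particles ($r < 10^{-6}$ nm) and non-finite coordinates abort
  with the step index; the blow-up check runs at list rebuilds and frame
  samples.
* Single-bead "chains" are admitted by the builders so that the two-body
  limit of the PMF machinery can be validated against the exact pair
  potential.

## Known limitations

* The intrachain scaling exponent of a 20-mer has no clean asymptotic
  regime: because the bead diameter (0.5 nm) exceeds the bond length
  (0.38 nm), short internal separations are effectively swollen and the
  local exponent decreases with separation (from ~0.6 at s = 3–5 toward
  ~0.47 at s = 10–19). The default fit over the full s ∈ [3, N−1] range
  therefore reports a value a few hundredths above the large-separation
  asymptote; `intrachain_scaling()` exposes `fit_range` so either regime
  can be examined.
* Desk-scale coexistence campaigns (tens of chains, nanoseconds) classify
  phase states robustly below the threshold composition, but a single
  finite aggregate of all chains is geometrically indistinguishable from a
  thin slab, so beyond-threshold classification and quantitative
  dense-phase concentrations need the full-scale geometry (hundreds of
  chains, microseconds). Dense concentrations from short desk runs also
  carry an upward finite-size bias (curved interfaces).
* The rigid-conformation Mayer estimator neglects intrachain relaxation in
  the pair field; it is a cross-check at weak coupling, not a replacement
  for umbrella sampling at strong coupling.
* Kinetic temperature is controlled, but transport coefficients are only
  meaningful in the low-friction Langevin sense (no hydrodynamics).
* The desk-scale slab geometry makes dense plateaus only a few interface
  widths wide; near-threshold classifications are reported with that
  caveat and the full-size geometry remains available through the
  configuration.
* No electrostatics, no temperature-dependent hydropathies, no
  constant-pressure ensembles.
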
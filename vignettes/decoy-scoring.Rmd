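---
title: "Scoring docking decoys with constraint-force free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring docking decoys with constraint-force free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdock)
```

## The problem and the model

A protein–protein docking run produces thousands of candidate binding
orientations of a receptor and a ligand. `cgdock` scores each candidate by
an estimate of its binding free energy: if the pose is (near-)native, it
should sit in a deep free-energy well along the dissociation coordinate;
if it is a packing artefact, the well should be shallow.

The dissociation coordinate is the distance $r$ between the centres of
mass (COM) of the two partners. At a series of fixed values of $r$, the
mean *constraint force* $\langle f_c \rangle(r)$ — the force required to
hold the COM distance at $r$ — is sampled by simulation. The potential of
mean force is the integral

$$W(r_i) = \int_{r_i}^{r_N}\left[\langle f_c\rangle(s) -
\frac{2 k_B T}{s}\right]\,ds , \qquad W(r_N) = 0,$$

where $r_N$ is the largest sampled distance. The $2k_BT/s$ term is the
radial Jacobian (entropic) correction: a distance constraint in three
dimensions acquires an outward entropic force of exactly $2k_BT/r$ even
between non-interacting bodies, and subtracting it makes the PMF of free
bodies flat. The correction is a flag on `integrate_pmf()` and is on by
default, because only then does $\Delta G_\mathrm{off} = 0$ for
non-interacting partners; this package fixes the sign convention of the
recorded force operationally by that requirement.

The binding free energy is extracted as

$$\Delta G_\mathrm{off} = W(r_\mathrm{min}) - W(r_\mathrm{max}),
\qquad r_\mathrm{min} < r_\mathrm{max},$$

with $r_\mathrm{min}$ the location of the lowest PMF value and
$r_\mathrm{max}$ the location of the *highest* PMF at any larger distance.
Ties are resolved to the smallest $r$ for the minimum (the most bound
state) and the largest $r$ for the maximum (the most separated state). We
read "highest value at larger distance" as the global later maximum, not
the long-range plateau; for profiles with a barrier the two differ, and
the global reading makes $\Delta G_\mathrm{off}$ penalise the full
dissociation barrier. If the minimum falls on the last window the profile
has no dissociation signal in range and the value is defined as 0, flagged
degenerate.

## Window schedule

The schedule is anchored at the decoy's docked COM distance
$d$ (`dock_COM`): 23 distances spaced 0.05 nm starting 0.1 nm below $d$,
plus 9 distances spaced 0.1 nm starting 1.15 nm beyond $d$ — dense where
the well and barrier live, sparse along the dissociated tail, 32 windows
in all. The gap between the two series is exactly 0.15 nm.

```{r schedule}
make_schedule(3.0)
```

`make_schedule()` refuses `dock_COM` ≤ 0.1 nm, which would place a window
at a non-positive distance.

## Coarse-graining

`coarse_grain()` maps each residue to a single bead at the unweighted
centroid of its heavy atoms, carrying the summed heavy-atom mass. Each of
the 20 amino acids belongs to one of four particle classes — polar (P),
nonpolar (N), apolar (C), charged (Q) — with charges −1 for Asp/Glu and +1
for Lys/Arg; histidine is treated as neutral polar, its dominant state at
pH 7. The table lives in `residue_classes()` and is an argument of
`coarse_grain()`, i.e. explicitly configurable: it is a hydropathy-based
default, not a fitted parameter set. One bead per residue (rather than a
backbone/side-chain split) is sufficient here because the dynamics treats
each partner as rigid, so intramolecular detail cannot influence the
score.

All-atom structures are in Å (the native PDB unit); bead models and
everything downstream are in nm, ps, amu and kJ/mol, a unit system in
which no conversion constants appear in the equations of motion.

## The rigid-body engine

The sampling engine (`simulate_window()`) is a toy, and deliberately so:
it replaces a full coarse-grained MD package with the smallest model that
preserves what the score actually discriminates — the decoy's binding
orientation. Each partner moves as a rigid body (rotation represented by a
unit quaternion, renormalised every step) under overdamped Langevin
dynamics at temperature $T$ with friction $\gamma$ (default 10 ps⁻¹):

* translational drift $F/(\gamma M)\,\Delta t$ with diffusive noise of
  variance $2k_BT\Delta t/(\gamma M)$ per coordinate;
* rotational drift $\tau/(\gamma I)\,\Delta t$ about each axis, with
  matching isotropic angular noise, where $I = \sum_i m_i |b_i|^2$ is a
  scalar inertia proxy;
* bead–bead forces between opposite groups only: a truncated
  Lennard-Jones potential ($\sigma = 0.47$ nm, cutoff 1.2 nm, energy
  shifted to zero at the cutoff) with well depth $\varepsilon_{XY}$ from a
  4×4 class-pair table, plus Debye-screened Coulomb
  ($\lambda = 1$ nm, prefactor $138.935/15$ kJ mol⁻¹ nm) between charged
  beads. The $\varepsilon$ table orders like-class contacts strongest and
  apolar–polar contacts weakest; it is configuration
  (`default_epsilon()`), not a physics claim.

After every step the COM distance is projected back to the window value
$r$ exactly: both bodies are displaced along the inter-COM axis with
mass weights $M_B/(M_A+M_B)$ and $M_A/(M_A+M_B)$. The restoring
displacement, converted to a force through the friction coefficient,

$$f_c = \gamma\,\mu\,\frac{d_\mathrm{unconstrained} - r}{\Delta t},
\qquad \mu = \frac{M_A M_B}{M_A + M_B},$$

*is* the recorded constraint force. For free bodies
$\mathbb{E}[f_c] = 2k_BT/r$ analytically under this scheme, which is the
sign/normalisation anchor mentioned above; with a radial potential $U$,
$\mathbb{E}[f_c] = -U'(r) + 2k_BT/r$, so the Jacobian-corrected integral
recovers $U$. Both identities are exercised by the test suite (the second
at $T = 10$ K to a 5% tolerance).

Numerical choices worth knowing:

* **Time step** 20 fs (the conventional coarse-grained value), total
  window length a free knob (`n_steps`, default 5×10⁴ with the first 20%
  discarded as equilibration).
* **Error bars** per window come from block averaging (64 blocks), which
  is robust to the short-lag correlation of the force samples; the PMF
  standard error is propagated linearly through the trapezoid weights.
* **Quadrature** is trapezoidal. The windows are dense (0.05 nm) where
  curvature lives, and the rule is exact for linear force profiles, which
  makes the harmonic-potential oracle in the tests exact to rounding.
* **Stability**: the deterministic part of a translation step is capped at
  0.05 nm so that a clashed starting pose relaxes instead of exploding;
  the noise term is never clamped. Non-finite forces abort with the step
  number. Window start-up places the ligand on the current COM axis at the
  window distance; in bead-interaction mode, placements with inter-group
  bead distances below 0.15 nm are retried with random ligand orientations
  (up to 1000 attempts) before erroring.
* **Determinism**: all randomness flows through R's RNG; identical
  `(model, r, params, seed)` give bit-identical samples. Per-window seeds
  are derived from (base seed, decoy index, window index, replicate id)
  with a Lehmer-style hash (`derive_seed()`), so replicates and windows
  get separated, reproducible streams.
* An analytically known radial potential (`radial_potential()`, harmonic
  or Gaussian well) can be injected in place of the bead sums, acting
  between the COMs. This is the validation backdoor used throughout the
  tests, and also the fast scoring path for synthetic decoy sets.

## The staged replicate protocol

`run_full_protocol()` scores every decoy once (replicate 1), ranks
ascending on $\Delta G_\mathrm{off}$, keeps the best (lowest) 50% —
$\lceil N/2\rceil$, so the median decoy survives an odd set — and gives
survivors four more replicates. The final ranking orders survivors by the
mean $\Delta G_\mathrm{off}$ over all five replicates; averaging happens
at the free-energy level, not the force level, matching the protocol the
replicates are meant to stabilise. Cut decoys keep their stage-1 score and
are appended after the survivors (flagged `stage1-cut`), so enrichment
over the full set remains computable. Ties are broken lexicographically by
decoy id, which makes the whole protocol a deterministic function of the
base seed. A crystal-reference mode (`crystal_reference()`, 20 replicates
by default) scores the native structure for comparison.

## CAPRI quality measures

`assess_decoy()` computes, against the native structure:

* **fnat** — the fraction of native residue–residue contacts reproduced;
  a contact is any heavy-atom pair across the interface within 5 Å (the
  CAPRI convention; configurable). **fnonnat** is the fraction of the
  decoy's contacts that are non-native; Precision = 1 − fnonnat.
* **L-rms** — backbone (N, CA, C, O) RMSD over the ligand after
  least-squares superposition of the receptors, without re-fitting.
* **I-rms** — backbone RMSD over the interface residues (native residues
  with any heavy atom within 10 Å of the partner chain; configurable),
  superposed on that same set.

Superpositions go through bio3d's Kabsch fit; the test suite checks them
against an independent SVD implementation. Residues missing from either
structure are dropped from both before fitting, so partial decoys are
handled by pairwise-complete correspondence.

`classify_capri()` applies the four-tier rules in order High → Medium →
Acceptable → Incorrect, "and" binding tighter than "or", first match wins:

* High: fnat ≥ 0.5 and L-rms ≤ 1.0 and I-rms ≤ 1.0
* Medium: (fnat ≥ 0.5 and L-rms > 1.0 and I-rms > 1.0) or
  (0.3 ≤ fnat < 0.5 and (L-rms ≤ 5.0 or I-rms ≤ 2.0))
* Acceptable: (fnat ≥ 0.3 and L-rms > 5.0 and I-rms > 2.0) or
  (0.1 ≤ fnat < 0.3 and (L-rms ≤ 10.0 or I-rms ≤ 4.0))
* Incorrect: everything else.

The Medium and Acceptable "or" branches carry no upper RMSD bounds, so a
decoy with fnat 0.4 and arbitrarily large L-rms but I-rms ≤ 2 is still
Medium under this rule set. The official CAPRI criteria add upper bounds
there; this package implements the rule set as written above (ordered
evaluation makes it total and unambiguous) and treats the discrepancy as a
property of the rule set, not a bug. The target *difficulty* is the
fraction of acceptable-or-better decoys in the full set.

## The synthetic generator

`make_native()` builds a two-chain complex from backbone-only residue
stubs (N, CA, C, O at idealised local geometry, 3.8 Å CA spacing, a mild
out-of-plane texture) facing each other across a 7 Å plane gap, with a
configurable number of directly juxtaposed residue pairs, each
contributing one inter-chain heavy-atom contact within 5 Å. The residue
sequence cycles through all 20 amino acids so every particle class and
charge appears. `make_decoys()` perturbs the ligand rigidly per quality
tier; the default magnitudes (High ≤ 0.5 Å / 2°, Medium 0.5–2 Å / 2–8°,
Acceptable 2–6 Å / 8–25°, Incorrect ≥ 15 Å / ≥ 90°) land the tiers in
roughly the four CAPRI categories, and the default tier mix (5/10/15/70
out of 100) mirrors a realistic benchmark in which near-native poses are
a minority. Generative labels are *never* used as truth downstream — the
classifier is.

What the generator does **not** emulate: side chains and their packing
(contacts are backbone–backbone and therefore sparser and more fragile
than in real interfaces — a 1–2 Å shift can break a toy contact that a
real side-chain-rich interface would keep, so generative tier and assigned
category correlate imperfectly by design); flexible backbones; chemically
heterogeneous interface patches; crystallographic artefacts (altlocs,
gaps) beyond what the reader tolerates. Passing tests on this material
validates the machinery — geometry, integration, ranking, classification —
not the force field's ability to score real interfaces.

`make_force_profiles()` synthesises the force profile a perfect
measurement of a known radial potential would give (optionally with the
Jacobian term and Gaussian noise); it doubles as the import path for force
data produced elsewhere, via the same tabular window-sample format.

## Problem sizes and validation

The test suite builds everything it needs at run time. The acceptance
blocks use: 12-residue chains (24 beads); 5×10⁴-step windows for the
free-body flatness and low-temperature force checks; 4×10³-step windows at
50 K for the staged-protocol ordering of four injected Gaussian wells
(−60/−40/−20/−5 kJ/mol depths, 10 seeded runs); and 100-decoy synthetic
sets over 10 seeds for the enrichment property (top-10
acceptable-or-better fraction at least the full-set fraction in ≥ 9/10
seeds). These sizes were chosen so the whole suite validates the method in
a few minutes on one core; all of them scale up through `sim_params()` and
`synth_config()` if sharper statistics are wanted.

## Known limitations

* Rigid bodies: induced fit and interface relaxation are invisible to the
  score; a decoy with clashes relaxes only through rigid displacement.
* The bead interaction table is a plausible ordering, not a validated
  force field; absolute $\Delta G_\mathrm{off}$ values have no
  experimental meaning here — only their ranking within a decoy set is
  used.
* PMF error bars come from per-window standard errors only; no bootstrap
  or autocorrelation-time analysis beyond block averaging.
* Homo-oligomer symmetry (chain-swap-aware contact matching) is not
  implemented; chain correspondence is taken literally.
* The classifier follows the rule set stated above; scores near the
  Medium/Acceptable upper-bound gaps differ from official CAPRI
  assessments.
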
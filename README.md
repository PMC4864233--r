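# cgdock

Scoring protein–protein docking decoys by a simulated binding free energy.

Docking programs generate thousands of candidate binding orientations
("decoys") for a receptor–ligand pair; the hard part is recognising the
near-native ones. `cgdock` ranks decoys by a physics-based score: the
binding free energy estimated from the potential of mean force (PMF) along
the receptor–ligand centre-of-mass (COM) separation, sampled by
coarse-grained constrained dynamics.

## Method

Every structure is coarse-grained to one bead per residue, typed as polar
(P), nonpolar (N), apolar (C) or charged (Q). Starting from the decoy's
docked COM distance *d*, a schedule of 32 window distances is laid out —
23 distances spaced 0.05 nm starting 0.1 nm below *d*, and 9 distances
spaced 0.1 nm starting 1.15 nm beyond *d*. At each window the two partners
are held at the set COM distance *r* while a rigid-body overdamped Langevin
engine samples the mean constraint force ⟨f_c⟩ needed to keep them there.
The force profile, minus the radial Jacobian term 2·k_B·T/r, is integrated
over distance to the PMF W(r) (zero at the largest window), and the binding
free energy is

    ΔG_off = W(r_min) − W(r_max),   r_min < r_max,

the difference between the lowest PMF value and the highest PMF at any
larger distance. Lower (more negative) ΔG_off means stronger predicted
binding.

Decoy sets are ranked by a staged replicate protocol: one replicate for all
decoys, keep the best (lowest) 50%, run four more replicates for the
survivors, and rank on the mean ΔG_off over all five replicates. Selections
(top 1/5/10/20/100) are assessed with the CAPRI quality measures — fnat
(fraction of native contacts), L-rms (ligand backbone RMSD after receptor
superposition), I-rms (interface backbone RMSD) and the
High/Medium/Acceptable/Incorrect four-tier classification — together with
enrichment, Recall (fnat) and Precision (1 − fnonnat) reports.

A synthetic-data module generates toy native complexes, decoy sets spanning
all four quality tiers, and force profiles from analytically known radial
potentials, so the whole pipeline runs and validates at desk scale without
external data. The rigid-body engine is a deliberately small stand-in for a
full coarse-grained MD package: it preserves each decoy's internal geometry
and binding orientation, which is exactly what the score discriminates.

## Worked example

```r
library(cgdock)

cfg    <- synth_config(seed = 1)
native <- make_native(cfg)
model  <- coarse_grain(native)
model
#> Coarse-grained bead model: 24 beads
#>   receptor: 12  ligand: 12
#>   types: C=6 N=4 P=6 Q=8
#>   COM distance: 0.929 nm

sched  <- make_schedule(com_distance(model))
sched
#> Window schedule: 32 distances, 0.829 - 2.879 nm (dock_COM 0.929 nm)

forces <- run_replicate(model, sched, sim_params(n_steps = 2e4),
                        replicate = 1, base_seed = 1)
extract_dgoff(integrate_pmf(forces, temperature = 300))
#> Binding free energy: -35.816 kJ/mol  (r_min 0.829 nm, r_max 2.379 nm)
```

The native complex binds at its docked separation (the PMF minimum sits at
the innermost window) and dissociates over ~1.5 nm; the −36 kJ/mol span is
the predicted binding strength under the default bead interactions.

Ranking a full synthetic decoy set end to end:

```r
cfg        <- default_config()
cfg$seed   <- 7
cfg$outdir <- tempfile()
res <- run_pipeline(cfg, quiet = TRUE)
res$report
#> Target difficulty (acceptable-or-better fraction): 0.400
#>  selection  n High Medium Acceptable Incorrect acceptable_or_better recall precision
#>       full 20 0.15    0.1       0.15       0.6                  0.4  0.415     0.971
#>   top_half 10 0.30    0.2       0.30       0.2                  0.8  0.517     0.947
#>      top_1  1 1.00    0.0       0.00       0.0                  1.0  1.000     1.000
#>      top_5  5 0.60    0.2       0.20       0.0                  1.0  0.807     0.947
#>     top_10 10 0.30    0.2       0.30       0.2                  0.8  0.517     0.947
```

Here 40% of the 20-decoy set is of acceptable-or-better quality, while the
top-5 selection by ΔG_off is 100% acceptable-or-better — the ranking
enriches near-native poses, with Recall rising from 0.42 (full set) to 0.81
(top 5). `run_pipeline()` writes `ranking.tsv`, `quality.tsv`, `report.tsv`
and `scatter.tsv` (ΔG_off vs I-rms) with a provenance header.

A command-line wrapper with subcommands (`synth`, `split`, `cg`, `windows`,
`simulate`, `pmf`, `dgoff`, `rank`, `assess`, `enrich`, `run`, `config`)
is installed at `inst/cli/cgdock.R`:

```sh
Rscript inst/cli/cgdock.R windows --dock-com 3.0
Rscript inst/cli/cgdock.R assess --native native.pdb --decoy decoy_01.pdb
```

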
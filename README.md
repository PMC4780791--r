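# permeon

Ion-binding state analysis of single-file potassium-channel permeation.

## The problem

Potassium channels conduct K⁺ through a narrow selectivity filter in single
file. Long unbiased MD trajectories of a conducting pore are usually
analysed by discretizing each frame into an *ion-binding state*: which of
the binding sites — S0 at the extracellular mouth through S4 in the filter,
plus the Thr side-chain site S5 and the hydrated cavity S6 — hold an ion.
A frame with ions at S0, S2 and S4 is the state `K:0:2:4`, the usual
three-ion *resting state*. Watching the state sequence reveals how each
conduction event proceeds:

- **push (III-IV-III)**: a new intracellular ion associates *before* the
  outermost ion leaves; the pore transits a four-ion intermediate
  (the knock-on picture);
- **pull (III-II-III)**: the outermost ion dissociates *first*; the pore
  transits a two-ion intermediate until a new ion associates
  (the association/dissociation picture).

The balance between the two is a function of the driving forces: entry
pressure from the intracellular ion concentration pushes, the
transmembrane field pulls. `permeon` packages this analysis — site
discretization, state-transition graphs, conduction detection with
back-running rejection, mechanism classification, intermediate lifetimes,
currents with local block bootstrap errors, and occupancy free-energy
differences — together with a kinetic Monte Carlo generator of synthetic
single-file trajectories whose exact event log serves as ground truth for
every stage.

## Core quantities

- Current from the net traversal count: `I = N e / T` (pA), outward
  positive.
- Push fraction: `n_push / (n_push + n_pull)` over classified conductions,
  with a local-block-bootstrap standard error.
- Group free energies from occupancies: `ΔG(II, IV) = −RT ln(P_IV / P_II)`
  (kJ/mol, 300 K), negative when four-ion states are the more stable.
- Intermediate lifetime: time spent away from the resting ion count within
  one conduction cycle.

## Worked example

```r
library(permeon)

sim <- simulate_hopping(hop_model(), t_end_ns = 100, seed = 1)
s   <- summarize_condition("base-demo", sim$trajectory,
                           default_site_model(), n_boot = 1e4, seed = 1)
```

With the baseline generator (a moderately driven outward-conducting
channel) this prints, via `str(s)`:

```
 $ n_outward            : int 51
 $ n_inward             : int 0
 $ current_pA           : num 81.71
 $ current_se_pA        : num 11.04
 $ n_push               : int 40
 $ n_pull               : int 9
 $ n_unclassified       : int 2
 $ push_ratio           : num 0.8163
 $ push_ratio_se        : num 0.05423
 $ deltaG_II_IV_kJmol   : num -3.386
 $ mean_pore_ions       : num 3.242
 $ mean_lifetime_push_ns: num 0.653
 $ mean_lifetime_pull_ns: num 0.9133
```

51 ions completed outward traversals in 0.1 µs, a current of 82 pA; 40 of
the 49 classifiable conductions went through a four-ion intermediate
(push fraction 82 %), consistent with the negative ΔG(II, IV): four-ion
states are more stable than two-ion states here, and the pore averages
3.24 ions. Two conductions were cut by the trajectory edges and excluded
from the ratio. The same numbers are reproduced bit-for-bit by rerunning
with the same seed.

The pipeline also runs end-to-end from a config:

```r
cfg <- run_config(simulate = list(regime = "push", strength = 10,
                                  t_end_ns = 60),
                  seed = 1, out_dir = "out")
run_pipeline(cfg)   # writes state_sequence.tsv, graph.graphml/.dot,
                    # events.csv, summary.json, manifest.json
```

or from the command line: `Rscript inst/cli/permeon.R run --config run.json`
(also `simulate` and `validate` subcommands).

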
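---
title: "Ion-binding state analysis of single-file permeation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-binding state analysis of single-file permeation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeon)
```

## The model

A potassium channel pore is reduced to a one-dimensional axis: the line
from the centroid of the four Thr carbonyl oxygens at the base of the
selectivity filter (z = 0) to the centroid of the four Tyr carbonyls,
z increasing towards the extracellular side. Every K⁺ position is its
scalar projection onto this axis, and eight thresholds partition the axis
into `INTRA | S6 | S5 | S4 | S3 | S2 | S1 | S0 | EXTRA`. A frame's
*ion-binding state* is the multiset of occupied sites, written
`K:0:2:4`; two ions in S0 (capacity 2, all other sites 1) appear with
repetition, `K:0:0:2:4`. The analysis is agnostic about where thresholds
come from: they can be supplied, taken from the shipped synthetic
defaults, or estimated as the minima of the axial ion density between the
seven tallest modes (`estimate_thresholds()`, after a 3-bin moving-average
smoothing — raw histograms of finite trajectories are noisy and no
universal rule exists, so the smoothing width is fixed and documented
rather than tuned).

Conductions are detected from *boundary events* per persistent ion
identity: association from the intracellular fluid (INTRA to S6),
dissociation to the extracellular fluid (S0 to EXTRA), and the mirrored
pair for inward current. A completed conduction is an ion whose entry and
exit sides differ. Two deliberate conventions:

* **Back-running cancels an exit.** If an ion dissociates and its next
  boundary event is re-entry from the same side, it is treated as never
  having left (it keeps its original entry side). This makes a
  dissociation/re-association flicker at the mouth contribute zero
  conductions, which is the defining property of back-running, and it
  makes net counting exact: an ion that pops out, returns, and later
  leaves for good is counted once, at the final exit.
* **Initial residents count.** Ions already in the pore at the first frame
  have an unknown entry side; when they exit they are counted with the
  direction of their exit and flagged `initial_resident`. Over long
  trajectories this is a one-off O(3) correction either way; flagging
  keeps it auditable.

## Mechanism classification

Classification is kinetic, not graph-topological: the pore ion count on
the frame immediately before the permeating ion's exit is compared with
the resting count (3, configurable). Above resting means the replacement
ion associated before the dissociation — push, III-IV-III, a four-ion (or
five-ion, when S0 is doubly occupied) intermediate. At resting means the
dissociation came first and the pore dips below resting — pull,
III-II-III. The same rule serves inward conductions unchanged, because it
is phrased in counts rather than sides. The *intermediate lifetime* is
the span of the contiguous run of non-resting-count frames ending at the
exit (push) or starting at it (pull).

The classifier abstains (`unclassified`, excluded from ratios) when the
cycle is cut by a trajectory edge, or when an exit is exactly compensated
within one frame interval so no intermediate is visible. The latter is a
sampling limit, not an error: an intermediate shorter than the frame
spacing is unobservable by construction. The generator-backed tests
therefore demand exact label recovery only where the intermediate dwell
exceeds five frame intervals, and demand that every abstention be
attributable to one of these two causes.

## State groups

Nodes of the transition graph are grouped the way the landscape is
conventionally drawn: II (two ions), IV (four), V (five or more), and the
three-ion states split into the resting cluster IIIr and the
return-path cluster IIIe. The split is temporal: after a conduction
cycle's second boundary crossing, the three-ion states visited before the
first return to the modal three-ion state vote IIIe; all other three-ion
frames vote IIIr; each state takes its majority. Back-running returns
(same-side crossings) vote IIIr, matching the observation that a
re-entering extracellular ion restores the resting cluster directly.
Nothing downstream depends on this tag — mechanism counts use event
ordering only — so the ambiguity inherent in a narrative definition is
confined to reporting.

## Currents, errors, free energies

The current is `I = N e / T` with N the net signed traversal count and T
the full trajectory duration (equilibration trimming is exposed but the
current convention uses full length; the two conventions differ by 10 %
and the full-length one is the arithmetically consistent reading of the
worked examples the acceptance suite reproduces). Statistical errors come
from a *local block bootstrap*: the event series is cut into 100-ps
blocks, and each replicate redraws every block position uniformly from
positions within a ±10-block window (window configurable; as the window
grows the scheme tends to the ordinary i.i.d. block bootstrap, which is
the property the test suite pins against the closed-form binomial SE).
Replicates: 10⁶ by convention at the command line, 10⁴ in tests — the SE
estimate's own relative error is ~(2·n_boot)^(-1/2), so 10⁴ is already
below a percent and the scale-down only buys runtime. The same scheme
applied to per-event mechanism labels gives the ratio error.

Group stabilities are compared by Boltzmann inversion of occupancy:
`ΔG(a, b) = −RT ln(P_b / P_a)` at 300 K (RT = 2.494 kJ/mol), so
`delta_g(P_II, P_IV) < 0` means the four-ion states are the more stable.
Zero occupancies raise an error rather than returning ±Inf; the pipeline
reports NA with a flag in that case.

## What the synthetic generator emulates — and what it does not

`simulate_hopping()` is an exact Gillespie simulation of a single-file
hopping chain: seven sites with hard-core exclusion and no passing,
voltage-biased hop and boundary rates, concentration-like entry rates,
fresh ion identities on entry. Two ingredients stand in for the ion-ion
electrostatics that shape real filter occupancy:

* a **repulsion range** of one site: a move is rejected if another ion
  sits adjacent to the destination, which enforces the
  vacancy-separated occupancy pattern and makes `K:0:2:4` (deep wells at
  S0, S2, S4) the resting configuration;
* a **crowding factor** `exp(crowding · (n_pore − 3))` on the exit rates:
  a supernumerary ion destabilizes the outermost one (the kinetic face of
  knock-on), a depleted pore retains its ions.

The push regime multiplies the intracellular entry rate and divides the
extracellular exit rate by `1 + strength` (high concentration); the pull
regime is the inverse (strong field). At strength 0 both are the base
model. Baseline rates were chosen once so that the resting state is
modal, the mean pore count sits near 3, and both mechanisms occur; they
were not adjusted afterwards.

Deliberately absent: explicit water and co-permeation, real energetics or
any fit to simulation data, conformational gating, and sub-frame event
reconstruction (frame sampling discards inter-frame events by design —
tests constrain the frame interval relative to dwell times instead).
Consequently a green generator-backed test establishes that the analysis
is correct on trajectories with the assumed statistical structure
(discrete sites, exclusion, Markov hopping, Gaussian jitter), not that
any particular force field or channel behaves this way.

Frame sampling renders an ion at its reservoir-side bulk position for the
one-frame margin around its entry and exit so that crossing sides are
observable downstream; when an ion appears or vanishes inside the pore
without such a margin (real MD data often will), the side is inferred
from the nearest pore end and the event flagged `inferred`.

## Numerical choices

* Half-open `[lo, hi)` intervals, boundary values to the extracellular
  side: deterministic tie-break where the sources are silent.
* Raw per-frame states by default; `debounce_states()` suppresses
  sub-dwell flicker for reporting, but event detection always uses raw
  assignments, so debouncing cannot change conduction counts.
* Transitions with crossings on both pore boundaries within one frame
  interval are flagged `internal` with a warning: the ordering inside one
  frame is unknowable.
* Positional jitter must stay below half the minimal inter-site spacing
  (constructor-enforced) or site assignment would be corrupted.
* All randomness (Gillespie, jitter, bootstrap) is seeded; the event log
  is drawn before any jitter, so the ground truth is invariant to the
  frame interval at a fixed seed.
* The master-equation oracle in the test suite enumerates the reachable
  occupancy space of the seven-site chain (a few dozen configurations
  under the repulsion rule) and solves πQ = 0 by a dense linear solve —
  an independent route to the same stationary occupancies the simulator
  must reproduce.

## Known limitations

Site thresholds shipped as defaults are synthetic geometry, not fitted
values; real analyses should estimate or supply their own. The
IIIr/IIIe split is majority-vote and can relabel rarely-visited states
on short trajectories. Inward dissociation accepts any pore-to-INTRA
crossing (S6 or S5), which double-counts nothing but is more permissive
than a strict S6-only reading. The local block bootstrap assumes the
block size exceeds the event autocorrelation time; 100 ps is conventional
for these trajectories but is not validated per-dataset.
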
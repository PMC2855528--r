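---
title: "Mining active state transition diagrams from hybrid Petri net simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining active state transition diagrams from hybrid Petri net simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfpne)
```

## The model class

A hybrid functional Petri net with extension (HFPNe) is a Petri net whose
places, transitions and arcs each come in three kinds.  Discrete places
hold non-negative integer token counts; continuous places hold
non-negative real concentrations (for mRNAs, proteins, complexes);
generic places hold arbitrary serializable values such as genotype
strings.  Continuous transitions fire continuously at expression-valued
speeds, the usual way to encode transcription, translation, complex
formation and degradation; discrete and generic transitions fire after an
expression-valued delay, moving tokens or replacing a mark wholesale.
Arcs carry the wiring: a *normal* arc moves quantity, while *test* and
*inhibitory* arcs are read-only conditions running place to transition
only.  Every input arc has an activity expression `w` — a numeric
threshold for discrete/continuous transitions, a boolean condition for
generic ones — and every normal arc has an update expression `u` (amount,
speed, or replacement value).  Times are in the model's virtual time unit
[pt], concentrations in the virtual concentration unit [vc].

Enabling is strict on both sides: a non-inhibitory arc requires the
source mark to *exceed* its threshold, an inhibitory arc requires it to
stay *strictly below*; ties disable.  A transition with no input arcs is
treated as permanently enabled (the vacuous conjunction, the standard
Petri-net reading).  Token reservation is switched off throughout (the
α = 0 convention), so the effective marking always equals the plain
marking; the reserved marking is kept in the data model only so that its
invariant — identically zero, or null for generic places — is testable.

## Execution semantics

`simulate_net()` runs a fixed-step schedule.  Time points are
`x_i = i·Δ` for `i = 0 … N−1` with `N = end/Δ`; the half-open convention
is deliberate, because it makes a 150 [pt] run sampled at 0.01 [pt]
contain exactly 15,000 points, the count the downstream state-diagram
stages are specified against.  At each point the simulator first applies
scheduled discrete/generic firings that have come due (checking the
transition is still enabled; a firing whose transition was disabled in
the meantime is canceled and logged, or raises under the strict policy),
then schedules firings for newly enabled discrete/generic transitions at
`x + d(t)[M(x)]` with per-arc amounts snapshotted at the trigger time,
then records the marking, and finally advances the continuous transitions
by forward Euler over `[x, x+Δ)`.

Numerical choices worth knowing:

* **Integrator.** Forward Euler with step Δ, with an optional integer
  `substeps` refinement that subdivides the integration while still
  reporting at Δ.  Nothing in the formalism prescribes an integrator;
  Euler keeps the one-step resimulation property (below) exact by
  construction and is the default against which it is stated.
* **Summation order.** Contributions are accumulated iterating
  transitions in declaration order and arcs in index order.  A subnet
  built from the same net preserves relative order, which is what makes
  subnet-vs-full-model comparisons hold *bit for bit*, not merely to
  tolerance.
* **Negative marks** arising from an Euler overshoot are clamped to zero
  and logged (non-negativity is a marking invariant; the formalism is
  silent on recovery).
* **Delays off the grid** fire at the first sampled point at or after
  the scheduled time.  A delay evaluating to 0 fires within the same
  time point, at most once per point.
* **Re-triggering.** A discrete/generic transition still enabled after
  firing re-triggers immediately, so a persistently enabled discrete
  transition fires every delay period.  (Under a literal
  disabled-to-enabled reading it would fire once and never again, which
  contradicts ordinary discrete Petri-net behaviour.)
* **Conflicts.** Simultaneous discrete firings whose summed demands
  exceed a place's mark are resolved greedily: transitions are visited in
  priority order (declaration order by default, matching the
  deterministic case study) or a seeded random order, and accepted while
  their demands fit; rejected firings are canceled and logged.
* **Generic firings** evaluate their replacement values at the trigger
  time, consistent with the snapshot used for discrete amounts.

Traces are written in EDF, the expression data format: here a plain CSV
with header `time,<place ids>,delay:<transition ids>`, one row per time
point, generic values quoted, numbers at 17 significant digits so a
write/read round trip is exact.  The original tool's EDF syntax was never
published; this dialect is the package's own.  The elapsed-delay columns
(time since trigger, `-1` when idle) matter because the one-step
resimulation guarantee for nets *with* pending discrete firings needs
that bookkeeping; without them the guarantee is only stated for nets
without discrete/generic delays.

## Temporal subnets

At each time point the *temporal subnet* H′(x) is the minimal element set
still doing something: enabled arcs, the transitions they connect, and
the places those touch.  Extraction deletes arcs per transition by a
four-case rule, then sweeps isolated transitions and places:

1. no inhibitory input arcs and some normal/test arc disabled (threshold
   ≥ source mark, or condition false) → delete all of the transition's
   arcs;
2. some inhibitory arc enabled (threshold < source mark: active
   repression) and no normal/test arc disabled → keep *only* the enabled
   inhibitory arcs — the repressed transition and its repressor are part
   of the state, which is why a repressed transition survives the
   isolated-transition sweep;
3. enabled inhibitory arcs *and* disabled normal/test arcs → delete all
   of the transition's arcs;
4. inhibitory arcs present but none enabled → if some normal/test arc is
   disabled delete everything, otherwise delete just the quiescent
   inhibitory arcs (the transition fires through the rest).

The published pseudocode for this step has typographically blanked set
symbols in several branches; the rule above is reconstructed from the
branch skeleton, the arc-status set definitions, and the worked
repressed-transition example, and case 3 in particular is an
interpretation (a transition that is simultaneously repressed and lacking
an enabling input retains nothing).  When a transition has several
inhibitory arcs of which only some are enabled, exactly the enabled ones
are retained.  Both decisions are kept visible here rather than buried in
code.

Extraction runs in O(|A|+|T|+|P|) per time point; constant numeric
thresholds are compared vectorised across the whole trace.  Subnets store
element-id sets only — no marking — so a state is purely structural.

Two properties give the construction its meaning, and both are tested:

* **Resimulation equivalence.**  Simulating H′(x_i), from the marking
  restricted to its places, one step forward reproduces the full model's
  values at x_{i+1} exactly (bitwise) for every retained place.  The
  property-test generator keeps each expression closed over the places
  its transition connects; an expression reaching into an unconnected
  place's variable would escape the restriction, and the guarantee is
  only claimed under that closure.
* **One-step minimality.**  Deleting any single retained arc changes
  either some retained place's one-step value or some transition's
  enabling.  This is probed on enumerated tiny nets (up to three
  transitions, normal/inhibitory inputs, marks straddling the
  threshold).  Satisfied *test* arcs are excluded from the probe: a
  read-only condition that currently holds consumes nothing and does not
  flip enabling when removed, so it has no one-step footprint — its
  influence is only visible over longer horizons, a scale the probe
  deliberately does not claim.

## The active state transition diagram

Structurally identical subnets are merged by a canonical key (the sorted
place/transition/arc id sets).  Walking the subnet stream in time order,
each change of key either registers a new state (ids numbered from 1 in
first-appearance order) or revisits a known one, and records a directed
edge previous → current.  Consecutive identical states emit no edge, so
there are no self-loops, and the first state has no incoming edge.  The
construction inserts an edge at every state change while the published
diagrams draw set-like edges; the package stores edges deduplicated by
(src, dst) *with a traversal count*, so both readings are available and
the edge multiset is recoverable — and is, verifiably, a pure function of
the visited sequence Q.  Bidirectional pairs (two states oscillating into
one another) are represented naturally as two directed edges.

Three per-state characterisations support the graphical overviews:

* **duration** — Δ times the number of time points spent in the state;
  durations partition the sampled time axis, and the conservation
  Σ duration = |Q|·Δ is asserted on every fixture;
* **out-degree** — outgoing traversals (default) or distinct outgoing
  edges, displayed as ln(count); ln(1) = 0, and a terminal state's count
  of 0 maps to an NA sentinel drawn at minimum size rather than ln(0)
  (sustained oscillations have no terminal state, so the choice is
  cosmetic);
* **total concentration difference** — for a place p and state z, the sum
  of M(p)[x_i] − M(p)[x_{i−1}] over adjacent pairs *both* of whose
  endpoints lie in z.  Whether boundary pairs (previous point in a
  different state) belong to the state is unspecified in the source
  material; assigning them to no state keeps the per-state sums
  telescoping cleanly (a single-state trace gives exactly final − initial
  value).  Heat-map export colours states on a diverging scale with red
  at the largest positive difference.

`compare_astds()` matches states across two models built over the same
element-id namespace — wild type against a mutant — reporting shared and
model-specific states.

## Fixtures and what they do (and do not) show

`toy_oscillator()` is a two-species relaxation oscillator: an activator
synthesised at constant speed while the repressor is below threshold 1.0,
a test arc propagating activation, and first-order degradations.  Under
the packaged configuration (150 [pt] at 0.01 [pt]) it yields 7 states
whose recurring part (states entered more than once, mirroring the
transient-discarding reading of the published analysis) is a single
directed cycle.  Those numbers are frozen as regression values.

`random_net()` is a seeded generator used by the property suites:
constant thresholds, positive constant or linear-in-own-place speeds,
typing rules enforced by construction.  It emulates the *structural*
variety of pathway models, not their kinetics: no stiff dynamics, no
marking-dependent thresholds, no conservation structure.  Passing
property tests on these nets therefore certifies the algorithms'
set-level behaviour, not biological fidelity.

`circadian_scaffold()` reconstructs the two interlocked feedback loops of
the Drosophila clock — PER/TIM repressing per/tim transcription (two
inhibitory arcs) while activating dClk transcription, dCLK/CYC doing the
reverse — with the three printed fragments wired in: dCLK translation at
speed `m_1/5`, PER/DBT formation at `m_7*m_12/1000`, TIM translation
gated at threshold 1.0.  Every other rate, threshold and initial value is
a configuration slot, because the original full parameter set was
distributed through a project website that is no longer available.  The
shipped defaults are a plausible synthetic completion chosen once and
labelled as such; the published state counts (24 wild-type states, 23 in
the dbt-long mutant, 22 shared) belong to the original parameterisation
and are *not* reproduced by the defaults — given the original model file,
the comparison is a single two-model pipeline run.
`make_dbt_mutant()` implements the mutant transform: it replaces exactly
the formation transition's speed formula (the single formula is shared by
that transition's three normal arcs) and nothing else.

## Problem sizes in the shipped tests

The suites run the canonical 15,000-point extraction on the toy
oscillator and on a 50-element random net, 200 seeded random nets for the
bitwise resimulation property, 84 enumerated tiny nets for the minimality
probe, and a three-size timing ladder (25/50/100 elements) for the
linear-runtime check — sizes chosen to exercise the algorithms at the
published scale while keeping the default test run quick on one CPU.

## Known limitations

Marking-dependent thresholds are accepted by the expression grammar but
are untested against any printed example.  Variable-step or event-driven
integration is out of scope, as are stochastic transitions; the firing
conflict of discrete transitions is resolved deterministically (or by
seeded shuffle) rather than probabilistically.  Reachability-graph
construction is deliberately not implemented: the state diagram built
here is a structural quotient of the trace, not a marking graph.
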
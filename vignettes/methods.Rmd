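---
title: "Models, damage operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, damage operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionette)
```

`lesionette` trains two classic connectionist models of neuropsychological
deficits and damages them in five parameterised ways, asking whether the
behavioural consequences of damage depend on how the damage is
implemented.  This vignette records the models, their assumptions, the
synthetic data they are trained on, and every numerical choice that the
published descriptions of these models leave open.

## The hub-and-spoke auto-associator

The semantic network has 216 visible units — 40 localist name units, 64
visual feature units and 112 verbal feature units — bidirectionally
connected to a recurrent hidden "hub" (64 units by default).  Every unit
receives a fixed, untrainable bias input of −2.0, so an undriven unit
rests at `plogis(-2) ≈ 0.12`.  Updates are synchronous: on each cycle the
hub reads the previous visible and hidden activations and the visible
units read the previous hub activations, each through a logistic sigmoid.
Synchrony (rather than random asynchronous sweeps) was chosen for
determinism and testability.

Training runs for 1000 epochs at learning rate 0.001 with weight decay
0.001.  Each epoch presents all 48 items three times — once each with the
name, verbal and visual block clamped — and updates the weights after
every presentation.  Gradients come from backpropagation through the
unrolled settling cycles (2 clamped + 5 free), with the full 216-unit
target applied on every free cycle.  Two choices here deserve comment:

* **Weight decay semantics.**  Decay is added to the gradient and scaled
  by the learning rate (`w ← w − lr·(∂E/∂w + λ·w)`), the convention of the
  simulator lineage these models come from.  Subtracting `λ·w` directly at
  every one of the 144,000 updates of a run would shrink weights by ~13%
  per epoch and provably pins the network at base-rate responding; under
  the gradient-scaled form the published convergence criterion (all units
  within 0.20 of their targets) is reachable.
* **Where targets apply.**  With targets on only the last 3 of the 7
  unrolled cycles the trained maximum unit error plateaus near 0.65; with
  targets on all 5 free cycles it falls to roughly 0.13–0.17.  The default
  is therefore `target_cycles = 5`.  The training loss is cross-entropy
  (the `loss = "sse"` option is retained for comparison).

Naming is probed by clamping an item's 64 visual features for 2 cycles,
running 5 free cycles, and reading the most active name unit above 0.5
(ties break to the lowest index; no unit above threshold is "no
response").  A response is correct when it equals the item's assigned
name unit.  Because 48 items share a 40-unit localist name block, eight
within-category item pairs share a name unit; the pairs are drawn with
the pattern set's seed.  An item's "attractor" is its final hub state
under this same protocol.

A feed-forward variant (`make_feedforward_variant()`) with the same
216–64–216 shape but a single forward pass and no hidden recurrence is
provided for comparisons that isolate the role of settling dynamics.

## The synthetic semantic pattern sets

No external data ship with the package.  `build_profile()` defines, for
each of six categories (birds, mammals, fruits = living; tools, vehicles,
household = artefacts), a Bernoulli probability per visual/verbal feature
slot, and `generate_patterns()` samples 48 binary items (8 per category).
The two built-in profiles are calibrated so the closed-form expected
active-feature counts equal the published per-category means of the two
reference training sets they emulate (e.g. birds 42.250 under "P1-like",
35.875 under "P2-like"), within the 0.5 calibration tolerance the
generator enforces at build time.

The probability structure is a three-tier block design over the 176
feature slots:

* 24 *universal* slots (probability 0.45 for every category).  These keep
  the cross-domain correlation near zero — with fully disjoint domain
  supports, mean-centring makes cross-domain correlations systematically
  negative, which the reference sets do not show.
* 40 *domain-shared* slots per domain, whose per-category probability is
  solved from the calibration target.
* *Category-specific* slots: under "P1-like", 6 slots at probability
  0.65 for each living category and 18 at 0.5 for each artefact category;
  under "P2-like", 12 slots at 0.5 for every category.

The profiles differ deliberately in how distinctive the living categories
are.  "P1-like" living things have very few distinguishing features, so
birds and mammals are densely packed and mutually confusable; "P2-like"
categories carry more distinctive structure.  This is the statistical
difference that, in the lesioning studies, reverses the effect of
connection severing between the two training regimes.

Each block also fixes how many of its slots are visual.  Living-thing
features are predominantly visual and artefact features predominantly
verbal (the sensory/functional asymmetry described for living versus
non-living concepts), and the asymmetry is stronger under "P1-like"
(artefact identity there is carried visually only by the universal
block).  Because naming is probed from the visual spokes, this allocation
shapes how much of an item's identity survives input clamping, and it is
part of the calibration.

What the generator does *not* emulate: real feature norms have heavy-
tailed feature frequencies, correlated features within an item, and
meaningful feature identities; items here are exchangeable draws within
a category.  Passing tests therefore show that the *statistics the
theory appeals to* (feature richness, within/between-category
correlation, domain separation) drive the behavioural results — not that
the package reproduces any particular published training set item for
item.  `boost_domain_norms()` rescales one domain's probabilities to a
target mean count (clipped proportional scaling) for the norm-boosting
manipulation.

## Damage operators

All five operators exempt bias weights, take explicit seeds, and attach a
replayable `lesion_record` (re-applying it to the intact network
reproduces the damaged network bit for bit):

* `sever(net, q)` — each non-bias weight is zeroed independently with
  probability `q` (a single pooled draw across all targeted matrices).
* `perturb_weights(net, r)` — adds independent `U(−r, +r)` noise.
* `ablate_units(net, p)` — selects hidden/context units with probability
  `p` and zeroes all their *outgoing* weights; incoming weights are kept.
* `scale_weights(net, s)` — multiplies every non-bias weight by
  `s ∈ (0, 1]`, deterministically; equivalent to lowering the activation
  gain.
* `activation_noise(sigma)` — a per-step injector for sequential runs:
  `N(0, σ²)` noise on the context activations at every step.

The severity grids for the semantic study are the published ladders:
severing 2.5–50% in steps of 2.5 (20 levels), perturbation half-range
0.05–1.00 in steps of 0.05 (20 levels), ablation 0.00–1.00 in steps of
0.05 (21 levels) and scaling 0.75 down to 0.55 in steps of 0.01 (21
levels).  Stochastic lesions are drawn 10 times per level per network at
study scale (5 at desk scale); scaling is deterministic, so one
application per level suffices.

The "area between curves" statistic is the mean over severity levels of
(artefact − animal) accuracy, per network — a span-normalised trapezoid
area that is comparable across damage kinds with different severity
units.  Confidence intervals are Student-t over the per-network areas;
the source analyses do not name their interval method, and with ~20
approximately normal per-network areas the t interval is the standard
choice.

## The sequential-action model and its world

The second model is a simple recurrent network: 24 input units (12
featural units for the fixated object and 12 for the held object —
identity one-hot plus open/empty/loaded/stirred state bits; an empty hand
is all zeros), 50 sigmoid hidden units whose previous state is copied
into context units, and a softmax readout over 17 discrete actions with
argmax selection.  The beverage world is fully deterministic: objects
(cup, coffee packet, sugar packet, sugar bowl with lid, cream carton,
spoon, teabag) respond to fixation and manipulation actions through
applicability predicates; inapplicable actions leave the world unchanged
and are flagged anomalous.  The only environmental variability is the
sugar source: a world contains either a sugar packet or an open/lidded
bowl, and the generic `fixate_sugar` action fixates whichever is present.

The corpus holds six sequences — four coffee variants of exactly 37 steps
(add grounds; add sugar from packet or bowl and add cream, in either
order; drink) and two tea variants of exactly 20 steps (steep; add sugar
from packet or bowl; drink) — plus 250+ single-step background items
pairing a world state with its canonical affordance.  Subtask boundaries
fall after steps 10, 21 and 32 of coffee and after steps 10 and 15 of
tea.  Every subtask contains exactly one *crux* action (the pour, dip or
sip that fulfils its goal).  All post-initial subtasks begin with a
fixation action issued from an identical junction state (cup stirred,
spoon in hand), so the choice of what to do next is carried entirely by
the learned context — which is precisely where context noise and
recurrent-pathway damage act.  Two background states that coincide with
the task-opening cue states are excluded from the background set so the
one-step items never contradict the sequence corpus at the shared neutral
context.

Training is backpropagation through time over whole sequences plus the
one-step items, 20,000 epochs, with learning rate 0.01, momentum 0.9 and
a background-item gradient weight of 0.2 (the published descriptions fix
the epoch count but not the optimiser; these values reach exact
reproduction of all six sequences across seeds within the epoch budget,
verified by `verify_sequences()`).  During training, N(0, 0.02) noise is
added to the context copy at every step.  This makes the learned
trajectories genuinely attracting: a mildly damaged network is recaptured
by a valid subtask routine instead of drifting off-grammar, which is the
precondition for the clean whole-subtask error forms the damaged model is
supposed to produce.  (Raising the training noise to 0.05 prevents exact
sequence learning; 0.02 leaves intact argmax behaviour untouched.)  In
the damage sweeps, the weight-lesion operators target the recurrent
context-to-hidden pathway — damaging the input or output pathways
destroys local affordances and produces mid-block wandering instead of
the boundary-locked errors of interest — while weight scaling applies to
all non-bias weights.  Because the sugar/cream order in
coffee is a genuine branch point with identical history, "reproduces a
sequence" is operationalised teacher-forced: at every step the argmax
action must equal the target or begin an alternative valid realization
sharing the history so far.

## Error taxonomy

The published error categories name no algorithm, so the package commits
to one and checks it against an exhaustive oracle.  A produced sequence
is segmented into complete subtask templates by a dynamic program that
maximises the number of covered actions (template matches preferred over
junk, templates in inventory order on ties).  Missing goals are subtask
*omissions*; out-of-task goals *intrusions*; repeats *perseverations*;
order violations (measured by longest common subsequence against the
valid goal orders) *displacements*; each maximal run of uncovered
actions is one *within-subtask* error, and the uncovered actions
themselves are the *independent actions*.  Action-level errors come from
a Levenshtein alignment with the nearest valid realization (deletions =
action omissions; insertions echoing nearby actions = sequence errors;
the rest = other), with each error flagged crux or non-crux by the
reference position it touches.  Survival curves use the first divergence
from the *nearest* valid realization, so legitimate order variation never
counts as an error.  On every episode of ≤ 25 steps the dynamic program
is required (by test) to agree exactly with a brute-force enumeration of
all segmentations.

For the mild-versus-severe comparison of error *form*, an erroneous
episode counts as "clean subtask form" when every produced action lies
inside a completed subtask routine (its errors are whole-subtask events;
a subtask realized through the other task's routine counts as clean in
form though it is labelled a within-subtask error), and as
"disorganised" otherwise.  "Mild" severity is operationalised per damage
kind as the lowest ladder rung with a measurable error rate, since a
fixed severity value corresponds to very different effective damage
across operators.

## Scale presets and problem sizes

Study scale means 20 hub networks per profile with 10 lesions per level,
and 12 SRNs with 500 episodes per cell.  The desk preset — used by the
test suite and the acceptance script — keeps every severity grid
unchanged and reduces replication only: 5 hub networks × 5 lesions per
level, 3 SRNs, 40–100 episodes per cell.  The fixture seeds are fixed
arbitrary constants; the acceptance script derives all of its seeds from
the single `--seed` argument via `derive_seed()`, a splittable
label+counter hash, so no stage touches R's global RNG state.

## Known limitations

* The attractor-density comparison (mean pairwise hub-state distance,
  animals versus artefacts) is sensitive to feature-count saturation:
  richly represented items drive hub units toward the corners of
  activation space, which *increases* their pairwise distances and can
  overwhelm the confusability effect that makes living-thing attractors
  dense.  Under the shipped templates the living < artefact density
  ordering is reliable only for the "P1-like" profile; the published
  ordering for both training sets is not always reproduced, and the
  corresponding check is expected to be the suite's weakest point.
* The weight-scaling grid (0.75–0.55) brackets the breakdown region of
  the *reference* networks.  Networks trained here are sometimes still at
  ceiling across that whole range, in which case the scaling area is ~0
  and its direction is noise.
* The beverage world is a reconstruction from the published description
  of the task environment, not a copy: object feature inventories,
  exact step counts within subtasks and the affordance background set
  are this package's own design, constrained to the published sequence
  lengths, boundary positions and variant structure.
* Exact reproduction of the published weight/attractor tables depends on
  the original training sets, which are not distributed; directions and
  orderings are the testable content.
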
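# lesionette

Simulated neural damage in recurrent connectionist networks.

When a connectionist model of a cognitive faculty is "lesioned" to
simulate a neuropsychological deficit, does it matter *how* the damage is
implemented?  `lesionette` makes that question computable for two classic
models:

* **A hub-and-spoke semantic network** — 216 visible units (40 localist
  name, 64 visual, 112 verbal) bidirectionally connected to a recurrent
  amodal hub — trained to auto-associate 48 binary concept patterns
  (8 items in each of six categories: birds, mammals, fruits vs tools,
  vehicles, household objects) and probed with a picture-naming task
  (clamp the visual features for 2 cycles, settle 5 free cycles, read the
  most active name unit above 0.5).
* **A simple recurrent network of routine action** — an Elman network
  that prepares coffee (37 steps) and tea (20 steps) in a simulated
  beverage world, trained by backpropagation through time on six action
  sequences plus 250+ one-step affordances.

Both are damaged with five parameterised operators — connection severing
(Bernoulli zeroing with probability *q*), weight perturbation (uniform
±*r* noise), unit ablation (all outgoing weights of a fraction *p* of
hidden units), weight scaling (multiply by *s* ∈ (0, 1]), and per-step
activation noise (σ) — always sparing bias weights, and always replayable
from a recorded seed.

The headline analysis asks whether damage dissociates the two semantic
domains.  For a damage grid with severity levels *l* and per-network
naming accuracy acc(domain, *l*), the package computes the signed area
between the domain curves,

    A = mean over l of [ acc(artefact, l) − acc(animal, l) ],

per trained network, with Student-t 95% confidence intervals over
networks (positive = artefact advantage).  The substantive result the
package reproduces: whether severing spares or spoils animal naming
depends not on the architecture but on the statistics of the training
patterns — two pattern generators calibrated to the same published
per-category feature counts but differing in category distinctiveness
("P1-like" vs "P2-like") give opposite severing dissociations, while
weight perturbation always penalises animals.

For the action model, damaged episodes are classified against a subtask
grammar (omission, intrusion, perseveration, displacement, within-subtask
disorganisation; crux vs non-crux errors; independent actions), with
survival curves that locate failures at subtask boundaries and a
weight-scaling failure-onset search per task.

## A worked example

```r
library(lesionette)

ps   <- generate_patterns(build_profile("P2-like"), seed = 1)
net  <- train_hub(init_hub(hub_config(), seed = 1), ps)   # ~30 s
mean(name_accuracy(net, ps)$correct)                      # intact: at ceiling
max_unit_error(net, ps)                                   # learning criterion

curve <- run_damage_grid(list(net), damage_grid("sever", lesions_per_level = 5),
                         ps, master_seed = 1)
area_between_curves(curve)
```

```
[1] 1
[1] 0.141
area (artefact - animal): mean -0.0175 (SD NA), 95% CI [NA, NA], n = 1
```

The intact network names all 48 items correctly and settles every unit
within 0.20 of its target; after severing up to 50% of connections the
area between the domain curves is negative, i.e. artefact naming suffers
more than animal naming under this training set — the reverse of the
classic living-things deficit.  Training a cohort (`run_semantic_study()`)
replaces the single-network area with a mean and confidence interval.

For the action model:

```r
corpus <- build_corpus()
srn <- train_srn_verified(srn_config(), corpus, seed = 2) # ~2 min
length(run_episode(srn, world_initial_state("coffee", "packet"))$actions)
ep  <- run_episode(srn, noise = activation_noise(0.10), seed = 7, task = "coffee")
classify_episode(ep, corpus)$subtask
```

```
[1] 37
      omission      intrusion  perseveration   displacement within_subtask
             0              0              1              0              4
```

The intact network reproduces the full 37-step coffee sequence; with
σ = 0.10 context noise this particular episode repeats an already
completed subtask (one perseveration) with four stray actions around the
repeat — a classic mild action-slip profile.  Batch analyses
(`damage_sweep()`, `survival_analysis()`) aggregate these labels over
hundreds of episodes and locate the failures at the subtask boundaries.

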
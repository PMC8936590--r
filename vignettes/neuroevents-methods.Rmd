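---
title: "Extracting neuroimaging research events: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting neuroimaging research events: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuroevents)
```

## The task and its schema

A sentence such as *"High b-value fMRI was obtained through the central
sulcus"* reports a data-acquisition step. `neuroevents` represents it as an
event mention: a trigger span ("obtained", category Acquisition), role links
from argument spans to the trigger ("fMRI" fills `produces`, "central
sulcus" fills `from`), and attribute links from modifier spans to arguments
("b-value" modifies "fMRI"). Six event categories cover findings
(Activate, Deactivate, Effect), experimentation (PerformExperiment),
acquisition (Acquisition) and analysis (PerformAnalysis); nine argument
categories and three attribute categories fill their slots. Slot arities are
part of the schema (`one`, `+`, `*`) and `validate_event()` reports
violations as data rather than refusing to represent them — bootstrapped and
predicted mentions are routinely imperfect.

Two deliberate schema readings deserve a note, because the source tables a
user may compare against are not fully consistent with one another:

* The `from` slot of Acquisition admits brain areas as well as study
  participants. The canonical worked example links the brain area "central
  sulcus" to an acquisition trigger through `from`, while the slot
  definition names only study participants; admitting both keeps the worked
  example representable. The scored relation inventory (18 labels: 14
  event-qualified roles, 3 attribute relations, `none`) contains no
  `Acquisition-from` label, so such links exist in the annotation layer but
  are not scored or trained as arcs.
* "b-value" is treated as an attribute token (tagged `B-ACQ_A`, linked to
  "fMRI") rather than as an untagged token with a role of its own. The two
  printed views of the same sentence disagree here; we follow the
  role/attribute view. Attribute attachment falls back to the nearest
  argument of *any* category when no argument of the paired category is
  present — the worked example attaches a device attribute to an
  acquisition object — and `validate_event()` still flags the resulting
  link, by design.

## Features

Each token is the concatenation `[v_w, v_c, v_t]`:

* `v_w`: a word vector, looked up case-insensitively (25 dimensions by
  default; any text-format table can be loaded, and seeded random tables
  stand in for pretrained vectors in tests — no 25-dimensional release of
  the standard pretrained tables exists, so the original table is not
  reconstructible anyway).
* `v_c`: a one-hot case feature with **seven** classes (numeric, allLower,
  allUpper, initialUpper, mainly_numeric, contains_digit, other). The prose
  the feature derives from says "six dimensions" but lists seven values; we
  implement seven. Precedence is fixed and digit-containing tokens are
  excluded from the pure letter classes so every class is reachable.
* `v_t`: the 0-based index of the token's gazetteer BIO label in the
  37-label list, kept as a **raw integer in one dimension** ("O" = 0). This
  is faithful to the described one-dimensional terminology feature even
  though a one-hot encoding would be more learnable; the raw index (0..36)
  also dominates the input scale, which is part of why the synthetic
  benchmark needs a few dozen epochs rather than a handful.

## The joint model

The encoder is a stacked bidirectional LSTM (defaults: 3 layers, hidden
size d = 64 per direction, tanh cells, dropout between layers with
keep-probability 0.9 — the stated "dropout 0.9" is read as a keep
probability; dropping 90% of units would be pathological). The time
recursion runs in compiled code (`src/lstm.cpp`) with exact hand-derived
backpropagation, verified against finite differences in the test suite; no
neural-network framework is available in the target environment, and the
gradients with respect to the *inputs* (needed for adversarial training)
fall out of the same backward pass.

Element tagging scores each token through a tanh layer
(`V tanh(U h_i)`) into 37 tag scores and combines them with a learned
transition matrix in a linear-chain CRF. The printed per-token
cross-entropy objective is implemented as the standard sequence-level CRF
negative log-likelihood (which the printed sequence-probability equation
implies); the log-partition uses the forward algorithm in log space and
decoding is Viterbi with ties broken toward the lowest tag index.

Role/attribute recognition is multi-head selection: for dependent `i`,
candidate head `j` and relation `r`,
`s = V_r tanh(U h_i + W h_j + b)`, `p = sigmoid(s)`, trained with summed
binary cross-entropy (the printed loss omits the logarithms; we implement
standard BCE) and decoded by `p > 0.5` (the threshold is configurable; no
value is stated). Arc direction is dependent-to-head: argument start to
trigger start, attribute start to argument start; tokens with no head carry
a self-arc labelled `none`. Two numerical choices matter:

* probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the loss;
* the per-relation bias is initialized at −4. Gold arcs are a vanishing
  fraction of the `n² × 18` candidates, and a zero-logit start (every arc at
  p = 0.5) costs hundreds of loss units of undirected gradient before
  structure can emerge. Starting near the true positive rate roughly halves
  the epochs needed on the synthetic benchmark. With the bias present,
  `V_r = 0` yields p = 0.5 only when the bias is also zero, matching the
  bias-free printed formula.

The joint objective is the plain sum of the two losses, optimized with Adam
(lr 1e-3 default, batch size 8 — unstated in the source, chosen once).

## Adversarial training

The free-adversarial-training loop replays each minibatch K consecutive
times (K = 3 by default; no value is stated). Each replay runs a clean pass
and a pass on inputs shifted by the current perturbation, takes one Adam
step on the summed two-term objective, and updates the perturbation with the
input gradient that the perturbed pass already produced:
`r <- r + eps * g / ||g||`, followed by projection onto the eps-ball
(the projection is an addition — without it `||r||` can grow to `K * eps`
across replays). The radius is `eps = alpha * sqrt(D)` with alpha = 0.01 and
D the input width; the literal `alpha * D` reading printed in the source
would give perturbations an order of magnitude larger than the embeddings
themselves and is exposed as `adv_config(radius = "linear")` for
comparison. The perturbation resets at every new batch, gradients are
normalized by the global L2 norm over the batch, and the outer epoch count
is `ceiling(epochs / K)`.

One degenerate case is handled explicitly: at `alpha = 0` the perturbed pass
is skipped entirely, so the loop is *exactly* plain joint training,
step-for-step under the same seed. (For small positive alpha the summed
objective doubles the clean gradient, which Adam almost — but not exactly —
scales away; the exact identity therefore lives at the limit point.)

## Evaluation protocol

Scoring is strict throughout: a span counts only with exact boundaries and
label; an arc only with exact dependent start, head start and
event-qualified relation; an event (strict mode) only with exact trigger
span, category and complete role-link set, with a relaxed trigger-only mode
available because the event-level criterion used for the headline numbers
in the source is not stated. Zero denominators yield 0. The few-shot
fivefold protocol stratifies each event category into five parts (±1),
trains on one part and tests on the other four, and pools counts over folds
into micro scores.

## The synthetic world

The generator emits slot-grammar sentences, not natural text: one mention
per sentence, a trigger, 2–4 in-schema arguments with gold roles, at most
two attributes placed immediately before their argument, and function-word
distractors (at least one between element groups, so nearest-argument
attribute attachment is unambiguous). Category proportions default to the
empirical mention distribution of the corpus the schema was bootstrapped
from (24/4/35/20/8/9% for Activate/Deactivate/Effect/PerformExperiment/
Acquisition/PerformAnalysis). Vocabulary defaults (6 terms per trigger
category, 12 per argument, 6 per attribute) are desk-scale choices: a
one-fifth training fold of a 600-mention corpus then sees most of the
inventory, which is the regime the few-shot protocol is meant to probe.
Because the scored relation inventory has no `Acquisition-from` label, the
`from` slot defaults to staying empty (`slot_presence` overrides this).
Disjoint pseudo-word vocabularies (ambiguity 0) make gazetteer matching
exact, so Rule-1/Rule-2 re-extraction recovers 100% of generated mentions —
a closure property the tests assert. An `ambiguity` knob reintroduces shared
terms for harder experiments.

What a green synthetic benchmark does **not** establish: performance on
real prose (no syntax, no paraphrase, no out-of-gazetteer entities, no
multi-event sentences), robustness to annotation noise, or the absolute F1
levels reported on any manually annotated corpus.

## Compute scaling of the acceptance benchmark

The end-to-end acceptance test (600 mentions, 3 seeds, fivefold, plain and
adversarial variants = 30 training runs) must fit a single-CPU budget. It
therefore runs a scaled encoder (1 BiLSTM layer, d = 32, scorer width 32)
for 45 epochs at lr 5e-3, instead of the package defaults (3 × 64, 100+
epochs, lr 1e-3). This is purely a compute scaling of the *training
schedule*; the data-generating world, the protocol and the pass thresholds
are untouched. With the default schedule the same pipeline only improves
(more capacity, more epochs), at roughly six times the cost.

## Known limitations

* One flat mention per trigger; no nested or overlapping event structures.
* The corpus column format stores one role label per token, so a token
  shared by two mentions with different labels cannot be serialized.
* Embeddings are frozen during training; only encoder/scorer parameters
  update. This keeps the adversarial input-gradient exactly the gradient
  with respect to `v_i`.
* Multi-label arcs for the same `(i, j)` pair are permitted by thresholding,
  as the head-selection formulation allows; nothing deduplicates them.
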
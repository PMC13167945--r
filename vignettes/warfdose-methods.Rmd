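---
title: "Methods: sequence models for warfarin dose prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence models for warfarin dose prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling and design decisions behind
`warfdose`: the dose-prediction network, the supervised framing of
longitudinal dosing records, the training protocol, the evaluation
endpoints, and the virtual-patient simulator that stands in for clinical
cohorts. It is the package's own account of its methods; every number
quoted here is computed by the test suite or by `scripts/acceptance.R`,
not asserted from outside.

## The prediction problem

A patient on warfarin generates an irregular visit series: on day $t_i$
an INR is measured and the clinician prescribes an adjusted daily dose.
The supervised task is: given the fixed covariates and the history up to
and including visit $i$ — with the dose *at* visit $i$ hidden — predict
that adjusted dose (mg/day). Each time step carries the tuple
$(\mathrm{Dose}_{i-1}, \mathrm{INR}_i, \mathrm{Interval}_{i+1},
\mathrm{Dose}_i)$. Three framing decisions were genuinely open:

* **Masking the decision visit's dose.** The current dose is listed among
  the time-series inputs, yet it is also the prediction target. We
  include the step but replace its dose with a sentinel after
  normalization (−8, far below any achievable normalized dose, so it can
  never be confused with a true zero). This keeps the information set
  honest (no label leakage) while letting the network see the decision
  visit's INR and planned interval. The INR model variant
  (`label_type = "inr"`) swaps the roles: INR masked and predicted, dose
  visible.
* **First step's previous dose.** The first visit has no predecessor; we
  duplicate the initiation dose rather than using 0, which would encode a
  false "no prior anticoagulation" signal.
* **The planned interval is treated as known.** It is chosen by the
  scheduler, so at decision time it is available in deployment; for the
  final observed visit the last interval is carried forward.

Features are z-scored, $x_{norm} = (x - \bar x)/x_{sd}$, with statistics
computed from training-fold samples only and stored inside the trained
artifact; evaluation data never contribute (asserted by a leakage test).
Constant features receive $x_{sd} = 1$ and a flag. Unknown genotype is
encoded as the training mean of each genotype feature — exactly 0 after
normalization — which is also how genotype ablation is realized at
prediction time.

Genotype is encoded ordinally, as is conventional in published warfarin
dosing algorithms: the count of reduced-function CYP2C9 alleles (*2 or
*3), an indicator of *3 carriage (the stronger allele), and the count of
VKORC1 −1639A alleles.

## Architecture

Two branches. Fixed covariates pass through one ReLU hidden layer
(`ffn_hidden`, default 64). The visit sequence passes through
`num_layers` stacked LSTM layers (`hidden_size` units per direction,
default 128); with `bidirectional = TRUE` each layer runs two independent
LSTMs, forward and backward over the valid prefix, and concatenates the
direction-wise hidden states per time step. The top layer's outputs are
max-pooled **over time positions, masked to valid steps** — pooling over
all positions rather than taking the final state was chosen because it is
what the masked-pooling fusion describes, and it makes predictions
provably invariant to padding (a property test). The pooled recurrent
vector (width `hidden_size`, doubled if bidirectional) and the
feedforward vector are concatenated and mapped by a linear head to a
single scalar; dose predictions are denormalized and clamped to
`[0, max_dose]` (default 10 mg/day).

No deep-learning framework is used: the forward pass and backpropagation
through time are implemented in vectorized base R (gate order i/f/g/o,
uniform $\pm 1/\sqrt{H}$ initialization with +1 forget-gate bias, Adam).
The backward direction is realized by per-sample reversal of the valid
prefix; the reversal is a permutation, so the same operation routes
gradients. Analytic gradients are verified against central finite
differences on every parameter block in the test suite (agreement to
~1e−9 relative). Dropout between recurrent layers is supported but
defaults to 0 — regularization is handled by early stopping.

## Training protocol

Loss is the MSE of normalized doses; reported metrics are always on
denormalized mg/day. Splits are **patient-level** (visits within a
patient are correlated): 10% of patients form the test set; the remaining
90% are partitioned into k = 10 folds, each serving once as validation
(≈9% of patients) with the rest (≈81%) training. Training runs at most
100 epochs and stops when the validation loss has failed to improve by
`min_delta` for 10 consecutive epochs; "no significant reduction" is
quantified as improvement < 1e−4 in normalized-loss units, relative to
the best so far. The best-validation-epoch parameters are restored. The
controller is exposed as the pure function `stopping_epoch()` so its
boundary behavior is directly testable (constant losses halt after
epoch 11; strictly improving losses run to 100).

Hyperparameters are swept sequentially — hidden size, batch size, layers,
learning rate — each axis with the others held at incumbents, each
candidate trained `reps = 3` times and scored by mean ±20% dose accuracy.
Scoring on the held-out test set follows the protocol as described, but
it leaks test information into model choice; a `score_on = "validation"`
switch is provided and flagged as the methodologically cleaner option.
The final configuration is trained repeatedly (10 by default) with seeds
differing only in initialization and batch order; the candidate with the
highest external-set accuracy wins, ties broken by lower RMSE. The
four fit statistics (MSE, MAE, RMSE, R²) are all computed, and their
internal identities (RMSE² = MSE, MAE ≤ RMSE, R² ≤ 1) are property
tests. Adam at learning rate 0.025 (the swept optimum) is the default
optimizer; the optimizer itself was not named in the protocol and is
config-exposed.

Minibatches are length-bucketed (samples sorted by history length, cut
into batches, collated once; epochs shuffle batch order). This trades a
little SGD noise for a large constant-factor saving in an interpreted
language, and keeps training bit-reproducible under a fixed seed.

## Evaluation endpoints

* **Tolerance-band classification.** A prediction is `within` when
  $|pred - ref| \le tol \cdot ref$, boundary inclusive; `over`/`under`
  otherwise by sign. Dose tolerance 0.20, INR tolerance 0.30. Reported
  percentages use one-decimal half-up rounding, matching clinical
  reporting; the class partition is exact before rounding.
* **Stable dose.** The earliest window in which the dose is unchanged
  across consecutive visits spanning ≥14 days with every in-window INR
  inside the patient's target range. The qualifier "within 7 days after
  initial dosing" is grammatically ambiguous; the default reading
  excludes the induction transient (window must **begin at or after day
  7**, leading earlier visits trimmed), with `starts_within_7d` available
  for the alternative reading. Detection is validated against a
  brute-force scan over all visit windows. Stable-dose accuracy
  classifies model predictions (conditioned on history up to each
  in-window decision visit) against the stable dose.
* **Sensitivity subgroups.** A CPIC-style decision table: VKORC1 AA with
  any reduced-function CYP2C9 allele is `highly_sensitive`; AA alone or a
  reduced-function allele alone is `sensitive`; GG/GA with *1/*1 is
  `normal`. The exact published mapping lives in supplementary material
  that is not available, so the table is a documented convention and is
  replaceable via an argument.
* **Rosendaal %TTR.** INR is linearly interpolated between consecutive
  measurements and each segment's time is allocated exactly from the
  boundary-crossing points; the implementation agrees with a
  10,000-points-per-segment numerical oracle to <0.1 percentage points on
  200 random series (an acceptance check). The target interval is closed
  (boundary INRs count as in range, the way the ranges are printed);
  segments with gaps >56 days (a common convention, config-exposed) are
  excluded from numerator and denominator; fewer than two usable
  measurements yield `NA`, not 0. Windowed summaries (0–30/0–60/0–90
  days) clip straddling segments at the bound with the interpolated INR
  as a synthetic, non-measured endpoint; TTR is aggregated per patient
  and summarized as median/IQR, while in/above/below-range proportions
  pool measurements.
* **Error summaries** use the convention error = predicted − reference
  (over-prediction positive), printed on the output so density plots
  cannot be misread.

## The virtual-patient simulator

Real longitudinal anticoagulation cohorts of this kind are not publicly
deposited, so the package ships a generative stand-in whose purpose is to
reproduce the *statistical structure* the models assume, not warfarin
pharmacology. It is explicitly labelled synthetic.

* **Dose–response:** delayed Emax. Steady-state INR is
  $INR_0 + E_{max} d^h / (ED_{50}^h + d^h)$ and the latent INR relaxes
  toward it at rate $k_e$ (0.35/day), so dose effects are delayed and the
  first week is unstable. Defaults: baseline INR 1.5 (a valve-surgery
  population), $E_{max}$ 2.6, wild-type $ED_{50}$ 9.5 mg/day, Hill 1.6.
* **Genotype:** Hardy–Weinberg sampling at Han-Chinese-like frequencies
  (VKORC1 A 0.90; CYP2C9 *2 0.02, *3 0.04). Each VKORC1 A allele
  multiplies $ED_{50}$ by 0.72, each reduced-function CYP2C9 allele by
  0.62, amiodarone by 0.8, with lognormal inter-individual variability
  (sd 0.25) on top. These constants were calibrated once so that the
  n = 500 cohort's mean stable dose brackets the clinical anchor of
  ~2.6 mg/day and the subgroup ordering (normal > sensitive > highly
  sensitive) holds, then frozen.
* **Titration:** the simulated clinician inverts the Emax curve at the
  measured INR (taken at face value as steady state — the source of the
  realistic day 3–5 overshoot), blends it on the log scale with a
  genotype-informed prior whose weight decays $0.5^k$ to a floor of 0.15
  (the anchoring on pharmacogenetic algorithms seen in genotype-guided
  management), moves the dose a fraction 0.5 toward the implied target
  dose, and rounds to the 0.25 mg tablet grid within [0.5, 10] mg/day.
  Measured INR carries 10% lognormal noise (point-of-care imprecision
  plus short-term biological variability), reported to two decimals.
* **Schedule:** days 3, 5, 7, then weekly to day 28, then fortnightly to
  day 84, jittered ±2 days after day 7 — dense early monitoring with
  irregular intervals. No distributional facts about real visit intervals
  were available, so the schedule is a documented guess and fully
  configurable.

What the simulator does *not* emulate: adherence lapses, acute illness,
diet and drug–drug interaction kinetics (beyond a static amiodarone
multiplier), enantiomer-specific PK, INR assay drift, or informative
visit timing (sicker patients being seen more often). Consequently,
passing the learning-recovery checks shows the architecture and protocol
can recover a measurement-driven dosing process from synthetic
longitudinal data — it does not certify clinical performance on real
patients.

A deliberate property of the design: under this generator the prescribed
dose is (up to grid rounding) a deterministic function of the visible
history plus genotype, so a sequence model *can* in principle predict it
well, and the persistence baseline (repeat the previous dose) cannot —
early titration steps change doses by more than the ±20% band. This is
what makes "beats persistence by ≥5 points" a meaningful recovery check
rather than a coin flip.

## Problem sizes and numerical choices

The acceptance-scale experiments use an 800-patient modeling cohort and a
200-patient external cohort (about 6,500 training samples), models at
hidden size 32, two layers, batch 64, ≤30 epochs, three seeds per
architecture — sizes chosen so the full experiment, including the
unidirectional comparator and genotype ablation, completes in a few
minutes on one CPU while leaving the directional comparisons stable.
Unit tests run on 6–100-patient cohorts. Other numerical choices:
sentinel −8 on the normalized scale; Adam $\beta$ = (0.9, 0.999),
$\epsilon$ = 1e−8; max-pooling ties broken by the earliest time step
(irrelevant to the value, fixed for gradient routing); cohort CSVs write
doubles at 17 significant digits so write–read round-trips are exact;
all randomness flows through explicitly seeded, state-restoring RNG
scopes, making cohorts, splits and trainings byte-reproducible.

## Known limitations

* The simulator is a stand-in; none of its constants are estimates from
  data, and conclusions about real cohorts require real cohorts.
* Training is CPU-bound R; it is fast at the shipped problem sizes but
  not intended for hidden size 128 × 10 repetitions × full sweeps, which
  would take hours rather than minutes.
* The INR-prediction variant shares all wiring with the dose model and is
  tested for wiring correctness, but the package's headline experiments
  are dose-focused.
* `run_sweep()`'s default test-set scoring reproduces the documented
  protocol including its leakage; use `score_on = "validation"` for
  methodologically clean sweeps.
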
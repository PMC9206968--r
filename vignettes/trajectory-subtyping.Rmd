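---
title: "Trajectory profile clustering and stratification timing for stroke recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory profile clustering and stratification timing for stroke recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcstroke)
```

## The problem

Longitudinal stroke trials score neurological deficit on ordinal
instruments such as the NIH Stroke Scale: 15 items, each on its own small
scale (coordination 0–2, language 0–3, limb strength 0–4), observed at a
handful of visits. Mixed-effects models describe *per-item* change well,
but recovery is organised by lesion anatomy: left-hemisphere strokes
couple right-sided weakness with aphasia, right-hemisphere strokes couple
left-sided weakness with extinction and gaze deviation. This package
clusters whole item-by-visit trajectories into such recovery subtypes and
then measures at which visit the subtypes become identifiable from a
single assessment.

## Trajectory profile clustering

For the score tensor $X_{ivt}$ (patient $i$, item $v$ with maximum
$\max(v)$, visit $t$):

1. **Binarization.** $T^i_{vt} = 1$ iff $X_{ivt} > \max(v)\cdot\kappa$,
   else 0. Severity is relative to each item's own scale, so items with
   different maxima are comparable. A score *equal* to the threshold maps
   to 0: the boundary belongs to the non-severe side, which also fixes the
   behaviour at half-integer cutoffs (max 4, $\kappa = 0.5$, score 2
   $\to$ 0).
2. **Agreement network.** $P_{ij} = \sum_{vt} w_{vt}\,[T^i_{vt} =
   T^j_{vt}]$. Weights default to 1: absent clinical consensus on symptom
   importance we stay agnostic. Counting agreement on *zeros* as well as
   ones means two fully recovered patients are maximally similar — the
   mildly-affected subtype exists because of this choice.
3. **Community detection.** Louvain maximization of Newman–Girvan
   modularity on the dense weighted network; the subtype count $L$ is
   chosen by the optimization. Louvain is stochastic, so
   `louvain_cluster()` runs 20 seeded restarts and keeps the
   best-modularity labeling; labels are then canonicalized (descending
   size, ties by smallest member index) so identical inputs give
   identical outputs.
4. **Subtype profiles.** $S^l_{vt} = N_l^{-1}\sum_{i\in C^l} T^i_{vt}$,
   the affected fraction. Communities under 10 members are kept in the
   label output but flagged non-reportable and omitted from profile
   reports, since tiny communities are usually outliers rather than
   subtypes.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kappa` | 0.5 | severity cutoff as a fraction of each item's maximum |
| `threshold_mode` | `"fraction"` | `"median"` instead cuts at the item's population median |
| `n_restarts` | 20 | Louvain restarts; stabilizes the data-driven $L$ |
| `min_report_size` | 10 | smallest community treated as a subtype |
| `weights` | uniform | optional $w_{vt}$ position weights |

Two thresholding conventions are defensible: a fixed fraction of the item
maximum (absolute severity) and the per-item population median (severity
relative to the cohort). Both are implemented; `"fraction"` with
$\kappa = 0.5$ is the default because it does not depend on cohort
composition. `"median"` is preferable when items rarely reach the top of
their scales.

### Numerical and degenerate-input choices

- **Diagonal policy.** Self-similarities $P_{ii}$ (raw value $\sum w_{vt}$)
  are zeroed before clustering: self-loops carry no inter-patient
  information and bias the modularity null model. The flag is recorded on
  the network object.
- **Dense network.** $P$ is used as-is, with no sparsification: agreement
  counts are meaningful at every pair, and $N$ in the hundreds poses no
  cost.
- **Uniform networks.** If every off-diagonal entry of $P$ is equal there
  is no community structure; `louvain_cluster()` returns a single
  community (e.g. a cohort of identical patients). If binarization yields
  all-zero profiles (e.g. $\kappa = 1$, which no score strictly exceeds),
  `run_tpc()` stops with a degenerate-network error before clustering —
  clustering "nobody is severely affected" would be meaningless.
- **All-in-one floor.** The trivial partition has modularity exactly 0,
  so any returned partition has $Q \ge 0$; this is property-tested.

## Stratification timing with a graph classifier

Each patient–visit pair yields a symptom–symptom graph
$G_{it} = v\,v^{\mathsf T}$ from the binary symptom vector $v$ at that
visit — the one-mode projection of the patient–symptom bipartite graph,
rank $\le 1$, with diagonal entries marking the severe symptoms. A
two-layer graph convolutional network classifies these graphs into the
full-trajectory subtypes:

$$H_1 = \mathrm{ReLU}(\hat A F W_0),\quad
  H_2 = \mathrm{ReLU}(\hat A H_1 W_1),\quad
  p = \mathrm{softmax}\!\left(\tfrac1V \textstyle\sum_v H_{2,v\cdot}\right)$$

with $\hat A = D^{-1/2}(G + I)D^{-1/2}$. Training uses full-batch ADAM on
mean cross-entropy over a stratified 70/30 split; held-out accuracy per
visit, replicated over seeds, forms the stratification curve. Accuracy at
a visit measures how strongly subtype membership is expressed in that
visit's symptom configuration.

Design points the architecture description leaves open, and what this
package does:

- **Node features.** Not determined by the method; default is a one-hot
  identity per item (feature dimension $V$), letting the model learn
  item-specific roles — appropriate because the items are a fixed, named
  catalog. A `"degree"` mode (feature = node degree) is provided; it is
  permutation-invariant but blind to item identity.
- **Self-connections and normalization.** $\hat A$ adds self-loops and
  normalizes symmetrically — the standard graph-convolution propagation
  rule; it also makes the all-zero graph (a fully recovered patient at a
  late visit) well-defined: $\hat A = I$ and the model falls back to
  feature information alone.
- **Hidden width.** 64 units by default; 16 gives indistinguishable
  results on these problem sizes and is used in some tests for speed.
  Both are exposed via `hidden_units`.
- **Optimizer.** ADAM with learning rate 0.01, $\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, full-batch (a few hundred
  graphs). 100 epochs suffice for convergence on separable fixtures.
- **Replication.** Accuracies vary by split and initialization at the
  $10^{-2}$ level, so each (visit, slice) cell is the mean of 10 seeded
  replicates with its standard error.
- **Labels.** Subtypes come from the *full* trajectory, pooled across
  arms; patients in non-reportable communities are excluded. Arm-specific
  curves slice the pooled-label classification by arm.

Gradients are hand-derived and verified against central finite
differences (relative error below $10^{-4}$ on a 4-node toy); the
graph-level prediction is checked to be invariant under joint node/feature
relabeling.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, not any
particular trial's marginals:

- Three archetypes (equal prevalence) over the 15-item catalog at 5
  visits: *left motor* (left limb weakness + extinction + gaze, admission
  severity $\ge 0.8$, essentially no right-sided motor signs), *right
  motor* (the mirror, with language and command-following deficits), and
  *mildly affected* (severity $\le 0.2$ throughout). Severity decays
  linearly to 30% of the admission level by the final visit — recovery.
- Scores discretize a latent severity: template value, minus
  `boost * t` for treated patients (treatment accelerates recovery but
  never changes archetype membership), plus $N(0,\sigma)$ noise, clamped
  to $[0,1]$ and scaled/rounded onto $\{0..\max(v)\}$. One dispersion
  parameter, ordinality preserved. Defaults: $n = 300$, noise
  $\sigma = 0.05$, boost 0.05/visit, treated fraction 0.5, seed 42.
- True archetype labels are returned beside, never inside, the cohort, so
  no downstream stage can consume them accidentally.

What it does **not** emulate: real NIHSS marginal distributions,
mortality/dropout, imputation artifacts, correlated item noise, or
subtype-specific treatment response. Passing tests on this generator
therefore demonstrate correctness of the machinery and recoverability
under controlled conditions — not clinical validity on trial data.

One subtlety: `empirical_affected_fraction()` converges to the template
severity only where severities sit far from the discretization threshold
(near 0 or 1). At mid-range severities the binarized fraction is a probit
transform of the severity, not the severity itself; validation tests use
near-extreme templates for this reason.

Note a consequence of modelling recovery as decaying severity: in the
default cohort the subtypes are most identifiable at admission and fade
to chance by the last visit. A cohort whose archetypes share early
severity and diverge later produces the opposite, rising curve; the test
suite constructs exactly such a late-separation cohort and verifies the
accuracy gain (final minus admission visit) exceeds 0.3.

## Problem sizes used in the checks

The shipped tests and the acceptance script run TPC on the default
300-patient cohort with 20 Louvain restarts; oracle comparisons use 100
random small instances per primitive; exhaustive-partition comparisons
use 8-node networks (4140 partitions); classifier checks use 50–60-graph
fixtures and 5–10 replicates per cell. These sizes were chosen so the
full suite exercises every path at comfortable desk scale.

## Known limitations

- Louvain operates on a *dense* network; cohorts beyond a few thousand
  patients would want sparsification or a different backend.
- Agreement counts treat all items and visits symmetrically; missing
  visits are not supported (validation rejects incomplete cohorts rather
  than imputing).
- The GCN sees rank-one graphs; with one-hot features the information it
  can use is exactly the binary symptom set, so its value over a plain
  multilayer perceptron on $v$ is architectural consistency with richer
  graphs, not extra signal here.
- Modularity values on dense agreement networks are small in magnitude
  and should be compared between partitions of the *same* network, not
  across cohorts.
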
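# tpcstroke

Stroke patients do not recover along one axis: lesions in different
territories produce distinct *combinations* of deficits that evolve
together over time. `tpcstroke` identifies such recovery subtypes from
longitudinal ordinal symptom scores — e.g. the 15 NIH Stroke Scale (NIHSS)
item subscores collected at repeated visits — and then asks *when* during
recovery those subtypes become identifiable from a single visit. It is
aimed at researchers analysing repeated ordinal clinical measurements
(stroke trials foremost, but nothing in the machinery is stroke-specific).

## The method

**Trajectory profile clustering (TPC).** Scores form a tensor
`X[i, v, t]`: patient `i`, item `v` (maximum `max(v)`), visit `t` of `M`.

1. *Binarize.* The trajectory profile `T^i` marks severe expression:
   `T^i_vt = 1` iff `X_ivt > max(v) * kappa` (default `kappa = 0.5`; a
   score exactly at the threshold maps to 0). For an item scored 0–5,
   `kappa = 0.5` puts the cutoff at 2.5, so 0–2 map to 0 and 3–5 to 1.
2. *Patient–patient network.* `P_ij = sum_vt w_vt * [T^i_vt == T^j_vt]`
   counts positions where two profiles agree (uniform unit weights by
   default; the raw diagonal `V*M` is zeroed before clustering).
3. *Community detection.* Louvain maximization of Newman–Girvan
   modularity `Q = (1/2m) sum_ij (P_ij - k_i k_j / 2m) delta(c_i, c_j)`
   on the dense weighted network. The number of subtypes `L` is an
   output, not an input; the best of 20 seeded restarts is kept.
4. *Subtype profiles.* `S^l_vt = (1/N_l) sum_{i in C^l} T^i_vt` — the
   fraction of subtype members severely affected by symptom `v` at visit
   `t`. Communities with fewer than 10 patients are flagged
   non-reportable.

**Stratification timing (GCN).** For each visit, every patient yields a
symptom–symptom graph `G_it = v v^T` (the outer product of the patient's
binary symptom vector at that visit). A two-layer graph convolutional
network — `H1 = ReLU(Ahat F W0)`, `H2 = ReLU(Ahat H1 W1)`, mean readout,
softmax — is trained per visit on a stratified 70/30 split (100 epochs,
full-batch ADAM) with the full-trajectory subtypes as labels. Held-out
accuracy as a function of visit shows when subtype membership is expressed
in the symptoms, overall and by treatment arm.

**Synthetic cohorts.** `generate_cohort()` plants left-motor, right-motor
and mildly-affected recovery archetypes over the 15 NIHSS items at 5
visits, with time-decreasing latent severity, Gaussian noise, ordinal
discretization and a treated arm whose severity decays faster — so the
whole pipeline is testable without trial data.

## Worked example

```r
library(tpcstroke)

gen  <- generate_cohort(sim_config())        # 300 patients, seed 42
part <- run_tpc(gen$cohort, kappa = 0.5, seed = 2024, n_restarts = 20)
#> TPC: kappa=0.5 mode=fraction -> L=3 communities (modularity=0.02968;
#>      sizes: 102, 101, 97)

mclust::adjustedRandIndex(part$labels, gen$archetype[names(part$labels)])
#> [1] 1
```

Three reportable subtypes emerge and match the planted archetypes exactly
(adjusted Rand index 1). Their admission profiles are the lateralized
patterns the generator planted — e.g. subtype 2 has affected fractions
`MOTORLA=1, MOTORLL=1, GAZE=0.99, EXTIN=0.98`: the left-motor subtype.
Modularity is small in absolute terms because the agreement network is
dense (every pair agrees on most of the 75 positions); what matters is
that the maximizing partition is the planted one.

```r
curve <- stratification_analysis(gen$cohort, part, slices = "all",
                                 replicates = 10, seed = 7)
curve[, c("timepoint", "mean_accuracy")]
#>   timepoint mean_accuracy
#> 1         0         0.930
#> 2         1         0.870
#> 3         2         0.433
#> 4         3         0.336
#> 5         4         0.338
```

In this simulated cohort the subtypes are sharpest at admission and fade
toward chance (1/3) as all archetypes converge to low severity — the
mirror image of a cohort whose subtypes are determined late, which the
test suite exercises with a late-separation fixture (accuracy rises from
~0.57 at admission to 1.0 at the final visit).

The numbered drivers in `analysis/` run these stages end to end and write
their tables under `results/` (`01_simulate.R`, `02_cluster.R`,
`03_stratify.R`); `run_full_pipeline()` does the same in one call with a
manifest.

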
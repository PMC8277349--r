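# pfcensembles

Analysis of two-photon calcium imaging from cortical populations recorded
during head-fixed Pavlovian reward conditioning. In the task, one
auditory cue (CS+) predicts a sucrose reward delivered after a 1 s trace
interval and a second cue (CS-) predicts nothing; the cues are presented
50 times each in random order with 20-50 s inter-trial intervals.
Anticipatory licking in the trace interval indexes learning, and the
imaging question is how the recorded population organizes into neuronal
ensembles and what each ensemble encodes.

The package implements the full analysis chain:

* **Behaviour** — per-trial lick counts in task epochs and normalized
  auROC scores: cue discrimination is `2 (AUC − 0.5)` over
  baseline-subtracted trace-interval lick rates (CS+ trials as
  positives), bounded in [−1, 1]; sessions classify as *early*
  (score < 0.3) or *late* (score > 0.31, sticky per mouse).
* **PSTHs** — trial-aligned tensors of 69 frames (23 baseline, 23
  cue/trace, 23 outcome at exactly 23/3 Hz) and 138-element per-cell
  response vectors (mean CS+ PSTH ‖ mean CS- PSTH), after baseline
  z-scoring.
* **Ensembles** — `fit_ensembles()`: PCA to the scree-plot elbow, then
  spectral clustering on a symmetrized k-NN graph with the cluster and
  neighbour counts chosen by maximum silhouette over a grid
  (k ∈ 2–10, neighbours ∈ {5, 10, 15, 20, 30, 50}), compared against
  agglomerative and k-means baselines, and canonicalized against five
  ensemble response motifs. Returns a classed model object with
  `print`, `summary`, `plot`, `predict` and `fitted` methods.
* **Decoding** — linear-SVM decoding of five task variables (CS+, CS-,
  cue discrimination, reward, licking) from epoch-mean population or
  single-ensemble activity, under stratified 5-fold cross-validation,
  against 100-permutation shuffled nulls, with the two normalization
  schemes used for population and ensemble heat maps.
* **Tracking** — cross-session stability correlations of tracked cells,
  within-FOV identity-shuffle controls, within-session trial-block
  stability, early→late response-evolution ANOVAs, and cross-correlation
  lag matrices between ensembles.
* **Synthetic data** — a calcium-transient simulator
  (`sim_config()`, `generate_session()`, `generate_experiment()`) that
  reproduces the task design with five planted response motifs,
  learning-dependent amplitudes and licking, and stable cell identities,
  so the entire pipeline is testable against ground truth.

See the vignette (`vignettes/ensemble-analysis.Rmd`) for the methods in
detail, including every tunable parameter and the generator's design.

## Worked example

Simulate a learned session with 120 cells split evenly over the five
motifs, score behaviour, fit ensembles, and decode cue identity:

```r
library(pfcensembles)

cfg   <- sim_config(n_cells = 120, trials_per_cue = 25,
                    motif_props = rep(0.2, 5))
truth <- sample_ground_truth(cfg, stage = 1, seed = 1)
sess  <- generate_session(cfg, truth, seed = 1)

behavior_score(sess$record)
#>   mouse_id session_index cue_discrimination cs_minus_error
#> 1       m1             1             0.8368         -0.056
#>   delta_lick_rate_cs_plus delta_lick_rate_cs_minus phase
#> 1                    3.76                     0.04  late

rv  <- session_response_vectors(sess$record, sess$traces)
fit <- fit_ensembles(rv$vectors, k_range = 2:8, nn_range = c(5, 10, 20),
                     seed = 1)
fit
#> Neuronal ensemble fit (spectral clustering)
#>   cells: 120   PCA components: 4
#>   selected: 5 clusters, 20 neighbours (silhouette 0.770)
#>   cluster sizes: 1=23 2=24 3=25 4=24 5=24

table(planted = truth$cells$motif, recovered = fit$labels)
#>        recovered
#> planted  1  2  3  4  5
#>       1 23  0  1  0  0
#>       2  0 24  0  0  0
#>       3  0  0 24  0  0
#>       4  0  0  0 24  0
#>       5  0  0  0  0 24

samp <- build_samples(sess$record, rv$traces_norm, "cs_disc")
acc  <- decode(samp$x, samp$y, seed = 1)
null <- shuffled_null(samp$x, samp$y, n_shuffles = 100, seed = 1)
c(accuracy = acc, null_mean = mean(null),
  p = (1 + sum(null >= acc)) / 101)
#>  accuracy null_mean         p
#>     0.980     0.505     0.010
```

The behaviour table says the simulated mouse licks ~3.8 Hz more during
CS+ trace intervals than baseline but not after the CS-, scoring 0.84 on
cue discrimination (a *late*-learning session). The fit selects five
clusters whose labels recover the planted motifs almost perfectly, and
cue identity is decoded from single-trial population activity at 98%
accuracy against a 50% permutation null.

`run_pipeline(pipeline_config(seed = 1))` runs every stage end to end on
a simulated multi-mouse experiment and writes a reproducible report
bundle (labels, behaviour and decoding tables, stability and lag
matrices) stamped with the configuration hash.

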
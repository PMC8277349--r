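---
title: "Identifying and validating prefrontal neuronal ensembles during reward conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating prefrontal neuronal ensembles during reward conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pfcensembles` analyses two-photon calcium imaging of cortical populations
recorded while head-fixed mice learn a Pavlovian trace-conditioning task:
one auditory cue (CS+) predicts a sucrose reward delivered after a 1 s
trace interval, a second cue (CS-) predicts nothing, and the two cues are
presented 50 times each in random order with inter-trial intervals drawn
uniformly from 20-50 s. Anticipatory licking during the trace interval
indexes learning; the imaging question is how the recorded population
organizes into ensembles with distinct task-locked responses, and what
those ensembles encode.

This vignette documents the analysis model, its assumptions and tunable
parameters, the synthetic-data generator used for validation, and the
numerical choices made where the design was open.

## Behavioural scoring

Licking is scored per trial in three half-open windows tied to each cue:
the 1 s trace interval `[offset, offset + 1)`, a 3 s pre-cue baseline
`[onset - 3, onset)`, and a 3 s outcome window from reward delivery (or
the equivalent no-reward time on CS- trials). Cue discrimination is the
normalized area under the ROC curve, `2 * (AUC - 0.5)`, computed over
per-trial baseline-subtracted trace-interval lick rates with CS+ trials
as positives. The statistic is a rank statistic (Mann-Whitney), so it is
invariant to any monotone rescaling of lick counts; ties receive half
credit — the standard convention, adopted here because nothing in the
analysis constrains tie handling otherwise. A score of +1 means every
CS+ trial showed more anticipatory licking than every CS- trial; -1 is
the reversed contingency; 0 is chance.

Two scoring choices deserve note:

* **Rate matching.** Baseline subtraction compares a 1 s window against a
  3 s window, so both are converted to Hz before subtraction. The CS-
  'error' score (CS- trace licking vs CS- baseline licking) uses the same
  rate matching so the two windows are commensurate.
* **Phase thresholds.** Sessions score `early` below 0.3 and `late` above
  0.31, with stickiness within a mouse: after the first late session all
  subsequent sessions are late. Scores falling in the (0.3, 0.31] gap
  with no prior late session are reported `indeterminate` rather than
  silently assigned to either side.

## Trial alignment and response vectors

Imaging runs at 23/3 Hz (about 7.67 Hz), so a 3 s epoch holds exactly 23
frames. Each trial contributes 69 frames: 23 baseline frames preceding
the first frame at or after tone onset, 23 frames from tone onset (cue
plus trace interval), and 23 frames from the reward or equivalent
no-reward time. Frames are assigned by a nearest-frame-at-or-after rule
with half-open windows; trials truncated by the session edge are dropped
with a warning, never padded. Each cell's trial-averaged CS+ PSTH (69
frames) concatenated with its CS- PSTH gives the 138-element response
vector that all downstream stages consume, CS+ block first.

Before alignment, each cell is z-scored against the session's pooled
pre-cue baseline frames. The normalization is configurable
(`session_response_vectors(..., normalize = "none")`), but baseline
z-scoring is the default because it puts cells on a common signed scale
— necessary for the inhibitory ensemble — without letting high-rate
cells dominate the clustering geometry. Cells with zero baseline
variance raise an error naming the cell rather than propagating NaNs.

## Ensemble identification

`fit_ensembles()` is the package's central estimator:

1. **Dimensionality.** The pooled cells-by-138 matrix is reduced by PCA to
   the number of components at the scree-plot elbow, located as the point
   of maximum perpendicular distance from the cumulative
   variance-explained curve to the chord joining its endpoints (axes
   normalized to the unit square; ties resolve to the smaller count).
   This is an algorithmic stand-in for the visual "inflection point";
   it returns the exact rank on stepped spectra and 1 on a single
   dominant component over an isotropic floor.
2. **Clustering.** Spectral clustering on a symmetrized k-nearest-
   neighbour connectivity graph: normalized graph Laplacian, leading
   eigenvectors, row normalization, then k-means on the embedding (fixed
   seed, 10 restarts, so labels are reproducible). If the graph splits
   into more components than clusters the fit aborts with advice to
   raise `n_neighbors`. Agglomerative (Ward) and k-means baselines run
   on the same PCA scores for comparison (`compare_algorithms()`), with
   agreement summarized by the adjusted Rand index.
3. **Model selection.** The cluster count and neighbour count are chosen
   by maximum mean silhouette over a grid (defaults: k in 2-10,
   neighbours in {5, 10, 15, 20, 30, 50}), computed in the same PCA
   subspace the model was fit in. Ties break towards fewer clusters,
   then fewer neighbours. The affinity eigendecomposition is computed
   once per neighbour count and shared across cluster counts.
4. **Canonicalization.** Fitted clusters are renumbered by greedy
   one-to-one cosine matching of their mean response vectors to five
   canonical ensemble templates: (1) sustained excitation across both
   cues and reward, (2) CS+ excitation, (3) equal excitation to both
   cues, (4) reward excitation, (5) CS+ inhibition. The renumbering is
   invariant to the arbitrary label order the fit produces; clusters
   without a template match keep labels above 5.

All cells are assigned to a cluster; per-cluster silhouette widths (in
`summary()`) quantify how well each ensemble is delimited instead of
excluding cells.

## Decoding

Five binary task variables are decoded from epoch-mean features (one row
per trial epoch, one column per cell): CS+ and CS- (2 s cue epoch vs 2 s
pre-cue baseline), cue discrimination (CS+ vs CS- cue epochs), reward
(1 s post-delivery vs 1 s pre-delivery), and licking (high vs low lick
rate over the 6 s from CS+ onset, split at the median). The classifier
is a linear support-vector machine (cost 1, no rescaling — features are
already z-scored) under stratified 5-fold cross-validation with seeded
fold assignment; linear max-margin classification is robust at the
50-trials-per-class sample sizes typical here, and the classifier is
configurable. Chance is estimated by re-running the decoder on label
permutations (default 100), giving the permutation p-value
`(1 + #(null >= observed)) / (1 + n_shuffles)`. Group-level claims pool
FOVs by pairing shuffle replicates: the null statistic is the mean of
the b-th shuffle accuracy across FOVs.

Two normalization schemes support heat-map comparison: population scores
divide by the single maximum entry across variables and phases (cue
discrimination late in learning in practice), and ensemble scores divide
each variable by its own maximum across ensembles so each ensemble's
relative contribution is visible per variable.

## Longitudinal analyses

Tracking maps (FOV, cell in session A, cell in session B) are inputs;
the synthetic generator provides ground-truth maps. Per tracked cell the
mean epoch response (6 s cue/reward epoch minus 3 s baseline, averaged
over trials) is compared across sessions by Pearson correlation. The
control shuffles identities within each FOV only, enforcing a
derangement whenever one exists, so any surviving correlation would
reflect FOV-level similarity rather than cell identity. Within-session
stability correlates per-cell responses over the first 10 trials against
the last 10. Early-to-late response evolution is assembled per cluster
and tested with a standard two-way ANOVA (phase x cue) plus Tukey
post-hocs, delegated to `stats::aov`; clusters with fewer than three
tracked cells are excluded with a warning.

Cross-correlation lag structure uses full-session normalized traces:
for each ordered cell pair the optimal lag maximizes the normalized
cross-correlation (both traces standardized, product sums divided by the
overlap length) within ±5 s, computed by FFT with one transform per
cell and verified against a brute-force search. Positive lag for (a, b)
means b follows a, so the matrix of per-cluster-pair mean lags is
antisymmetric up to averaging noise. Given the indicator's kinetics,
lags are interpretable only on the hundreds-of-milliseconds scale and
the analysis is used comparatively (within- vs between-cluster).

## The synthetic-data generator

The generator exists so every stage above can be validated against known
ground truth without any external download. It emulates the study
conditions: 50 trials per cue in random order, 2 s tones, 1 s trace
interval, reward on CS+ only, ITIs uniform on 20-50 s, frames at exactly
23/3 Hz, five planted response motifs plus optional background cells,
learning-dependent response amplitudes and anticipatory licking, and
stable cell identities across tracked sessions.

**Response model.** Each motif defines a piecewise-constant drive level:
the cue gain holds from tone onset through the trace interval, and the
reward gain holds over a 2 s consumption window on CS+ trials. Motif 1
is a sustained responder whose drive holds the cue level through the
outcome window on both trial types — one continuous trial-long plateau —
so its fluorescence carries no event-locked contrast at reward delivery,
while motif 4 has a sharp reward-locked onset. Fluorescence is the drive
convolved with a difference-of-exponentials kernel (rise 0.2 s, decay
1.5 s, GCaMP6s-like; the kinetics are not constrained by the analysis,
so values were chosen so transients span several frames at 7.67 Hz).
Because a slow indicator low-passes a step drive, the underlying rate
includes a fast onset-adaptation transient at every step towards the
response direction (tau 0.2 s, gain 4.9, calibrated once so a sustained
unit drive yields a flat unit plateau); steps back toward baseline decay
with the kernel, as an indicator does. Without this compensation a
"sustained" cell's fluorescence keeps creeping upward across the reward
boundary, which would leak spurious reward information into every
sustained ensemble.

**Amplitudes and variability.** Per-cell amplitudes are normal (mean 3,
SD 0.5, truncated at 0.5) in baseline-SD units with unit Gaussian frame
noise, i.e. an amplitude-to-noise ratio of 3. All cells of a motif share
a per-trial Gamma gain (shape 6 for motifs 1-4; shape 3 for motif 5),
modelling ensemble-wide trial-to-trial variability. The motif-5 gain is
the behaviour-coupled one: it multiplies both that trial's inhibitory
response and the anticipatory lick rate, so licking is decodable from
ensemble 5 and from the population after learning. Background cells (0
by default; the default mixture follows the relative ensemble sizes of
the pooled late-learning population) receive Ornstein-Uhlenbeck drift
(SD 0.5, tau 30 s) so clustering faces realistic nuisance variance when
they are enabled.

**Learning.** A session's stage in [0, 1] scales the amplitudes of
motifs 2-5 and the anticipatory lick rate linearly; motif 1 is
stage-independent. This is the simplest monotone model consistent with
ensembles that "appear" across learning while one ensemble responds
robustly from the start. Licking is an inhomogeneous Poisson process:
baseline 0.5 Hz throughout, anticipatory rate `stage x 6 Hz x gain`
during CS+ trace intervals, consumption at `6 Hz x gain` for 2 s after
reward. None of these rates are constrained numerically by the study
design, so they are free parameters of `sim_config()` set to values
typical of well-trained head-fixed mice. In multi-mouse experiments the
motif mixture is Dirichlet-jittered per mouse and, by default, the
asymptotic anticipatory rate scales with the mouse's motif-5 share,
planting the ensemble-proportion/behaviour correlation the analysis is
designed to detect.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: motion and neuropil artifacts, spike-level
dynamics (drives are rates, not spike trains), non-stationary drift in
responsive cells, overlapping or merged ROIs, lick-bout microstructure,
and session-to-session changes in optical access. Tests passing on the
generator demonstrate that the pipeline recovers planted structure under
the study's design and realistic noise, not that the biological claims
hold.

## Validation problem sizes

The packaged validation suite exercises: planted-ensemble recovery on
populations of 300 cells over 20 seeds (silhouette-selected spectral
clustering over k in 2-10); decoding on six late- and six early-learning
FOVs of 60 cells each with 100-permutation nulls; stability and
shuffle-control analyses on one tracked FOV of 60 cells across three
sessions with 100 identity shuffles; and oracle equivalence on 1000
random auROC inputs and 100 shifted-trace pairs. These sizes were chosen
as the smallest at which the planted effects are comfortably detected.

## Known limitations

* The scree elbow is a heuristic; on spectra without a clear knee it
  errs towards few components. The component count can be overridden
  (`n_components`).
* Silhouette-based selection favours compact, balanced clusters; strongly
  elongated or heavily unbalanced ensembles may be merged. The full
  selection grid is returned for inspection.
* The decoder is linear by design; nonlinearly separable codes would be
  underestimated.
* Cross-correlation lags inherit the indicator's temporal blur and are
  only comparative.
* The loader for externally deposited datasets reads the package's own
  session layout; archives in other layouts must be converted first.
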
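#' Binary decoding task definitions
#'
#' The five task variables and their epoch contrasts, all relative to
#' trial events: `cs_plus` (2 s cue epoch vs 2 s pre-cue baseline on CS+
#' trials), `cs_minus` (same on CS- trials), `cs_disc` (2 s CS+ cue epoch
#' vs 2 s CS- cue epoch), `reward` (1 s from sucrose delivery vs 1 s
#' pre-delivery), and `licking` (high vs low relative lick rate over the
#' 6 s from CS+ onset, split at the median).
#'
#' @return Character vector of task names.
#' @export
decoding_tasks <- function() {
  c("cs_plus", "cs_minus", "cs_disc", "reward", "licking")
}

#' @noRd
epoch_features <- function(traces, frame_times, starts, duration) {
  t(vapply(starts, function(s) {
    idx <- frames_in(frame_times, s, s + duration)
    if (length(idx) == 0) stop_validation("empty epoch window at t=%.2f", s)
    rowMeans(traces[, idx, drop = FALSE])
  }, numeric(nrow(traces))))
}

#' Build a decoder design matrix for one task
#'
#' One feature row per trial epoch; each feature is a cell's mean
#' normalized activity in that epoch. Scope restricts features to the
#' cells of one fitted ensemble.
#'
#' @param record A `session_record`.
#' @param traces Normalized `trace_matrix` (see [normalize_traces()]).
#' @param task One of [decoding_tasks()].
#' @param scope `"population"` or `"cluster"`.
#' @param labels Named cluster labels (required for `scope = "cluster"`).
#' @param cluster Cluster ID to decode from (scope `"cluster"`).
#' @return List: `x` (samples x cells matrix), `y` (factor of two classes).
#' @export
build_samples <- function(record, traces, task = decoding_tasks(),
                          scope = c("population", "cluster"), labels = NULL,
                          cluster = NULL) {
  task <- match.arg(task)
  scope <- match.arg(scope)
  vals <- traces$values
  rownames(vals) <- traces$cell_ids
  if (scope == "cluster") {
    if (is.null(labels) || is.null(cluster)) {
      stop_validation("cluster scope requires labels and a cluster id")
    }
    cells <- names(labels)[labels == cluster]
    cells <- intersect(cells, traces$cell_ids)
    if (length(cells) < 2) {
      stop_validation("cluster %s has fewer than 2 cells in this session", cluster)
    }
    vals <- vals[cells, , drop = FALSE]
  }
  ft <- record$frame_times_s
  tr <- session_trials(record)
  plus <- tr[tr$identity == "CS+", , drop = FALSE]
  minus <- tr[tr$identity == "CS-", , drop = FALSE]
  if (task %in% c("cs_plus", "cs_disc", "reward", "licking") && nrow(plus) == 0) {
    stop_validation("task '%s' requires CS+ trials", task)
  }
  if (task %in% c("cs_minus", "cs_disc") && nrow(minus) == 0) {
    stop_validation("task '%s' requires CS- trials", task)
  }
  out <- switch(task,
    cs_plus = list(
      x = rbind(epoch_features(vals, ft, plus$onset_s, 2),
                epoch_features(vals, ft, plus$onset_s - 2, 2)),
      y = rep(c("cue", "baseline"), each = nrow(plus))
    ),
    cs_minus = list(
      x = rbind(epoch_features(vals, ft, minus$onset_s, 2),
                epoch_features(vals, ft, minus$onset_s - 2, 2)),
      y = rep(c("cue", "baseline"), each = nrow(minus))
    ),
    cs_disc = list(
      x = rbind(epoch_features(vals, ft, plus$onset_s, 2),
                epoch_features(vals, ft, minus$onset_s, 2)),
      y = c(rep("cs_plus", nrow(plus)), rep("cs_minus", nrow(minus)))
    ),
    reward = list(
      x = rbind(epoch_features(vals, ft, plus$outcome_s, 1),
                epoch_features(vals, ft, plus$outcome_s - 1, 1)),
      y = rep(c("reward", "pre"), each = nrow(plus))
    ),
    licking = {
      n_lick <- vapply(plus$onset_s, function(on) {
        sum(record$lick_times_s >= on & record$lick_times_s < on + 6)
      }, numeric(1))
      hi <- rank(n_lick, ties.method = "first") > nrow(plus) / 2
      list(x = epoch_features(vals, ft, plus$onset_s, 6),
           y = ifelse(hi, "high", "low"))
    }
  )
  if (length(unique(out$y)) < 2) {
    stop_validation("task '%s' produced a single class", task)
  }
  list(x = out$x, y = factor(out$y))
}

#' Cross-validated accuracy of a linear max-margin decoder
#'
#' Mean held-out accuracy of a linear support-vector classifier under
#' stratified k-fold cross-validation. Deterministic given `seed` (which
#' controls the fold assignment).
#'
#' @param x Samples x features matrix.
#' @param y Two-class factor.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param cost SVM margin cost (default 1).
#' @return Accuracy in \[0, 1\].
#' @export
decode <- function(x, y, n_folds = 5, seed = 1, cost = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (min(table(y)) < 2) stop_validation("need >= 2 samples per class")
  if (min(table(y)) < n_folds) {
    stop_validation("smallest class (%d) is smaller than n_folds (%d)",
                    min(table(y)), n_folds)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    mean(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Permutation null distribution of decoding accuracy
#'
#' Re-runs [decode()] on label permutations to build the chance
#' distribution the observed accuracy is compared against.
#'
#' @inheritParams decode
#' @param n_shuffles Number of label permutations (default 100).
#' @return Numeric vector of `n_shuffles` accuracies (empty if 0).
#' @export
shuffled_null <- function(x, y, n_shuffles = 100, n_folds = 5, seed = 1,
                          cost = 1) {
  if (n_shuffles == 0) return(numeric(0))
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_shuffles))
  vapply(seq_len(n_shuffles), function(i) {
    yp <- with_seed(sub[i], sample(y))
    decode(x, yp, n_folds = n_folds, seed = sub[i], cost = cost)
  }, numeric(1))
}

#' Decode all task variables across sessions and scopes
#'
#' For every session x task x scope cell, builds samples, computes the
#' cross-validated accuracy and its permutation null, and reports the
#' permutation p-value `(1 + #{null >= observed}) / (1 + n_shuffles)`.
#' Failures (e.g. too few cells in a cluster) are recorded per row and do
#' not abort the remaining cells.
#'
#' @param experiment An `ensemble_experiment`, or a list of session
#'   entries each with `record`, `traces` and optionally `mouse_id`,
#'   `session_index`.
#' @param labels Named cluster labels over cell IDs (needed for cluster
#'   scopes).
#' @param tasks Tasks to decode (default all five).
#' @param scopes `"population"` and/or `"cluster"`.
#' @param clusters Cluster IDs for cluster scope (default 1-5).
#' @param n_folds,n_shuffles,seed Decoder settings.
#' @param cluster_shuffles Shuffle count for cluster scopes (defaults to
#'   `n_shuffles`).
#' @return Data frame, one row per FOV x task x scope, with accuracy,
#'   null mean/SD, permutation p and the session's behavioural phase.
#'   Null distributions are kept in `attr(, "nulls")` (list indexed by
#'   row).
#' @export
decode_all <- function(experiment, labels = NULL, tasks = decoding_tasks(),
                       scopes = c("population", "cluster"), clusters = 1:5,
                       n_folds = 5, n_shuffles = 100, seed = 1,
                       cluster_shuffles = n_shuffles) {
  sessions <- if (inherits(experiment, "ensemble_experiment")) {
    experiment$sessions
  } else experiment
  rows <- list()
  nulls <- list()
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    length(sessions)))
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    tn <- normalize_traces(s$traces, s$record)
    phase <- classify_phase(cue_discrimination(s$record))
    for (task in tasks) {
      scope_specs <- list()
      if ("population" %in% scopes) {
        scope_specs <- c(scope_specs, list(list(scope = "population",
                                                cluster = NA, ns = n_shuffles)))
      }
      if ("cluster" %in% scopes) {
        for (cl in clusters) {
          scope_specs <- c(scope_specs, list(list(scope = "cluster",
                                                  cluster = cl,
                                                  ns = cluster_shuffles)))
        }
      }
      for (sp in scope_specs) {
        res <- tryCatch({
          samp <- build_samples(s$record, tn, task, scope = sp$scope,
                                labels = labels, cluster = sp$cluster)
          acc <- decode(samp$x, samp$y, n_folds = n_folds, seed = sub[si])
          nl <- shuffled_null(samp$x, samp$y, n_shuffles = sp$ns,
                              n_folds = n_folds, seed = sub[si])
          list(acc = acc, null = nl, n_cells = ncol(samp$x), err = NA_character_)
        }, error = function(e) {
          list(acc = NA_real_, null = numeric(0), n_cells = NA_integer_,
               err = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = s$mouse_id %||% NA_character_,
          session_index = s$session_index %||% NA_integer_,
          phase = phase, task = task, scope = sp$scope,
          cluster = sp$cluster, n_cells = res$n_cells,
          accuracy = res$acc,
          null_mean = if (length(res$null)) mean(res$null) else NA_real_,
          null_sd = if (length(res$null) > 1) stats::sd(res$null) else NA_real_,
          p = if (length(res$null)) {
            (1 + sum(res$null >= res$acc)) / (1 + length(res$null))
          } else NA_real_,
          error = res$err
        )
        nulls[[length(rows)]] <- res$null
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nulls") <- nulls
  out
}

#' Pooled permutation p-value for one task across FOVs
#'
#' Pairs shuffle replicates across FOVs: the group statistic is the mean
#' accuracy over FOVs, and the null is the distribution of the mean of
#' the b-th shuffle accuracy over FOVs.
#'
#' @param results A [decode_all()] result (with its `"nulls"` attribute).
#' @param task Task name.
#' @param phase Optional phase filter (`"early"`/`"late"`).
#' @param scope Scope filter (default `"population"`).
#' @return List: `mean_accuracy`, `null_means`, `p`.
#' @export
pooled_permutation_p <- function(results, task, phase = NULL,
                                 scope = "population") {
  keep <- results$task == task & results$scope == scope & !is.na(results$accuracy)
  if (!is.null(phase)) keep <- keep & results$phase == phase
  idx <- which(keep)
  if (length(idx) == 0) stop_validation("no results for task '%s'", task)
  nulls <- attr(results, "nulls")[idx]
  nb <- unique(vapply(nulls, length, integer(1)))
  if (length(nb) != 1 || nb[1] == 0) {
    stop_validation("pooled p requires equal non-zero shuffle counts")
  }
  null_means <- rowMeans(do.call(cbind, nulls))
  obs <- mean(results$accuracy[idx])
  list(mean_accuracy = obs, null_means = null_means,
       p = (1 + sum(null_means >= obs)) / (1 + length(null_means)))
}

#' Normalize decoding accuracies for heat-map comparison
#'
#' `mode = "population"`: mean accuracy per task x phase, divided by the
#' single maximum entry (in the target experiments this reference is cue
#' discrimination late in learning). `mode = "ensemble"`: mean accuracy
#' per task x cluster, each task row divided by its own maximum so the
#' relative contribution of each ensemble is comparable across tasks.
#'
#' @param results A [decode_all()] result.
#' @param mode `"population"` or `"ensemble"`.
#' @return Numeric matrix of normalized scores (max entry 1 per the mode).
#' @export
normalize_scores <- function(results, mode = c("population", "ensemble")) {
  mode <- match.arg(mode)
  if (mode == "population") {
    df <- results[results$scope == "population" & !is.na(results$accuracy), ]
    if (nrow(df) == 0) stop_validation("no population results")
    m <- tapply(df$accuracy, list(df$task, df$phase), mean)
    mx <- max(m, na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) stop_validation("zero maximum score")
    m / mx
  } else {
    df <- results[results$scope == "cluster" & !is.na(results$accuracy), ]
    if (nrow(df) == 0) stop_validation("no cluster-scope results")
    m <- tapply(df$accuracy, list(df$task, df$cluster), mean)
    mx <- apply(m, 1, max, na.rm = TRUE)
    if (any(!is.finite(mx)) || any(mx == 0)) stop_validation("zero maximum score")
    m / mx
  }
}
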
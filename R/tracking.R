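#' Validate a tracking map against two sessions
#' @noRd
validate_tracking_map <- function(map, ids_a = NULL, ids_b = NULL) {
  need <- c("fov_id", "cell_id_a", "cell_id_b")
  if (!all(need %in% names(map))) {
    stop_validation("tracking map needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$cell_id_a) || anyDuplicated(map$cell_id_b)) {
    stop_validation("each cell may appear in at most one tracked pair")
  }
  if (!is.null(ids_a)) {
    bad <- setdiff(map$cell_id_a, ids_a)
    if (length(bad)) stop_validation("pair with unknown session-A cell '%s'", bad[1])
  }
  if (!is.null(ids_b)) {
    bad <- setdiff(map$cell_id_b, ids_b)
    if (length(bad)) stop_validation("pair with unknown session-B cell '%s'", bad[1])
  }
  invisible(map)
}

#' Paired epoch responses of tracked cells
#'
#' Computes [mean_epoch_response()] per cell in each session and pairs
#' them by the tracking map, separately per cue.
#'
#' @param map Tracking map data frame (`fov_id`, `cell_id_a`,
#'   `cell_id_b`).
#' @param tensors_a,tensors_b Named lists with `csplus`/`csminus`
#'   `trial_tensor`s for sessions A and B.
#' @return Named list (per cue) of data frames `fov_id`, `cell_id_a`,
#'   `cell_id_b`, `response_a`, `response_b`.
#' @export
paired_epoch_responses <- function(map, tensors_a, tensors_b) {
  validate_tracking_map(map, attr(tensors_a$csplus, "cell_ids"),
                        attr(tensors_b$csplus, "cell_ids"))
  if (nrow(map) == 0) {
    empty <- data.frame(fov_id = character(0), cell_id_a = character(0),
                        cell_id_b = character(0), response_a = numeric(0),
                        response_b = numeric(0))
    return(list(csplus = empty, csminus = empty))
  }
  per_cue <- function(cue) {
    ra <- mean_epoch_response(tensors_a[[cue]], map$cell_id_a)
    rb <- mean_epoch_response(tensors_b[[cue]], map$cell_id_b)
    data.frame(fov_id = map$fov_id, cell_id_a = map$cell_id_a,
               cell_id_b = map$cell_id_b,
               response_a = unname(ra), response_b = unname(rb))
  }
  list(csplus = per_cue("csplus"), csminus = per_cue("csminus"))
}

#' Cross-session stability correlation
#'
#' Pearson correlation between session-A and session-B mean epoch
#' responses of tracked cells.
#'
#' @param pairs A data frame with `response_a`, `response_b` (one cue of
#'   [paired_epoch_responses()]).
#' @return List: `r`, `p`, `n`, `flag` (`"ok"` or `"constant"`).
#' @export
stability_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop_validation("need >= 3 tracked pairs")
  if (stats::sd(pairs$response_a) == 0 || stats::sd(pairs$response_b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = nrow(pairs), flag = "constant"))
  }
  ct <- stats::cor.test(pairs$response_a, pairs$response_b)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs), flag = "ok")
}

#' Shuffle tracking identities within each FOV
#'
#' Control for the stability analyses: permutes the session-B cell IDs
#' among tracked pairs of the same FOV (never across FOVs), enforcing a
#' derangement (no pair keeps its true partner) whenever one exists.
#' Single-pair FOVs are left unshuffled with a warning.
#'
#' @param map Tracking map data frame.
#' @param seed Integer seed.
#' @return The map with permuted `cell_id_b`.
#' @export
shuffle_within_fov <- function(map, seed = 1) {
  validate_tracking_map(map)
  out <- map
  with_seed(seed, {
    for (fov in unique(map$fov_id)) {
      idx <- which(map$fov_id == fov)
      n <- length(idx)
      if (n < 2) {
        warning(sprintf("FOV '%s' has a single pair; left unshuffled", fov))
        next
      }
      perm <- sample(n)
      for (tries in 1:1000) {
        if (!any(perm == seq_len(n))) break
        perm <- sample(n)
      }
      out$cell_id_b[idx] <- map$cell_id_b[idx][perm]
    }
  })
  out
}

#' Within-session trial-block stability
#'
#' Correlates, across cells, the mean epoch response over the first
#' `block_size` trials with that over the last `block_size` trials.
#'
#' @param tensor A `trial_tensor` for one cue.
#' @param block_size Trials per block (default 10).
#' @return List: `r`, `p`, `n_cells`.
#' @export
trial_block_correlation <- function(tensor, block_size = 10) {
  n_trials <- dim(tensor)[2]
  if (2 * block_size > n_trials) {
    stop_validation("block_size %d too large for %d trials", block_size, n_trials)
  }
  block <- function(trials) { # subset trials, keeping tensor attributes
    out <- tensor[, trials, , drop = FALSE]
    attributes(out) <- c(attributes(out)["dim"],
                         attributes(tensor)[c("identity", "cell_ids",
                                              "epochs", "class")])
    out
  }
  first <- mean_epoch_response(block(seq_len(block_size)))
  last <- mean_epoch_response(block((n_trials - block_size + 1):n_trials))
  ct <- stats::cor.test(first, last)
  list(r = unname(ct$estimate), p = ct$p.value, n_cells = length(first))
}

#' Ensemble response evolution from early to late in learning
#'
#' Assembles, for tracked cells carrying late-phase cluster labels, the
#' mean epoch responses per cluster x cue x phase and tests the
#' session-phase effect per cluster with a two-way ANOVA
#' (response ~ phase * cue) followed by Tukey post-hoc comparisons.
#' Clusters with fewer than 3 tracked cells are excluded with a warning.
#'
#' @param map Tracking map (session A = early, session B = late).
#' @param tensors_early,tensors_late Named lists (`csplus`, `csminus`) of
#'   `trial_tensor`s.
#' @param labels Named late-phase cluster labels (by session-B cell ID).
#' @return List: `responses` (long data frame), `summary` (mean response
#'   per cluster x cue x phase), `anova` (per-cluster phase F and p),
#'   `posthoc` (per-cluster Tukey tables).
#' @export
response_evolution <- function(map, tensors_early, tensors_late, labels) {
  pr <- paired_epoch_responses(map, tensors_early, tensors_late)
  if (nrow(pr$csplus) == 0) {
    return(list(responses = data.frame(), summary = data.frame(),
                anova = data.frame(), posthoc = list()))
  }
  cl <- labels[pr$csplus$cell_id_b]
  long <- rbind(
    data.frame(cell_id = pr$csplus$cell_id_b, cluster = cl, cue = "CS+",
               phase = "early", response = pr$csplus$response_a),
    data.frame(cell_id = pr$csplus$cell_id_b, cluster = cl, cue = "CS+",
               phase = "late", response = pr$csplus$response_b),
    data.frame(cell_id = pr$csminus$cell_id_b, cluster = cl, cue = "CS-",
               phase = "early", response = pr$csminus$response_a),
    data.frame(cell_id = pr$csminus$cell_id_b, cluster = cl, cue = "CS-",
               phase = "late", response = pr$csminus$response_b)
  )
  long <- long[!is.na(long$cluster), ]
  counts <- table(unique(long[, c("cell_id", "cluster")])$cluster)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    warning(sprintf("excluding cluster(s) with < 3 tracked cells: %s",
                    paste(small, collapse = ", ")))
    long <- long[!(long$cluster %in% as.integer(small)), ]
  }
  summary <- stats::aggregate(response ~ cluster + cue + phase, long, mean)
  anova_rows <- list()
  posthoc <- list()
  for (k in sort(unique(long$cluster))) {
    dk <- long[long$cluster == k, ]
    dk$phase <- factor(dk$phase, levels = c("early", "late"))
    dk$cue <- factor(dk$cue)
    fit <- stats::aov(response ~ phase * cue, data = dk)
    tab <- summary(fit)[[1]]
    i_phase <- which(trimws(rownames(tab)) == "phase")
    anova_rows[[as.character(k)]] <- data.frame(
      cluster = k,
      f_phase = tab[i_phase, "F value"],
      p_phase = tab[i_phase, "Pr(>F)"],
      direction = mean(dk$response[dk$phase == "late"]) -
        mean(dk$response[dk$phase == "early"])
    )
    posthoc[[as.character(k)]] <- stats::TukeyHSD(fit)
  }
  list(responses = long, summary = summary,
       anova = do.call(rbind, anova_rows), posthoc = posthoc)
}

#' Cross-correlation lag structure between ensembles
#'
#' For each ordered pair of cells, finds the lag (within `max_lag_s`)
#' maximizing the normalized cross-correlation of their full-session
#' traces (each standardized to mean 0, SD 1), then averages optimal lags
#' over cell pairs for each ordered cluster pair. Positive lag for pair
#' (a, b) means b follows a. Flat traces are skipped with a warning.
#'
#' @param traces `trace_matrix` of full-session (normalized) traces.
#' @param labels Named cluster labels over the trace cells.
#' @param max_lag_s Lag search window (s), default 5.
#' @param clusters Cluster IDs to include (default 1-5).
#' @return List: `lag_s` (signed mean-lag matrix, clusters x clusters),
#'   `abs_lag_s` (mean absolute lag), `n_pairs`.
#' @export
cross_correlation_lags <- function(traces, labels, max_lag_s = 5,
                                   clusters = 1:5) {
  fr <- traces$frame_rate_hz
  max_lag <- round(max_lag_s * fr)
  cells <- intersect(traces$cell_ids, names(labels))
  lab <- labels[cells]
  x <- traces$values[match(cells, traces$cell_ids), , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sprintf("skipping flat trace(s): %s",
                    paste(cells[flat], collapse = ", ")))
    x <- x[!flat, , drop = FALSE]
    lab <- lab[!flat]
    cells <- cells[!flat]
  }
  n <- nrow(x)
  if (n < 2) stop_validation("need >= 2 non-flat cells")
  x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  nf <- ncol(x)
  # FFT cross-correlation, computed once per cell
  pad <- stats::nextn(nf + max_lag, 2)
  fx <- t(apply(x, 1, function(v) stats::fft(c(v, numeric(pad - nf)))))
  lags <- -max_lag:max_lag
  best_lag <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { best_lag[i, j] <- 0; next }
      cc <- Re(stats::fft(fx[i, ] * Conj(fx[j, ]), inverse = TRUE)) / pad
      # cc[1 + m] = sum_t x_i[t + m] x_j[t] (m >= 0, circular); with zero
      # padding >= max_lag the circular wrap does not reach |m| <= max_lag
      pos <- cc[1 + 0:max_lag]          # x_i leads by m
      neg <- cc[pad + 1 - (1:max_lag)]  # x_j leads by m
      vals <- c(rev(neg), pos) / (nf - abs(lags)) # per-lag correlation
      # lag of pair (i, j): positive when j follows i, i.e. x_j[t] matches
      # x_i[t - m]; that is the "neg" branch above reversed
      best_lag[i, j] <- -lags[which.max(vals)] / fr
    }
  }
  k <- length(clusters)
  lag_s <- abs_lag <- matrix(NA_real_, k, k,
                             dimnames = list(paste0("cluster", clusters),
                                             paste0("cluster", clusters)))
  n_pairs <- matrix(0L, k, k, dimnames = dimnames(lag_s))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      ia <- which(lab == clusters[a])
      ib <- which(lab == clusters[b])
      if (length(ia) == 0 || length(ib) == 0) next
      pairs <- expand.grid(i = ia, j = ib)
      pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
      if (nrow(pairs) == 0) next
      vals <- best_lag[cbind(pairs$i, pairs$j)]
      lag_s[a, b] <- mean(vals)
      abs_lag[a, b] <- mean(abs(vals))
      n_pairs[a, b] <- nrow(pairs)
    }
  }
  list(lag_s = lag_s, abs_lag_s = abs_lag, n_pairs = n_pairs)
}

#' Optimal cross-correlation lag for one pair of traces
#'
#' Reference implementation for small inputs and testing: a direct
#' brute-force search over integer lags of the normalized
#' cross-correlation (both traces standardized to mean 0, SD 1; each lag's
#' product sum divided by the overlap length).
#'
#' @param a,b Numeric traces (equal length).
#' @param max_lag Maximum lag in frames.
#' @param frame_rate_hz Frame rate to convert the lag to seconds.
#' @return Lag in seconds; positive when `b` follows `a`.
#' @export
pair_optimal_lag <- function(a, b, max_lag, frame_rate_hz = 1) {
  n <- length(a)
  stopifnot(length(b) == n, max_lag < n)
  a <- (a - mean(a)) / stats::sd(a)
  b <- (b - mean(b)) / stats::sd(b)
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(l) {
    # correlate a[t] with b[t + l] over the overlapping segment
    if (l >= 0) sum(a[seq_len(n - l)] * b[seq_len(n - l) + l]) / (n - l)
    else sum(a[seq_len(n + l) - l] * b[seq_len(n + l)]) / (n + l)
  }, numeric(1))
  lags[which.max(vals)] / frame_rate_hz
}
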
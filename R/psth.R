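#' Baseline z-score normalization of traces
#'
#' Z-scores each cell's trace against that session's pooled pre-cue
#' baseline frames (the 23 frames preceding each tone onset), so baseline
#' activity has mean 0 and SD 1 per cell. A signed common scale preserves
#' inhibitory responses for clustering.
#'
#' @param traces A `trace_matrix`.
#' @param record The paired `session_record`.
#' @return A `trace_matrix` of normalized values.
#' @export
normalize_traces <- function(traces, record) {
  validate_session(record, traces)
  ft <- record$frame_times_s
  idx <- unlist(lapply(record$cue_events$onset_s, function(on) {
    cs <- frame_at_or_after(ft, on)
    if (is.na(cs) || cs < 24L) return(integer(0))
    (cs - 23L):(cs - 1L)
  }))
  idx <- sort(unique(idx))
  if (length(idx) < 2) stop_validation("no baseline frames available")
  m <- rowMeans(traces$values[, idx, drop = FALSE])
  s <- apply(traces$values[, idx, drop = FALSE], 1, stats::sd)
  zero <- which(s == 0)
  if (length(zero) > 0) {
    stop_validation("zero baseline variance for cell '%s'",
                    traces$cell_ids[zero[1]])
  }
  new_trace_matrix(traces$cell_ids, (traces$values - m) / s,
                   traces$frame_rate_hz)
}

#' Extract trial-aligned activity tensors
#'
#' For each trial of one cue identity, takes the 23 frames preceding the
#' first frame at or after tone onset (baseline), 23 frames from tone
#' onset (cue and trace interval), and 23 frames from the reward (CS+) or
#' equivalent no-reward time (CS-), giving 69 frames per trial. Trials
#' truncated by the session edge are dropped with a warning, never padded.
#'
#' @param traces A `trace_matrix` (normally normalized first).
#' @param record The paired `session_record`.
#' @param identity `"CS+"` or `"CS-"`.
#' @return A `trial_tensor`: 3-d array cells x trials x 69 with attributes
#'   `identity`, `cell_ids` and the epoch index sets (`baseline` 1-23,
#'   `cue` 24-46, `outcome` 47-69).
#' @export
extract_trials <- function(traces, record, identity = c("CS+", "CS-")) {
  identity <- match.arg(identity)
  validate_session(record, traces)
  ft <- record$frame_times_s
  tr <- session_trials(record)
  tr <- tr[tr$identity == identity, , drop = FALSE]
  if (nrow(tr) == 0) stop_validation("no trials of identity '%s'", identity)
  n_frames <- length(ft)
  keep <- list()
  for (i in seq_len(nrow(tr))) {
    cs <- frame_at_or_after(ft, tr$onset_s[i])
    os <- frame_at_or_after(ft, tr$outcome_s[i])
    if (is.na(cs) || is.na(os) || cs < 24L || os + 22L > n_frames) {
      warning(sprintf("dropping truncated trial %d (%s)", tr$trial[i], identity))
      next
    }
    keep[[length(keep) + 1L]] <- c((cs - 23L):(cs + 22L), os:(os + 22L))
  }
  if (length(keep) == 0) stop_validation("all '%s' trials truncated", identity)
  n_cells <- nrow(traces$values)
  arr <- array(NA_real_, dim = c(n_cells, length(keep), 69L))
  for (t in seq_along(keep)) arr[, t, ] <- traces$values[, keep[[t]]]
  structure(arr, identity = identity, cell_ids = traces$cell_ids,
            epochs = list(baseline = 1:23, cue = 24:46, outcome = 47:69),
            class = c("trial_tensor", "array"))
}

#' Per-cell trial-averaged response vectors
#'
#' Concatenates each cell's mean CS+ peristimulus time histogram (69
#' frames) with its mean CS- PSTH (69 frames) into a 138-element response
#' vector, the input representation for ensemble clustering.
#'
#' @param tensor_csplus,tensor_csminus `trial_tensor`s for the two cues
#'   over the same cells.
#' @return Numeric matrix, cells x 138, rownames = cell IDs.
#' @export
response_vectors <- function(tensor_csplus, tensor_csminus) {
  ids_p <- attr(tensor_csplus, "cell_ids")
  ids_m <- attr(tensor_csminus, "cell_ids")
  if (!identical(ids_p, ids_m)) {
    stop_validation("tensors cover different cells")
  }
  mean_psth <- function(tensor) {
    apply(tensor, c(1, 3), mean)
  }
  out <- cbind(mean_psth(tensor_csplus), mean_psth(tensor_csminus))
  rownames(out) <- ids_p
  colnames(out) <- c(sprintf("csp_f%02d", 1:69), sprintf("csm_f%02d", 1:69))
  out
}

#' Mean epoch response per cell
#'
#' Trial-averaged difference between the 6 s cue/reward epoch (frames
#' 24-69) and the 3 s baseline epoch (frames 1-23) of a trial tensor.
#'
#' @param tensor A `trial_tensor`.
#' @param cells Optional subset of cell IDs.
#' @return Named numeric vector, one response per cell.
#' @export
mean_epoch_response <- function(tensor, cells = NULL) {
  ids <- attr(tensor, "cell_ids")
  sel <- if (is.null(cells)) seq_along(ids) else match(cells, ids)
  if (anyNA(sel)) {
    stop_validation("cell '%s' not present in tensor", cells[which(is.na(sel))[1]])
  }
  resp <- apply(tensor[sel, , 24:69, drop = FALSE], 1, mean) -
    apply(tensor[sel, , 1:23, drop = FALSE], 1, mean)
  names(resp) <- ids[sel]
  resp
}

#' Response vectors straight from a session
#'
#' Convenience wrapper: normalize, align both cue types, and return the
#' cells x 138 response-vector matrix together with the tensors.
#'
#' @param record A `session_record`.
#' @param traces The paired `trace_matrix` (raw; normalization applied
#'   here).
#' @param normalize Either `"baseline_z"` (default) or `"none"`.
#' @return List: `vectors` (cells x 138), `tensor_csplus`,
#'   `tensor_csminus`, `traces_norm`.
#' @export
session_response_vectors <- function(record, traces,
                                     normalize = c("baseline_z", "none")) {
  normalize <- match.arg(normalize)
  tn <- if (normalize == "baseline_z") normalize_traces(traces, record) else traces
  tp <- extract_trials(tn, record, "CS+")
  tm <- extract_trials(tn, record, "CS-")
  list(vectors = response_vectors(tp, tm), tensor_csplus = tp,
       tensor_csminus = tm, traces_norm = tn)
}
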
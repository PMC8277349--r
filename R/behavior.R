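#' Per-trial lick counts in a task epoch
#'
#' Counts licks in a half-open window `[start, end)` tied to each trial of
#' one cue identity: `"trace"` is the trace interval (tone offset to
#' offset + 1 s by default), `"baseline"` the 3 s before tone onset, and
#' `"reward"` the 3 s from reward delivery (CS+) or the equivalent
#' no-reward time (CS-).
#'
#' @param record A `session_record`.
#' @param identity `"CS+"` or `"CS-"`.
#' @param window `"trace"`, `"baseline"` or `"reward"`.
#' @return Integer vector, one count per trial of that identity.
#' @export
trial_lick_counts <- function(record, identity = c("CS+", "CS-"),
                              window = c("trace", "baseline", "reward")) {
  identity <- match.arg(identity)
  window <- match.arg(window)
  tr <- session_trials(record)
  tr <- tr[tr$identity == identity, , drop = FALSE]
  if (nrow(tr) == 0) stop_validation("no trials of identity '%s'", identity)
  bounds <- switch(window,
    trace = cbind(tr$offset_s, tr$offset_s + record$trace_interval_s),
    baseline = cbind(tr$onset_s - 3, tr$onset_s),
    reward = cbind(tr$outcome_s, tr$outcome_s + 3)
  )
  licks <- record$lick_times_s
  vapply(seq_len(nrow(bounds)), function(i) {
    sum(licks >= bounds[i, 1] & licks < bounds[i, 2])
  }, integer(1))
}

#' Epoch durations (s) used to convert counts to rates
#' @noRd
window_duration <- function(record, window) {
  switch(window, trace = record$trace_interval_s, baseline = 3, reward = 3)
}

#' Normalized area under the ROC curve
#'
#' Rank statistic on two samples, `2 * (AUC - 0.5)`, where AUC is the
#' probability that a randomly chosen positive sample exceeds a randomly
#' chosen negative one, ties counted half (Mann-Whitney convention).
#' Ranges over \[-1, 1\]: +1 when every positive exceeds every negative,
#' -1 for the reverse, 0 for exchangeable samples.
#'
#' @param positive,negative Non-empty numeric samples.
#' @return Score in \[-1, 1\].
#' @examples
#' normalized_auroc(c(2, 3), c(0, 1))   # +1
#' normalized_auroc(c(0, 1), c(2, 3))   # -1
#' @export
normalized_auroc <- function(positive, negative) {
  if (length(positive) == 0 || length(negative) == 0) {
    stop_validation("both samples must be non-empty")
  }
  if (any(!is.finite(c(positive, negative)))) {
    stop_validation("samples must be finite")
  }
  n1 <- length(positive)
  r <- rank(c(positive, negative), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * length(negative))
  2 * (auc - 0.5)
}

#' Baseline-subtracted trace-interval lick rates per trial
#' @noRd
trial_anticipatory_rates <- function(record, identity) {
  trace <- trial_lick_counts(record, identity, "trace") /
    window_duration(record, "trace")
  base <- trial_lick_counts(record, identity, "baseline") / 3
  trace - base
}

#' Cue discrimination score
#'
#' Normalized auROC comparing per-trial baseline-subtracted trace-interval
#' lick rates on CS+ trials (positives) against CS- trials (negatives).
#' +1 means anticipatory licking on every CS+ trial exceeded every CS-
#' trial; -1 the reverse contingency.
#'
#' @param record A `session_record` containing both cue types.
#' @return Score in \[-1, 1\].
#' @export
cue_discrimination <- function(record) {
  ids <- unique(record$cue_events$identity)
  if (!all(c("CS+", "CS-") %in% ids)) {
    stop_validation("session must contain both CS+ and CS- trials")
  }
  normalized_auroc(trial_anticipatory_rates(record, "CS+"),
                   trial_anticipatory_rates(record, "CS-"))
}

#' CS- licking error score
#'
#' Normalized auROC comparing CS- trace-interval lick rates (positives)
#' against CS- baseline-epoch lick rates (negatives), both in Hz so the
#' 1 s and 3 s windows are commensurate. Positive scores indicate licking
#' 'errors': increased licking after the unrewarded cue.
#'
#' @param record A `session_record` with CS- trials.
#' @return Score in \[-1, 1\].
#' @export
cs_minus_error <- function(record) {
  trace <- trial_lick_counts(record, "CS-", "trace") /
    window_duration(record, "trace")
  base <- trial_lick_counts(record, "CS-", "baseline") / 3
  normalized_auroc(trace, base)
}

#' Mean baseline-subtracted lick rate (delta lick rate)
#'
#' Mean over trials of (trace-interval lick frequency - 3 s baseline lick
#' frequency), in Hz.
#'
#' @param record A `session_record`.
#' @param identity `"CS+"` or `"CS-"`.
#' @return Delta lick rate (Hz).
#' @export
delta_lick_rate <- function(record, identity = c("CS+", "CS-")) {
  identity <- match.arg(identity)
  mean(trial_anticipatory_rates(record, identity))
}

#' Classify sessions as early or late in learning
#'
#' Sessions scoring below 0.3 on cue discrimination are 'early'; sessions
#' scoring above 0.31 are 'late'. Classification is sticky within a mouse:
#' once a session is late, all subsequent sessions are late. Scores
#' falling inside the (0.3, 0.31\] gap with no prior late session are
#' 'indeterminate'.
#'
#' @param scores Numeric vector of cue-discrimination scores for one
#'   mouse, in session order.
#' @return Character vector: `"early"`, `"late"` or `"indeterminate"`.
#' @examples
#' classify_phase(c(0.05, 0.25, 0.6, 0.2))  # early early late late
#' @export
classify_phase <- function(scores) {
  stopifnot(is.numeric(scores), all(scores >= -1 & scores <= 1))
  out <- character(length(scores))
  seen_late <- FALSE
  for (i in seq_along(scores)) {
    if (seen_late || scores[i] > 0.31) {
      out[i] <- "late"
      seen_late <- TRUE
    } else if (scores[i] < 0.3) {
      out[i] <- "early"
    } else {
      out[i] <- "indeterminate"
    }
  }
  out
}

#' All behavioural statistics for one session
#'
#' @param record A `session_record`.
#' @return One-row data frame: `mouse_id`, `session_index`,
#'   `cue_discrimination`, `cs_minus_error`, `delta_lick_rate_cs_plus`,
#'   `delta_lick_rate_cs_minus`, `phase` (per-session threshold rule,
#'   without cross-session stickiness).
#' @export
behavior_score <- function(record) {
  cd <- cue_discrimination(record)
  data.frame(
    mouse_id = record$mouse_id,
    session_index = record$session_index,
    cue_discrimination = cd,
    cs_minus_error = cs_minus_error(record),
    delta_lick_rate_cs_plus = delta_lick_rate(record, "CS+"),
    delta_lick_rate_cs_minus = delta_lick_rate(record, "CS-"),
    phase = classify_phase(cd)
  )
}
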
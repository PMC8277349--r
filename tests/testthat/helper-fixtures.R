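# Small shared fixtures, generated once per test run.

small_config <- function(...) {
  sim_config(n_cells = 20, trials_per_cue = 8, ...)
}

# cached late-stage session used by several files
fixture_env <- new.env()

small_session <- function() {
  if (is.null(fixture_env$sess)) {
    cfg <- small_config()
    truth <- sample_ground_truth(cfg, stage = 1, seed = 42)
    fixture_env$sess <- c(generate_session(cfg, truth, seed = 42),
                          list(truth = truth, config = cfg))
  }
  fixture_env$sess
}

# hand-buildable toy session: deterministic frame clock and events
toy_session <- function(lick_times = numeric(0), n_plus = 2, n_minus = 2,
                        frame_rate = 23 / 3, iti = 25) {
  onsets <- 30 + (seq_len(n_plus + n_minus) - 1) * (3 + iti)
  identity <- rep(c("CS+", "CS-"), length.out = n_plus + n_minus)
  end <- max(onsets) + 15
  new_session_record(
    mouse_id = "toy", session_index = 1L,
    cue_events = data.frame(onset_s = onsets, offset_s = onsets + 2,
                            identity = identity),
    reward_times_s = onsets[identity == "CS+"] + 3,
    lick_times_s = sort(lick_times),
    frame_times_s = seq(0, end, by = 1 / frame_rate)
  )
}

# brute-force normalized auROC oracle: exhaustive pairwise comparison
oracle_auroc <- function(pos, neg) {
  u <- 0
  for (p in pos) for (n in neg) {
    u <- u + (p > n) + 0.5 * (p == n)
  }
  2 * (u / (length(pos) * length(neg)) - 0.5)
}
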
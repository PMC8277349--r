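test_that("baseline z-scoring gives mean 0, sd 1 baselines and scale invariance", {
  s <- small_session()
  tn <- normalize_traces(s$traces, s$record)
  ft <- s$record$frame_times_s
  idx <- unlist(lapply(s$record$cue_events$onset_s, function(on) {
    cs <- which(ft >= on)[1]
    (cs - 23):(cs - 1)
  }))
  idx <- sort(unique(idx))
  base <- tn$values[, idx]
  expect_lt(max(abs(rowMeans(base))), 1e-10)
  expect_lt(max(abs(apply(base, 1, sd) - 1)), 1e-10)
  # two cells differing only by gain normalize identically
  tr2 <- s$traces
  tr2$values[2, ] <- 3.5 * tr2$values[1, ]
  tn2 <- normalize_traces(tr2, s$record)
  expect_equal(tn2$values[2, ], tn2$values[1, ], tolerance = 1e-10)
  # zero-variance baseline names the cell
  tr3 <- s$traces
  tr3$values[4, ] <- 2
  expect_error(normalize_traces(tr3, s$record), tr3$cell_ids[4], fixed = TRUE)
})

test_that("hand-computed z-score matches on a toy trace", {
  rec <- toy_session(n_plus = 1, n_minus = 1)
  n <- length(rec$frame_times_s)
  set.seed(2)
  v <- matrix(rnorm(2 * n), nrow = 2)
  tm <- new_trace_matrix(c("a", "b"), v, 23 / 3)
  tn <- normalize_traces(tm, rec)
  ft <- rec$frame_times_s
  idx <- sort(unique(unlist(lapply(rec$cue_events$onset_s, function(on) {
    cs <- which(ft >= on)[1]; (cs - 23):(cs - 1)
  }))))
  manual <- (v[1, ] - mean(v[1, idx])) / sd(v[1, idx])
  expect_equal(tn$values[1, ], manual, tolerance = 1e-12)
})

test_that("trial alignment yields 69 frames matching a frame-index oracle", {
  s <- small_session()
  tn <- normalize_traces(s$traces, s$record)
  tp <- extract_trials(tn, s$record, "CS+")
  expect_equal(dim(tp)[3], 69)
  expect_equal(dim(tp)[2], 8)
  expect_identical(attr(tp, "epochs"),
                   list(baseline = 1:23, cue = 24:46, outcome = 47:69))
  # brute-force timestamp search oracle for the first two trials
  ft <- s$record$frame_times_s
  tr <- session_trials(s$record)
  tr <- tr[tr$identity == "CS+", ]
  for (i in 1:2) {
    cs <- min(which(ft >= tr$onset_s[i]))
    os <- min(which(ft >= tr$outcome_s[i]))
    oracle <- tn$values[, c((cs - 23):(cs + 22), os:(os + 22))]
    expect_equal(tp[, i, ], unname(oracle))
  }
  # event exactly on a frame: first cue frame timestamp equals tone onset
  rec <- toy_session(n_plus = 1, n_minus = 1)
  on <- rec$cue_events$onset_s[1]
  cs <- min(which(rec$frame_times_s >= on))
  expect_equal(rec$frame_times_s[cs], on, tolerance = 1e-9)
})

test_that("truncated trials are dropped with a warning, never padded", {
  rec <- toy_session(n_plus = 2, n_minus = 1)
  short <- rec
  # cut the session just after the last CS+ onset
  last_on <- max(rec$cue_events$onset_s)
  keep <- rec$frame_times_s <= last_on + 1
  short$frame_times_s <- rec$frame_times_s[keep]
  v <- matrix(rnorm(2 * sum(keep)), nrow = 2)
  tm <- new_trace_matrix(c("a", "b"), v, 23 / 3)
  expect_warning(tp <- extract_trials(tm, short, "CS+"), "truncated")
  expect_equal(dim(tp)[2], 1)
  expect_equal(dim(tp)[3], 69)
})

test_that("response vectors concatenate CS+ then CS- means into 138 columns", {
  s <- small_session()
  rv <- session_response_vectors(s$record, s$traces)
  expect_equal(ncol(rv$vectors), 138)
  expect_equal(nrow(rv$vectors), 20)
  expect_true(all(is.finite(rv$vectors)))
  # single-trial tensors: vector equals that trial's frames
  tp1 <- rv$tensor_csplus[, 1, , drop = FALSE]
  tm1 <- rv$tensor_csminus[, 1, , drop = FALSE]
  attr(tp1, "cell_ids") <- attr(rv$tensor_csplus, "cell_ids")
  attr(tm1, "cell_ids") <- attr(rv$tensor_csminus, "cell_ids")
  v1 <- response_vectors(tp1, tm1)
  expect_equal(unname(v1[3, 1:69]), rv$tensor_csplus[3, 1, ])
  # trial order never affects the mean
  perm <- sample(dim(rv$tensor_csplus)[2])
  tpp <- rv$tensor_csplus[, perm, , drop = FALSE]
  attr(tpp, "cell_ids") <- attr(rv$tensor_csplus, "cell_ids")
  vp <- response_vectors(tpp, rv$tensor_csminus)
  expect_equal(vp, rv$vectors)
  # mismatched cells error
  bad <- rv$tensor_csminus
  attr(bad, "cell_ids") <- rev(attr(bad, "cell_ids"))
  expect_error(response_vectors(rv$tensor_csplus, bad), "different cells")
})

test_that("mean epoch response is cue/reward mean minus baseline mean", {
  arr <- array(0, dim = c(2, 3, 69))
  arr[1, , 24:69] <- 1 # step of +1 at cue onset
  tens <- structure(arr, identity = "CS+", cell_ids = c("a", "b"),
                    epochs = list(baseline = 1:23, cue = 24:46,
                                  outcome = 47:69),
                    class = c("trial_tensor", "array"))
  r <- mean_epoch_response(tens)
  expect_equal(unname(r), c(1, 0))
  # toy numeric check
  arr[2, 2, 1:23] <- 2
  arr[2, 2, 24:69] <- 5
  tens2 <- structure(arr, identity = "CS+", cell_ids = c("a", "b"),
                     epochs = attr(tens, "epochs"),
                     class = c("trial_tensor", "array"))
  expect_equal(unname(mean_epoch_response(tens2)["b"]), (5 - 2) / 3)
  expect_error(mean_epoch_response(tens, cells = "zz"), "zz")
})

test_that("noiseless motifs reproduce their configured gain pattern", {
  cfg <- sim_config(n_cells = 10, trials_per_cue = 4, noise_sd = 0,
                    drift_sd = 0, amplitude = 3, amplitude_sd = 0,
                    trial_gain_shape = 1e8, lick_gain_shape = 1e8,
                    motif_props = rep(0.2, 5))
  truth <- sample_ground_truth(cfg, stage = 1, seed = 4)
  s <- generate_session(cfg, truth, seed = 4)
  rv <- session_response_vectors(s$record, s$traces, normalize = "none")
  lib <- motif_library()
  # mid-epoch plateaus (skipping onset frames; the reward drive spans
  # only the first 2 s of the 3 s outcome epoch) ~ amplitude x gain
  mid_cue <- 30:45
  mid_out <- 53:62
  for (m in 1:5) {
    cells <- which(truth$cells$motif == m)
    prof <- colMeans(rv$vectors[cells, , drop = FALSE])
    expect_lt(abs(mean(prof[mid_cue]) - 3 * lib$cs_plus_cue_gain[m]),
              0.25, label = sprintf("motif %d CS+ cue", m))
    expect_lt(abs(mean(prof[69 + mid_cue]) - 3 * lib$cs_minus_cue_gain[m]),
              0.25, label = sprintf("motif %d CS- cue", m))
    if (lib$reward_gain[m] > 0) {
      expect_lt(abs(mean(prof[mid_out]) - 3 * lib$reward_gain[m]), 0.3,
                label = sprintf("motif %d reward", m))
    }
  }
})
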
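tracked_experiment <- function(stage_a = 1, stage_b = 1, n_cells = 40,
                               trials = 10, seed = 17, noise_sd = 1) {
  cfg <- sim_config(n_cells = n_cells, trials_per_cue = trials,
                    noise_sd = noise_sd)
  truth <- sample_ground_truth(cfg, stage = 1, seed = seed)
  ta <- truth; ta$stage <- stage_a
  tb <- truth; tb$stage <- stage_b
  a <- generate_session(cfg, ta, seed = seed + 1)
  b <- generate_session(cfg, tb, seed = seed + 2)
  rva <- session_response_vectors(a$record, a$traces)
  rvb <- session_response_vectors(b$record, b$traces)
  map <- data.frame(fov_id = "fov1", cell_id_a = truth$cells$cell_id,
                    cell_id_b = truth$cells$cell_id)
  list(map = map, truth = truth,
       tens_a = list(csplus = rva$tensor_csplus, csminus = rva$tensor_csminus),
       tens_b = list(csplus = rvb$tensor_csplus, csminus = rvb$tensor_csminus),
       session_b = b)
}

test_that("paired responses align tracked cells and handle edge cases", {
  te <- tracked_experiment()
  pr <- paired_epoch_responses(te$map, te$tens_a, te$tens_a)
  expect_equal(pr$csplus$response_a, pr$csplus$response_b)
  empty <- te$map[0, ]
  pr0 <- paired_epoch_responses(empty, te$tens_a, te$tens_b)
  expect_equal(nrow(pr0$csplus), 0)
  bad <- te$map
  bad$cell_id_b[1] <- "ghost"
  expect_error(paired_epoch_responses(bad, te$tens_a, te$tens_b), "ghost")
})

test_that("planted-stable sessions correlate across days; shuffling collapses it", {
  te <- tracked_experiment(stage_a = 1, stage_b = 1)
  pr <- paired_epoch_responses(te$map, te$tens_a, te$tens_b)
  st <- stability_correlation(pr$csplus)
  expect_gt(st$r, 0.7)
  expect_lt(st$p, 0.001)
  # identical input: r exactly 1
  pr_id <- paired_epoch_responses(te$map, te$tens_a, te$tens_a)
  expect_equal(stability_correlation(pr_id$csplus)$r, 1)
  # within-FOV identity shuffle: correlation collapses towards zero
  rs <- vapply(1:20, function(i) {
    sm <- suppressWarnings(shuffle_within_fov(te$map, seed = i))
    prs <- paired_epoch_responses(sm, te$tens_a, te$tens_b)
    stability_correlation(prs$csplus)$r
  }, numeric(1))
  expect_lt(stats::quantile(rs, 0.975), st$r)
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("independent responses give near-zero stability correlation", {
  set.seed(6)
  n <- 200
  pairs <- data.frame(response_a = rnorm(n), response_b = rnorm(n))
  st <- stability_correlation(pairs)
  expect_lt(abs(st$r), 2 / sqrt(n))
  const <- data.frame(response_a = rep(1, 5), response_b = rnorm(5))
  expect_equal(stability_correlation(const)$flag, "constant")
  expect_error(stability_correlation(pairs[1:2, ]), ">= 3")
})

test_that("shuffle_within_fov permutes inside FOVs only, as a derangement", {
  map <- data.frame(fov_id = rep(c("A", "B"), c(6, 4)),
                    cell_id_a = sprintf("a%02d", 1:10),
                    cell_id_b = sprintf("b%02d", 1:10))
  sh <- shuffle_within_fov(map, seed = 3)
  # never mixes FOVs
  expect_setequal(sh$cell_id_b[sh$fov_id == "A"],
                  map$cell_id_b[map$fov_id == "A"])
  expect_setequal(sh$cell_id_b[sh$fov_id == "B"],
                  map$cell_id_b[map$fov_id == "B"])
  # derangement: no pair keeps its partner
  expect_true(all(sh$cell_id_b != map$cell_id_b))
  # reproducible
  expect_identical(sh, shuffle_within_fov(map, seed = 3))
  # two-pair FOV: the unique swap
  map2 <- map[map$fov_id == "B", ][1:2, ]
  sh2 <- shuffle_within_fov(map2, seed = 1)
  expect_equal(sh2$cell_id_b, rev(map2$cell_id_b))
  # single-pair FOV left unshuffled with warning
  map1 <- map[1, ]
  expect_warning(sh1 <- shuffle_within_fov(map1, seed = 1), "single pair")
  expect_identical(sh1, map1)
})

test_that("trial-block correlation is high for stationary responses", {
  te <- tracked_experiment(trials = 20, n_cells = 50)
  tb <- trial_block_correlation(te$tens_b$csplus, block_size = 10)
  expect_gt(tb$r, 0.6)
  expect_lt(tb$p, 0.001)
  # block-randomized responses: correlation near zero
  arr <- te$tens_b$csplus
  set.seed(8)
  arr2 <- array(rnorm(length(arr)), dim = dim(arr))
  attributes(arr2) <- attributes(arr)
  tb0 <- trial_block_correlation(arr2, block_size = 10)
  expect_lt(abs(tb0$r), 0.3)
  expect_error(trial_block_correlation(te$tens_b$csplus, block_size = 11),
               "too large")
})

test_that("response evolution isolates the learning-dependent clusters", {
  te <- tracked_experiment(stage_a = 0, stage_b = 1, n_cells = 80,
                           trials = 15, seed = 23)
  labels <- stats::setNames(te$truth$cells$motif, te$truth$cells$cell_id)
  ev <- response_evolution(te$map, te$tens_a, te$tens_b, labels)
  an <- ev$anova
  # motif 1 is stage-independent: no session effect
  expect_gt(an$p_phase[an$cluster == 1], 0.05)
  # motifs 2-4 strengthen with learning (motif 5 tested by direction)
  for (k in 2:4) {
    expect_lt(an$p_phase[an$cluster == k], 0.01)
    expect_gt(an$direction[an$cluster == k], 0)
  }
  expect_lt(an$direction[an$cluster == 5], 0) # inhibition deepens
  # empty map gives empty tables
  ev0 <- response_evolution(te$map[0, ], te$tens_a, te$tens_b, labels)
  expect_equal(nrow(ev0$responses), 0)
})

test_that("optimal lags match brute force and planted shifts", {
  set.seed(12)
  x <- as.numeric(stats::filter(rnorm(600), 0.7, method = "recursive"))
  shift <- 3
  y <- c(rep(0, shift), x[1:(600 - shift)]) # y follows x by 3 frames
  fr <- 23 / 3
  expect_equal(pair_optimal_lag(x, y, max_lag = 20, frame_rate_hz = fr),
               shift / fr)
  expect_equal(pair_optimal_lag(y, x, max_lag = 20, frame_rate_hz = fr),
               -shift / fr)
  expect_equal(pair_optimal_lag(x, x, max_lag = 20, frame_rate_hz = fr), 0)
})

test_that("lag matrix shows tighter lags within than between ensembles", {
  te <- tracked_experiment(n_cells = 50, trials = 12, seed = 29)
  b <- te$session_b
  tn <- normalize_traces(b$traces, b$record)
  labels <- stats::setNames(te$truth$cells$motif, te$truth$cells$cell_id)
  lm <- cross_correlation_lags(tn, labels, max_lag_s = 5)
  d <- diag(lm$abs_lag_s)
  off <- lm$abs_lag_s[upper.tri(lm$abs_lag_s) | lower.tri(lm$abs_lag_s)]
  expect_lt(mean(d, na.rm = TRUE), mean(off, na.rm = TRUE))
  # antisymmetry of the signed means up to averaging noise
  expect_lt(max(abs(lm$lag_s + t(lm$lag_s)), na.rm = TRUE), 1.5)
  # a flat trace is skipped with a warning
  tr2 <- b$traces
  tr2$values[1, ] <- 5
  expect_warning(
    cross_correlation_lags(new_trace_matrix(tr2$cell_ids, tr2$values,
                                            tr2$frame_rate_hz),
                           labels, max_lag_s = 2),
    "flat")
})

test_that("FFT pair lags agree with the brute-force search", {
  set.seed(33)
  fr <- 23 / 3
  for (i in 1:20) {
    x <- as.numeric(stats::filter(rnorm(400), 0.8, method = "recursive"))
    s <- sample(-10:10, 1)
    y <- if (s >= 0) c(rep(0, s), x[1:(400 - s)]) else
      c(x[(1 - s):400], rep(0, -s))
    y <- y + rnorm(400, sd = 0.1)
    tm <- new_trace_matrix(c("x", "y"), rbind(x, y), fr)
    lm <- suppressWarnings(
      cross_correlation_lags(tm, c(x = 1, y = 2), max_lag_s = 2,
                             clusters = 1:2))
    expect_equal(lm$lag_s["cluster1", "cluster2"],
                 pair_optimal_lag(x, y, max_lag = round(2 * fr),
                                  frame_rate_hz = fr),
                 tolerance = 1e-9, label = sprintf("shift %d", s))
  }
})
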
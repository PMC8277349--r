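make_blobs <- function(centers, n_per, sd = 0.05, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), ncol = ncol(centers)) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

centered_orthobasis <- function(n, k, seed) {
  # orthonormal, column-centered basis so PCA sees the planted spectrum
  set.seed(seed)
  z <- scale(matrix(rnorm(n * (k + 1)), n), center = TRUE, scale = FALSE)
  qr.Q(qr(z))[, 1:k]
}

test_that("scree elbow finds the rank of a stepped spectrum", {
  # exactly r identical large singular values then (near) zeros -> r
  for (r in c(2, 4, 6)) {
    u <- centered_orthobasis(60, 10, seed = r)
    v <- qr.Q(qr(matrix(rnorm(30 * 30), 30)))[, 1:10]
    d <- c(rep(10, r), rep(1e-8, 10 - r))
    x <- u %*% diag(d) %*% t(v)
    expect_equal(scree_components(x), r)
  }
  # single dominant component + full-rank isotropic noise floor -> 1
  u <- centered_orthobasis(50, 25, seed = 9)
  v <- qr.Q(qr(matrix(rnorm(25 * 25), 25)))
  x1 <- u %*% diag(c(50, rep(1, 24))) %*% t(v)
  expect_equal(scree_components(x1), 1)
  # rank-1 input
  x2 <- outer(1:20, rnorm(10))
  expect_equal(scree_components(x2 + 0), 1)
  expect_error(scree_components(x2[1, , drop = FALSE]), "2 cells")
})

test_that("well-separated clouds are perfectly separated by every algorithm", {
  b <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 30)
  for (alg in c("spectral", "agglomerative", "kmeans")) {
    m <- fit_clustering(b$x, alg, n_clusters = 2, n_neighbors = 8, seed = 1)
    expect_equal(mclust::adjustedRandIndex(m$labels, b$truth), 1,
                 label = alg)
    expect_gt(m$silhouette, 0.9)
  }
})

test_that("clustering is deterministic given a seed", {
  b <- make_blobs(rbind(c(0, 0), c(5, 0), c(0, 5)), 25, sd = 0.5)
  m1 <- fit_clustering(b$x, "spectral", 3, n_neighbors = 10, seed = 7)
  m2 <- fit_clustering(b$x, "spectral", 3, n_neighbors = 10, seed = 7)
  expect_identical(m1$labels, m2$labels)
})

test_that("three Gaussian blobs match a nearest-centroid oracle", {
  b <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 20, sd = 0.3)
  m <- fit_clustering(b$x, "spectral", 3, n_neighbors = 8, seed = 2)
  # brute-force assignment: each point joins its nearest true-centroid
  centers <- rowsum(b$x, b$truth) / 20
  oracle <- apply(b$x, 1, function(p) {
    which.min(colSums((t(centers) - p)^2))
  })
  expect_equal(mclust::adjustedRandIndex(m$labels, oracle), 1)
})

test_that("spectral clustering errors when the graph is too fragmented", {
  b <- make_blobs(rbind(c(0, 0), c(50, 0), c(0, 50), c(50, 50)), 8,
                  sd = 0.01)
  expect_error(fit_clustering(b$x, "spectral", 2, n_neighbors = 3, seed = 1),
               "n_neighbors")
  expect_error(fit_clustering(b$x, "spectral", 2, n_neighbors = 40, seed = 1),
               "< number of cells")
})

test_that("silhouette selection picks the planted cluster count", {
  b <- make_blobs(rbind(c(0, 0), c(8, 0)), 30, sd = 0.4)
  m <- select_hyperparameters(b$x, k_range = 2:6, nn_range = c(5, 10),
                              seed = 1)
  expect_equal(m$n_clusters, 2L)
  grid <- attr(m, "grid")
  # the selected model's silhouette is the grid maximum by construction
  expect_equal(m$silhouette, max(grid$silhouette, na.rm = TRUE))
  # grid of one point returns that fit
  m1 <- select_hyperparameters(b$x, k_range = 3, nn_range = 10, seed = 1)
  expect_equal(m1$n_clusters, 3L)
})

test_that("algorithm comparison reports silhouettes and label agreement", {
  b <- make_blobs(rbind(c(0, 0), c(9, 0), c(0, 9)), 20, sd = 0.3)
  cmp <- compare_algorithms(b$x, k_range = 2:4, nn_range = c(5, 10), seed = 1)
  expect_setequal(cmp$summary$algorithm,
                  c("spectral", "agglomerative", "kmeans"))
  expect_true(all(cmp$summary$silhouette >= -1 & cmp$summary$silhouette <= 1))
  # identical blob structure: all algorithms agree perfectly
  expect_true(all(cmp$ari == 1))
})

test_that("canonicalization recovers motif identities and ignores label order", {
  s <- small_session()
  cfg <- sim_config(n_cells = 150, trials_per_cue = 20,
                    motif_props = rep(0.2, 5))
  truth <- sample_ground_truth(cfg, stage = 1, seed = 31)
  sess <- generate_session(cfg, truth, seed = 31)
  rv <- session_response_vectors(sess$record, sess$traces)
  m <- fit_clustering(rv$vectors, "spectral", 5, n_neighbors = 10, seed = 1)
  cm <- canonicalize_clusters(m, rv$vectors)
  agree <- mean(cm$labels == truth$cells$motif)
  expect_gt(agree, 0.95)
  # already-canonical labels map to themselves
  cm2 <- canonicalize_clusters(cm, rv$vectors)
  expect_identical(cm2$labels, cm$labels)
  # a permuted labelling canonicalizes to the same result
  perm <- c(3L, 5L, 1L, 2L, 4L)
  mp <- m
  mp$labels <- stats::setNames(perm[m$labels], names(m$labels))
  cmp <- canonicalize_clusters(mp, rv$vectors)
  expect_identical(cmp$labels, cm$labels)
})

test_that("ensemble_fit methods behave like a fitted model object", {
  cfg <- sim_config(n_cells = 120, trials_per_cue = 15,
                    motif_props = rep(0.2, 5))
  truth <- sample_ground_truth(cfg, stage = 1, seed = 8)
  sess <- generate_session(cfg, truth, seed = 8)
  rv <- session_response_vectors(sess$record, sess$traces)
  fit <- suppressWarnings(
    fit_ensembles(rv$vectors, k_range = 2:6, nn_range = c(5, 10), seed = 1))
  expect_s3_class(fit, "ensemble_fit")
  expect_output(print(fit), "clusters")
  sm <- summary(fit)
  expect_equal(sum(sm$table$n_cells), 120)
  expect_identical(fitted(fit), fit$labels)
  # predict assigns the training cells back to their own clusters
  pred <- predict(fit, rv$vectors)
  expect_gt(mean(pred == fit$labels), 0.98)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})

test_that("ensemble-behaviour correlations detect a planted relationship", {
  set.seed(5)
  n_fov <- 12
  prop <- cbind(
    cluster1 = runif(n_fov, 0.1, 0.3),
    cluster2 = runif(n_fov, 0.1, 0.3),
    cluster5 = runif(n_fov, 0.05, 0.45)
  )
  scores <- 0.2 + 1.5 * prop[, "cluster5"] + rnorm(n_fov, sd = 0.03)
  out <- ensemble_behavior_correlation(prop, scores)
  expect_lt(out$p[out$cluster == "cluster5"], 0.05)
  expect_gt(out$r[out$cluster == "cluster5"], 0.8)
  expect_true(all(out$p[out$cluster != "cluster5"] > 0.05))
  # constant proportions flagged, not errored
  prop2 <- prop; prop2[, 1] <- 0.2
  out2 <- ensemble_behavior_correlation(prop2, scores)
  expect_equal(out2$flag[1], "constant")
  expect_true(is.na(out2$r[1]))
  expect_error(ensemble_behavior_correlation(prop[1:2, ], scores[1:2]),
               ">= 3 FOVs")
})

test_that("cluster proportions are per-FOV cell fractions", {
  labels <- c(a1 = 1, a2 = 1, a3 = 2, b1 = 2, b2 = 2)
  fov <- c("A", "A", "A", "B", "B")
  p <- cluster_proportions(labels, fov, clusters = 1:2)
  expect_equal(unname(p["A", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(p["B", ]), c(0, 1))
})
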
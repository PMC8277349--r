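#' Number of principal components at the scree-plot elbow
#'
#' Computes the cumulative variance-explained curve of a PCA of the
#' response vectors and returns the component count at its inflection,
#' located as the point of maximum perpendicular distance from the curve
#' to the chord joining its endpoints (axes normalized to \[0, 1\]).
#'
#' @param vectors Numeric matrix, cells x features (e.g. cells x 138).
#' @return Integer number of components (>= 1).
#' @export
scree_components <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop_validation("need at least 2 cells")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  k_max <- length(v)
  if (k_max <= 1) return(1L)
  cumvar <- cumsum(v) / sum(v)
  x <- (seq_len(k_max) - 1) / (k_max - 1)
  if (cumvar[k_max] - cumvar[1] <= 0) return(1L)
  y <- (cumvar - cumvar[1]) / (cumvar[k_max] - cumvar[1])
  d <- y - x
  # ties (flat spectra) resolve to the smallest component count
  as.integer(which(d >= max(d) - 1e-9)[1])
}

#' @noRd
knn_affinity <- function(scores, n_neighbors) {
  n <- nrow(scores)
  if (n_neighbors >= n) stop_validation("n_neighbors must be < number of cells")
  d <- as.matrix(stats::dist(scores))
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1L)]
    a[i, nb] <- 1
  }
  a <- pmax(a, t(a)) # symmetrized k-NN connectivity
  diag(a) <- 0
  a
}

#' Count connected components of an adjacency matrix (BFS)
#' @noRd
graph_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(a[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

#' Spectral embedding of a symmetrized k-NN graph
#'
#' Top eigenvectors of the normalized affinity D^-1/2 A D^-1/2
#' (equivalently the smallest eigenvectors of the symmetric normalized
#' Laplacian), for use by embedding k-means.
#' @noRd
spectral_embedding <- function(scores, n_neighbors, k_max) {
  a <- knn_affinity(scores, n_neighbors)
  ncomp <- graph_components(a)
  deg <- rowSums(a)
  if (any(deg == 0)) {
    stop_validation("k-NN graph has isolated nodes; increase n_neighbors")
  }
  dhalf <- 1 / sqrt(deg)
  m <- a * (dhalf %o% dhalf)
  e <- eigen(m, symmetric = TRUE)
  list(vectors = e$vectors[, seq_len(min(k_max, ncol(e$vectors))), drop = FALSE],
       n_graph_components = ncomp)
}

#' @noRd
embedding_kmeans <- function(emb, k, seed) {
  u <- emb[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm == 0] <- 1
  u <- u / nrm
  with_seed(seed, stats::kmeans(u, centers = k, nstart = 10, iter.max = 100))$cluster
}

#' @noRd
mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(as.integer(labels), d)[, "sil_width"])
}

#' Fit one clustering of response vectors
#'
#' Projects the cells x 138 response vectors onto their leading principal
#' components (count chosen by [scree_components()] unless given) and runs
#' the requested clustering algorithm in that subspace. Spectral
#' clustering uses a symmetrized k-nearest-neighbour connectivity graph,
#' the normalized graph Laplacian, and k-means on the row-normalized
#' spectral embedding; agglomerative uses Ward linkage; k-means runs
#' directly on the PCA scores. The silhouette is computed in the same PCA
#' subspace. Deterministic given `seed`.
#'
#' @param vectors Cells x features matrix (rownames = cell IDs).
#' @param algorithm `"spectral"`, `"agglomerative"` or `"kmeans"`.
#' @param n_clusters Number of clusters (>= 2).
#' @param n_neighbors Neighbours for the spectral graph (spectral only).
#' @param seed Integer seed for the embedding k-means step.
#' @param n_components PCA dimensionality; default from
#'   [scree_components()].
#' @return An object of class `cluster_model`: list with `algorithm`,
#'   `n_components`, `n_clusters`, `n_neighbors`, `labels` (named 1-based
#'   integers), `silhouette`, `embedding` (PCA scores), `center`,
#'   `rotation`, `seed`.
#' @export
fit_clustering <- function(vectors, algorithm = c("spectral", "agglomerative",
                                                  "kmeans"),
                           n_clusters = 5, n_neighbors = 10, seed = 1,
                           n_components = NULL) {
  algorithm <- match.arg(algorithm)
  vectors <- as.matrix(vectors)
  if (n_clusters < 2) stop_validation("n_clusters must be >= 2")
  if (n_clusters > nrow(vectors) - 1) stop_validation("n_clusters too large")
  n_components <- n_components %||% scree_components(vectors)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  labels <- switch(algorithm,
    spectral = {
      emb <- spectral_embedding(scores, n_neighbors, n_clusters)
      if (emb$n_graph_components > n_clusters) {
        stop_validation(paste0(
          "k-NN graph splits into %d components for %d clusters; ",
          "increase n_neighbors"), emb$n_graph_components, n_clusters)
      }
      embedding_kmeans(emb$vectors, n_clusters, seed)
    },
    agglomerative = stats::cutree(stats::hclust(stats::dist(scores),
                                                method = "ward.D2"),
                                  k = n_clusters),
    kmeans = with_seed(seed, stats::kmeans(scores, centers = n_clusters,
                                           nstart = 10, iter.max = 100))$cluster
  )
  names(labels) <- rownames(vectors)
  structure(list(
    algorithm = algorithm, n_components = n_components,
    n_clusters = as.integer(n_clusters),
    n_neighbors = if (algorithm == "spectral") as.integer(n_neighbors) else NA_integer_,
    labels = labels,
    silhouette = mean_silhouette(labels, stats::dist(scores)),
    embedding = scores, center = pc$center,
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
    seed = seed
  ), class = "cluster_model")
}

#' Silhouette-optimized hyperparameter selection
#'
#' Evaluates the clustering over a grid of cluster counts (and, for
#' spectral clustering, neighbour counts) and returns the model with the
#' maximum mean silhouette score; ties are broken towards fewer clusters,
#' then fewer neighbours. For spectral clustering the graph affinity and
#' its eigendecomposition are computed once per neighbour count and shared
#' across cluster counts.
#'
#' @param vectors Cells x features matrix.
#' @param k_range Candidate cluster counts (default 2-10).
#' @param nn_range Candidate neighbour counts (default 5, 10, 15, 20, 30,
#'   50); ignored by non-spectral algorithms.
#' @param algorithm As in [fit_clustering()].
#' @param seed Integer seed.
#' @param n_components PCA dimensionality; default from
#'   [scree_components()].
#' @return The best `cluster_model`, with the full grid as attribute
#'   `"grid"` (data frame: `n_clusters`, `n_neighbors`, `silhouette`).
#' @export
select_hyperparameters <- function(vectors, k_range = 2:10,
                                   nn_range = c(5, 10, 15, 20, 30, 50),
                                   algorithm = c("spectral", "agglomerative",
                                                 "kmeans"),
                                   seed = 1, n_components = NULL) {
  algorithm <- match.arg(algorithm)
  vectors <- as.matrix(vectors)
  if (length(k_range) == 0) stop_validation("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  n_components <- n_components %||% scree_components(vectors)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  d <- stats::dist(scores)
  if (length(nn_range) == 0) stop_validation("nn_range is empty")
  nn_range <- sort(unique(nn_range))
  if (algorithm != "spectral") nn_range <- NA_integer_

  grid <- expand.grid(n_clusters = k_range, n_neighbors = nn_range)
  grid$silhouette <- NA_real_
  grid$error <- NA_character_
  all_labels <- vector("list", nrow(grid))

  if (algorithm == "agglomerative") {
    hc <- stats::hclust(d, method = "ward.D2")
  }
  for (nn in nn_range) {
    rows <- which(grid$n_neighbors %in% nn | is.na(grid$n_neighbors))
    emb <- NULL
    if (algorithm == "spectral") {
      emb <- tryCatch(spectral_embedding(scores, nn, max(k_range)),
                      error = function(e) e)
      if (inherits(emb, "error")) {
        grid$error[rows] <- conditionMessage(emb)
        next
      }
    }
    for (r in rows) {
      k <- grid$n_clusters[r]
      res <- tryCatch({
        labels <- switch(algorithm,
          spectral = {
            if (emb$n_graph_components > k) {
              stop_validation("k-NN graph splits into %d components for %d clusters",
                              emb$n_graph_components, k)
            }
            embedding_kmeans(emb$vectors, k, seed)
          },
          agglomerative = stats::cutree(hc, k = k),
          kmeans = with_seed(seed, stats::kmeans(scores, centers = k,
                                                 nstart = 10,
                                                 iter.max = 100))$cluster
        )
        list(labels = labels, sil = mean_silhouette(labels, d))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        grid$error[r] <- conditionMessage(res)
      } else {
        grid$silhouette[r] <- res$sil
        all_labels[[r]] <- res$labels
      }
    }
  }
  if (all(is.na(grid$silhouette))) {
    stop_validation("all grid points failed: %s",
                    paste(unique(stats::na.omit(grid$error)), collapse = "; "))
  }
  ord <- order(-grid$silhouette, grid$n_clusters, grid$n_neighbors,
               na.last = TRUE)
  best <- ord[1]
  labels <- all_labels[[best]]
  names(labels) <- rownames(vectors)
  model <- structure(list(
    algorithm = algorithm, n_components = n_components,
    n_clusters = as.integer(grid$n_clusters[best]),
    n_neighbors = as.integer(grid$n_neighbors[best]),
    labels = labels, silhouette = grid$silhouette[best],
    embedding = scores, center = pc$center,
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
    seed = seed
  ), class = "cluster_model")
  attr(model, "grid") <- grid[, c("n_clusters", "n_neighbors", "silhouette")]
  model
}

#' Compare clustering algorithms on the same data
#'
#' Runs silhouette-optimized selection for spectral, agglomerative and
#' k-means clustering and reports the best silhouette per algorithm plus
#' the pairwise adjusted Rand index between the selected labelings.
#'
#' @inheritParams select_hyperparameters
#' @return List: `summary` (data frame: algorithm, n_clusters,
#'   n_neighbors, silhouette), `ari` (3 x 3 matrix), `models` (named list
#'   of `cluster_model`s).
#' @export
compare_algorithms <- function(vectors, k_range = 2:10,
                               nn_range = c(5, 10, 15, 20, 30, 50), seed = 1,
                               n_components = NULL) {
  algos <- c("spectral", "agglomerative", "kmeans")
  models <- lapply(algos, function(a) {
    select_hyperparameters(vectors, k_range, nn_range, algorithm = a,
                           seed = seed, n_components = n_components)
  })
  names(models) <- algos
  ari <- matrix(1, 3, 3, dimnames = list(algos, algos))
  for (i in 1:2) for (j in (i + 1):3) {
    ari[i, j] <- ari[j, i] <-
      mclust::adjustedRandIndex(models[[i]]$labels, models[[j]]$labels)
  }
  summary <- data.frame(
    algorithm = algos,
    n_clusters = vapply(models, function(m) m$n_clusters, integer(1)),
    n_neighbors = vapply(models, function(m) m$n_neighbors, integer(1)),
    silhouette = vapply(models, function(m) m$silhouette, numeric(1))
  )
  rownames(summary) <- NULL
  list(summary = summary, ari = ari, models = models)
}

#' @noRd
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Relabel clusters by canonical ensemble identity
#'
#' Renumbers fitted clusters 1-5 by greedily matching each cluster's mean
#' response vector to the canonical motif templates (cosine similarity,
#' one-to-one). Clusters without a template match keep labels 6, 7, ...
#' The result is independent of the arbitrary label order returned by the
#' fitting algorithm.
#'
#' @param model A `cluster_model`.
#' @param vectors The cells x 138 response vectors the model was fit on.
#' @return The model with remapped `labels` and a `canonical_map`
#'   component (old label -> new label).
#' @export
canonicalize_clusters <- function(model, vectors) {
  stopifnot(inherits(model, "cluster_model"))
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 138) stop_validation("vectors must have 138 columns")
  tpl <- motif_templates()
  old <- sort(unique(model$labels))
  prof <- t(vapply(old, function(l) {
    colMeans(vectors[model$labels == l, , drop = FALSE])
  }, numeric(138)))
  sim <- matrix(NA_real_, length(old), 5,
                dimnames = list(as.character(old), rownames(tpl)))
  for (i in seq_along(old)) for (j in 1:5) {
    sim[i, j] <- cosine_sim(prof[i, ], tpl[j, ])
  }
  map <- rep(NA_integer_, length(old))
  s <- sim
  repeat {
    if (all(is.na(s))) break
    ij <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    map[ij[1]] <- ij[2]
    s[ij[1], ] <- NA
    s[, ij[2]] <- NA
  }
  unmatched <- which(is.na(map))
  if (length(unmatched) > 0) map[unmatched] <- 5L + seq_along(unmatched)
  new_labels <- map[match(model$labels, old)]
  names(new_labels) <- names(model$labels)
  model$labels <- new_labels
  model$canonical_map <- stats::setNames(map, old)
  model$canonical_similarity <- sim
  model
}

#' Cluster proportions per field of view
#'
#' @param labels Named integer labels over pooled cells.
#' @param fov Factor/character of the same length giving each cell's FOV.
#' @param clusters Cluster IDs to tabulate (default 1-5).
#' @return Matrix FOV x cluster of cell proportions.
#' @export
cluster_proportions <- function(labels, fov, clusters = 1:5) {
  stopifnot(length(labels) == length(fov))
  fov <- factor(fov)
  tab <- unclass(table(fov, factor(labels, levels = clusters)))
  prop <- tab / as.vector(table(fov)) # denominator: all cells in the FOV
  colnames(prop) <- paste0("cluster", clusters)
  prop
}

#' Correlate ensemble proportions with behavioural scores across FOVs
#'
#' For each cluster, Pearson correlation between the per-FOV proportion of
#' cells assigned to that cluster and the FOV's behavioural score (cue
#' discrimination or CS- error).
#'
#' @param proportions FOV x cluster matrix (e.g. [cluster_proportions()]).
#' @param scores Numeric behavioural score per FOV (same row order).
#' @return Data frame: `cluster`, `r`, `p`, `n`, `flag` (`"ok"` or
#'   `"constant"` where the correlation is undefined).
#' @export
ensemble_behavior_correlation <- function(proportions, scores) {
  proportions <- as.matrix(proportions)
  if (nrow(proportions) < 3) stop_validation("need >= 3 FOVs")
  if (nrow(proportions) != length(scores)) {
    stop_validation("scores must match proportion rows")
  }
  out <- lapply(seq_len(ncol(proportions)), function(j) {
    p <- proportions[, j]
    if (stats::sd(p) == 0 || stats::sd(scores) == 0) {
      data.frame(cluster = colnames(proportions)[j] %||% j, r = NA_real_,
                 p = NA_real_, n = length(p), flag = "constant")
    } else {
      ct <- stats::cor.test(p, scores)
      data.frame(cluster = colnames(proportions)[j] %||% j,
                 r = unname(ct$estimate), p = ct$p.value, n = length(p),
                 flag = "ok")
    }
  })
  do.call(rbind, out)
}
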
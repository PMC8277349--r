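#' Fit neuronal ensembles to a pooled population
#'
#' The package's central estimator. Takes the pooled cells x 138
#' trial-response vectors (mean CS+ PSTH concatenated with mean CS- PSTH,
#' see [response_vectors()]), projects them onto the leading principal
#' components at the scree-plot elbow, selects spectral-clustering
#' hyperparameters (cluster count and neighbour count) by maximum mean
#' silhouette, and renumbers the resulting clusters against the five
#' canonical ensemble motifs.
#'
#' @param x Cells x 138 response-vector matrix (rownames = cell IDs).
#' @param k_range,nn_range,algorithm,seed,n_components Passed to
#'   [select_hyperparameters()].
#' @param canonicalize Match cluster numbers to canonical motifs
#'   (default `TRUE`).
#' @return An object of class `ensemble_fit` with components `model`
#'   (the selected `cluster_model`), `labels`, `silhouette`, `profiles`
#'   (per-cluster mean CS+/CS- PSTHs and sizes), `grid`, and the matched
#'   `canonical_map` when canonicalized.
#' @seealso [predict.ensemble_fit()], [plot.ensemble_fit()]
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cells = 80, trials_per_cue = 8)
#' s <- generate_session(cfg, seed = 2)
#' rv <- session_response_vectors(s$record, s$traces)
#' fit <- fit_ensembles(rv$vectors, k_range = 2:6, nn_range = c(5, 10), seed = 1)
#' print(fit)
#' }
#' @export
fit_ensembles <- function(x, k_range = 2:10, nn_range = c(5, 10, 15, 20, 30, 50),
                          algorithm = "spectral", seed = 1,
                          n_components = NULL, canonicalize = TRUE) {
  x <- as.matrix(x)
  model <- select_hyperparameters(x, k_range = k_range, nn_range = nn_range,
                                  algorithm = algorithm, seed = seed,
                                  n_components = n_components)
  if (canonicalize && ncol(x) == 138) model <- canonicalize_clusters(model, x)
  ids <- sort(unique(model$labels))
  profiles <- lapply(ids, function(l) {
    v <- colMeans(x[model$labels == l, , drop = FALSE])
    list(cluster_id = l, n_cells = sum(model$labels == l),
         mean_psth_csplus = unname(v[1:69]),
         mean_psth_csminus = unname(v[70:138]))
  })
  names(profiles) <- paste0("cluster", ids)
  structure(list(
    model = model, labels = model$labels, silhouette = model$silhouette,
    n_clusters = model$n_clusters, n_neighbors = model$n_neighbors,
    n_components = model$n_components, profiles = profiles,
    grid = attr(model, "grid"), canonical_map = model$canonical_map,
    vectors = x, call = match.call()
  ), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Neuronal ensemble fit (", x$model$algorithm, " clustering)\n", sep = "")
  cat(sprintf("  cells: %d   PCA components: %d\n",
              length(x$labels), x$n_components))
  cat(sprintf("  selected: %d clusters, %s neighbours (silhouette %.3f)\n",
              x$n_clusters,
              ifelse(is.na(x$n_neighbors), "-", x$n_neighbors),
              x$silhouette))
  sizes <- table(x$labels)
  cat("  cluster sizes:",
      paste(sprintf("%s=%d", names(sizes), as.integer(sizes)), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  d <- stats::dist(object$model$embedding)
  sil <- cluster::silhouette(as.integer(object$labels), d)
  per <- tapply(sil[, "sil_width"], object$labels, mean)
  out <- data.frame(
    cluster = as.integer(names(table(object$labels))),
    n_cells = as.integer(table(object$labels)),
    proportion = as.numeric(table(object$labels)) / length(object$labels),
    silhouette = as.numeric(per)
  )
  structure(list(table = out, silhouette = object$silhouette,
                 n_clusters = object$n_clusters,
                 n_neighbors = object$n_neighbors,
                 grid = object$grid),
            class = "summary.ensemble_fit")
}

#' @export
print.summary.ensemble_fit <- function(x, ...) {
  cat(sprintf("Selected %d clusters (silhouette %.3f)\n\n",
              x$n_clusters, x$silhouette))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cluster labels of a fitted ensemble model
#' @param object An `ensemble_fit`.
#' @param ... Unused.
#' @return Named integer vector of cluster labels.
#' @export
fitted.ensemble_fit <- function(object, ...) object$labels

#' Assign new cells to fitted ensembles
#'
#' Projects new 138-element response vectors into the fit's PCA subspace
#' and assigns each to the cluster with the nearest centroid.
#'
#' @param object An `ensemble_fit`.
#' @param newdata Cells x 138 matrix.
#' @param ... Unused.
#' @return Named integer vector of cluster labels.
#' @export
predict.ensemble_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  m <- object$model
  scores <- sweep(newdata, 2, m$center) %*% m$rotation
  ids <- sort(unique(m$labels))
  centroids <- t(vapply(ids, function(l) {
    colMeans(m$embedding[m$labels == l, , drop = FALSE])
  }, numeric(ncol(m$embedding))))
  d <- outer(rowSums(scores^2), rowSums(centroids^2), "+") -
    2 * scores %*% t(centroids)
  lab <- ids[apply(d, 1, which.min)]
  stats::setNames(lab, rownames(newdata))
}

#' Plot mean ensemble response profiles
#'
#' One panel per cluster showing the trial-averaged CS+ and CS- PSTHs
#' (69 frames each; dotted lines mark cue onset and the outcome epoch).
#'
#' @param x An `ensemble_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly `x`.
#' @export
plot.ensemble_fit <- function(x, ...) {
  prof <- x$profiles
  old <- graphics::par(mfrow = c(1, length(prof)), mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (p in prof) {
    graphics::matplot(cbind(p$mean_psth_csplus, p$mean_psth_csminus),
                      type = "l", lty = 1, col = c("firebrick", "steelblue"),
                      xlab = "frame", ylab = "z", ...)
    graphics::abline(v = c(23.5, 46.5), lty = 3, col = "grey50")
    graphics::title(sprintf("cluster %d (n=%d)", p$cluster_id, p$n_cells))
  }
  invisible(x)
}
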
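#' Pipeline configuration
#'
#' Validated, serializable configuration for [run_pipeline()]. Every
#' stochastic stage draws from `seed`; the configuration's MD5 hash is
#' recorded in every output so a report can be traced to its settings.
#'
#' @param seed Integer seed (required).
#' @param sim A [sim_config()] describing the synthetic experiment, or
#'   `NULL` to read sessions from `input_dir`.
#' @param n_mice,sessions_per_mouse Synthetic experiment shape.
#' @param input_dir Optional directory of sessions (see
#'   [load_dryad_dataset()]); used when `sim` is `NULL`.
#' @param k_range,nn_range Clustering grid.
#' @param n_folds,n_shuffles Decoder settings.
#' @param out_dir Output directory.
#' @param figures Whether to write PNG figures.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, sim = sim_config(n_cells = 60),
                            n_mice = 3, sessions_per_mouse = 2,
                            input_dir = NULL, k_range = 2:10,
                            nn_range = c(5, 10, 15, 20, 30, 50),
                            n_folds = 5, n_shuffles = 100,
                            out_dir = tempfile("ensembles_run_"),
                            figures = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_validation("pipeline config requires an explicit integer seed")
  }
  if (!is.null(sim)) validate_sim_config(sim)
  cfg <- structure(list(
    seed = as.integer(seed), sim = sim, n_mice = as.integer(n_mice),
    sessions_per_mouse = as.integer(sessions_per_mouse),
    input_dir = input_dir, k_range = as.integer(k_range),
    nn_range = as.integer(nn_range), n_folds = as.integer(n_folds),
    n_shuffles = as.integer(n_shuffles), out_dir = out_dir,
    figures = isTRUE(figures)
  ), class = "pipeline_config")
  cfg
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- config
  plain$out_dir <- NULL # identity of a run should not depend on where it lands
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full ensemble analysis
#'
#' Orchestrates the pipeline end to end: generate (or load) sessions,
#' score behaviour, build PSTHs, fit ensembles on the pooled late-phase
#' population, propagate labels to tracked early sessions, decode task
#' variables against shuffled nulls, and run the stability analyses.
#' Outputs (CSV/JSON, optional PNG figures) carry the configuration hash;
#' rerunning with the same configuration reproduces them exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `behavior`, `fit` (the `ensemble_fit`),
#'   `decoding`, `stability`, `lags`, `out_dir`, `config_hash`. Stage
#'   failures are reported with the stage name; earlier outputs are kept.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  exp <- stage("data", {
    if (!is.null(config$sim)) {
      generate_experiment(config$sim, n_mice = config$n_mice,
                          sessions_per_mouse = config$sessions_per_mouse,
                          seed = config$seed)
    } else {
      loaded <- load_dryad_dataset(config$input_dir)
      structure(list(sessions = lapply(loaded$sessions, function(s) {
        list(mouse_id = s$record$mouse_id,
             session_index = s$record$session_index,
             stage = NA_real_, record = s$record, traces = s$traces)
      }), truths = NULL, config = NULL, seed = config$seed),
      class = "ensemble_experiment")
    }
  })

  behavior <- stage("behavior", {
    b <- do.call(rbind, lapply(exp$sessions, function(s) behavior_score(s$record)))
    b$config_hash <- hash
    b
  })
  write_out <- function(df, file) {
    data.table::fwrite(df, file.path(config$out_dir, file))
  }
  write_out(behavior, "behavior.csv")

  psth <- stage("psth", lapply(exp$sessions, function(s) {
    session_response_vectors(s$record, s$traces)
  }))

  late <- which(behavior$phase == "late")
  if (length(late) == 0) late <- seq_along(exp$sessions)
  pooled <- do.call(rbind, lapply(late, function(i) psth[[i]]$vectors))

  fit <- stage("clustering", {
    fit_ensembles(pooled, k_range = config$k_range,
                  nn_range = config$nn_range, seed = config$seed)
  })
  labels_df <- data.frame(cell_id = names(fit$labels),
                          cluster = unname(fit$labels), config_hash = hash)
  write_out(labels_df, "labels.csv")
  jsonlite::write_json(
    list(algorithm = fit$model$algorithm, n_clusters = fit$n_clusters,
         n_neighbors = fit$n_neighbors, n_components = fit$n_components,
         silhouette = fit$silhouette, config_hash = hash),
    file.path(config$out_dir, "cluster_model.json"),
    auto_unbox = TRUE, digits = NA)

  decoding <- stage("decoding", {
    d <- decode_all(exp, labels = fit$labels,
                    n_folds = config$n_folds, n_shuffles = config$n_shuffles,
                    seed = config$seed, cluster_shuffles = 0)
    d$config_hash <- hash
    d
  })
  write_out(decoding[, setdiff(names(decoding), "error")], "decoding.csv")

  stability <- stage("tracking", {
    res <- list()
    if (config$sessions_per_mouse >= 2 && !is.null(exp$truths)) {
      for (m in seq_len(config$n_mice)) {
        map <- experiment_tracking_map(exp, m)
        sess_m <- Filter(function(s) s$mouse_id == sprintf("m%02d", m),
                         exp$sessions)
        idx <- order(vapply(sess_m, function(s) s$session_index, integer(1)))
        first <- sess_m[[idx[1]]]; last <- sess_m[[idx[length(idx)]]]
        pi_first <- which(vapply(exp$sessions, function(s) {
          identical(s$record, first$record)
        }, logical(1)))[1]
        pi_last <- which(vapply(exp$sessions, function(s) {
          identical(s$record, last$record)
        }, logical(1)))[1]
        tens_a <- list(csplus = psth[[pi_first]]$tensor_csplus,
                       csminus = psth[[pi_first]]$tensor_csminus)
        tens_b <- list(csplus = psth[[pi_last]]$tensor_csplus,
                       csminus = psth[[pi_last]]$tensor_csminus)
        pr <- paired_epoch_responses(map, tens_a, tens_b)
        res[[sprintf("m%02d", m)]] <- data.frame(
          fov_id = sprintf("m%02d", m),
          cue = c("CS+", "CS-"),
          r = c(stability_correlation(pr$csplus)$r,
                stability_correlation(pr$csminus)$r),
          p = c(stability_correlation(pr$csplus)$p,
                stability_correlation(pr$csminus)$p),
          config_hash = hash
        )
      }
    }
    if (length(res)) do.call(rbind, res) else data.frame()
  })
  if (nrow(stability)) write_out(stability, "stability.csv")

  lags <- stage("lags", {
    s_last <- exp$sessions[[late[length(late)]]]
    tn <- normalize_traces(s_last$traces, s_last$record)
    cross_correlation_lags(tn, fit$labels)
  })
  write_out(cbind(data.frame(cluster = rownames(lags$lag_s)),
                  as.data.frame(lags$lag_s),
                  data.frame(config_hash = hash)), "lag_matrix.csv")

  if (config$figures) {
    grDevices::png(file.path(config$out_dir, "ensemble_profiles.png"),
                   width = 1500, height = 350)
    plot(fit)
    grDevices::dev.off()
  }
  jsonlite::write_json(
    list(config_hash = hash,
         package_version = as.character(utils::packageVersion("pfcensembles")),
         n_sessions = length(exp$sessions)),
    file.path(config$out_dir, "run_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(behavior = behavior, fit = fit, decoding = decoding,
                 stability = stability, lags = lags,
                 out_dir = config$out_dir, config_hash = hash))
}

#' Write a small packaged test dataset
#'
#' Generates a compact synthetic experiment (3 mice x 2 sessions, ~60
#' cells per FOV) and writes it through [write_session()]; used by the
#' test suite and as a worked example of the on-disk layout.
#'
#' @param dir Output root directory.
#' @param seed Integer seed; same seed reproduces identical files.
#' @param n_cells,trials_per_cue Fixture size.
#' @return Invisibly, the written session directories.
#' @export
make_fixtures <- function(dir, seed = 1, n_cells = 60, trials_per_cue = 50) {
  cfg <- sim_config(n_cells = n_cells, trials_per_cue = trials_per_cue)
  exp <- generate_experiment(cfg, n_mice = 3, sessions_per_mouse = 2,
                             seed = seed)
  dirs <- character(0)
  for (s in exp$sessions) {
    d <- file.path(dir, sprintf("%s_s%02d", s$mouse_id, s$session_index))
    m <- as.integer(sub("m", "", s$mouse_id))
    write_session(s$record, s$traces, d, truth = exp$truths[[m]])
    phase <- if (s$stage > 0.5) "late" else "early"
    meta <- jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE)
    meta$phase <- phase
    meta$fov_id <- s$mouse_id
    jsonlite::write_json(meta, file.path(d, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}
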
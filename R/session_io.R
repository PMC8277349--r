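#' Construct and validate a session record
#'
#' A `session_record` is the event-level description of one conditioning
#' session: cue events, reward deliveries, lick times and the imaging
#' frame clock, all in session-relative seconds (0 at the first frame).
#'
#' @param mouse_id,session_index Session metadata.
#' @param cue_events Data frame with columns `onset_s`, `offset_s`,
#'   `identity` (`"CS+"`/`"CS-"`), sorted and non-overlapping.
#' @param reward_times_s,lick_times_s Event times (s).
#' @param frame_times_s Strictly increasing frame timestamps (s).
#' @param tone_s,trace_interval_s Task timing constants (s).
#' @return A validated object of class `session_record`.
#' @export
new_session_record <- function(mouse_id, session_index, cue_events,
                               reward_times_s, lick_times_s, frame_times_s,
                               tone_s = 2, trace_interval_s = 1) {
  rec <- structure(list(
    mouse_id = as.character(mouse_id),
    session_index = as.integer(session_index),
    cue_events = as.data.frame(cue_events),
    reward_times_s = as.numeric(reward_times_s),
    lick_times_s = as.numeric(lick_times_s),
    frame_times_s = as.numeric(frame_times_s),
    tone_s = tone_s, trace_interval_s = trace_interval_s
  ), class = "session_record")
  validate_session_record(rec)
  rec
}

#' @noRd
validate_session_record <- function(rec) {
  ev <- rec$cue_events
  need <- c("onset_s", "offset_s", "identity")
  if (!all(need %in% names(ev))) {
    stop_validation("cue_events is missing column(s): %s",
                    paste(setdiff(need, names(ev)), collapse = ", "))
  }
  if (!all(ev$identity %in% c("CS+", "CS-"))) {
    stop_validation("cue identity must be 'CS+' or 'CS-'")
  }
  if (nrow(ev) > 1) {
    if (is.unsorted(ev$onset_s, strictly = TRUE)) {
      stop_validation("cue events must be sorted by onset")
    }
    if (any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)])) {
      stop_validation("cue events overlap")
    }
  }
  if (any(ev$offset_s <= ev$onset_s)) stop_validation("cue offset before onset")
  ft <- rec$frame_times_s
  if (length(ft) < 2 || is.unsorted(ft, strictly = TRUE)) {
    stop_validation("frame_times_s must be strictly increasing")
  }
  dt <- stats::median(diff(ft))
  plus <- ev[ev$identity == "CS+", , drop = FALSE]
  if (nrow(plus) != length(rec$reward_times_s)) {
    stop_validation("expected one reward per CS+ trial (%d CS+, %d rewards)",
                    nrow(plus), length(rec$reward_times_s))
  }
  if (nrow(plus) > 0) {
    expected <- plus$offset_s + rec$trace_interval_s
    err <- rec$reward_times_s - expected
    if (any(rec$reward_times_s < plus$offset_s)) {
      stop_validation("reward precedes its CS+ offset (trial %d)",
                      which(rec$reward_times_s < plus$offset_s)[1])
    }
    if (any(abs(err) > dt)) {
      stop_validation(
        "reward time deviates from CS+ offset + trace interval by > 1 frame (trial %d)",
        which(abs(err) > dt)[1])
    }
  }
  invisible(rec)
}

#' Construct and validate a trace matrix
#'
#' @param cell_ids Character cell identifiers.
#' @param values Cells x frames fluorescence matrix (finite).
#' @param frame_rate_hz Frame rate (Hz).
#' @return A validated object of class `trace_matrix`.
#' @export
new_trace_matrix <- function(cell_ids, values, frame_rate_hz) {
  tm <- structure(list(
    cell_ids = as.character(cell_ids),
    values = as.matrix(values),
    frame_rate_hz = frame_rate_hz
  ), class = "trace_matrix")
  validate_trace_matrix(tm)
  tm
}

#' @noRd
validate_trace_matrix <- function(tm, record = NULL) {
  if (nrow(tm$values) != length(tm$cell_ids)) {
    stop_validation("values must have one row per cell_id")
  }
  bad <- which(!apply(is.finite(tm$values), 1, all))
  if (length(bad) > 0) {
    stop_validation("non-finite trace values for cell '%s'", tm$cell_ids[bad[1]])
  }
  if (anyDuplicated(tm$cell_ids)) stop_validation("duplicate cell_ids")
  if (!is.null(record) && ncol(tm$values) != length(record$frame_times_s)) {
    stop_validation("trace frame count (%d) != frame_times_s length (%d)",
                    ncol(tm$values), length(record$frame_times_s))
  }
  invisible(tm)
}

#' Validate a session record / trace matrix pair
#'
#' Checks every structural invariant the downstream analysis assumes:
#' sorted non-overlapping cues, one reward per CS+ at offset + trace
#' interval (within one frame), strictly increasing frame clock, finite
#' traces and matching frame counts.
#'
#' @param record A `session_record`.
#' @param traces A `trace_matrix`.
#' @return Invisibly `TRUE`; signals a classed validation error otherwise.
#' @export
validate_session <- function(record, traces) {
  validate_session_record(record)
  validate_trace_matrix(traces, record)
  invisible(TRUE)
}

#' Per-trial event table for a session
#'
#' One row per cue presentation with its outcome reference time: the
#' matched reward time for CS+ trials, and tone offset + trace interval
#' (the equivalent no-reward time) for CS- trials.
#' @param record A `session_record`.
#' @return Data frame: `trial`, `identity`, `onset_s`, `offset_s`,
#'   `outcome_s`.
#' @export
session_trials <- function(record) {
  ev <- record$cue_events
  out <- ev$offset_s + record$trace_interval_s
  is_plus <- ev$identity == "CS+"
  if (any(is_plus)) out[is_plus] <- record$reward_times_s
  data.frame(trial = seq_len(nrow(ev)), identity = ev$identity,
             onset_s = ev$onset_s, offset_s = ev$offset_s, outcome_s = out)
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `events.csv` (long table `time_s`, `type` with types
#' `cs_plus_on`, `cs_plus_off`, `cs_minus_on`, `cs_minus_off`, `reward`,
#' `lick`), `traces.csv` (wide, `cell_id` x frame), `frame_times.csv`,
#' `meta.json`, and optionally `ground_truth.csv`.
#'
#' @param record A `session_record`.
#' @param traces A `trace_matrix`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `ground_truth` to store alongside.
#' @return Invisibly, the directory path.
#' @export
write_session <- function(record, traces, dir, truth = NULL) {
  validate_session(record, traces)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- record$cue_events
  type_on <- ifelse(ev$identity == "CS+", "cs_plus_on", "cs_minus_on")
  type_off <- ifelse(ev$identity == "CS+", "cs_plus_off", "cs_minus_off")
  events <- rbind(
    data.frame(time_s = ev$onset_s, type = type_on),
    data.frame(time_s = ev$offset_s, type = type_off),
    data.frame(time_s = record$reward_times_s,
               type = rep("reward", length(record$reward_times_s))),
    data.frame(time_s = record$lick_times_s,
               type = rep("lick", length(record$lick_times_s)))
  )
  events <- events[order(events$time_s), ]
  data.table::fwrite(events, file.path(dir, "events.csv"))
  tr <- data.table::data.table(cell_id = traces$cell_ids)
  tr <- cbind(tr, data.table::as.data.table(traces$values))
  data.table::setnames(tr, c("cell_id", sprintf("f%06d", seq_len(ncol(traces$values)))))
  data.table::fwrite(tr, file.path(dir, "traces.csv"))
  data.table::fwrite(data.frame(frame_times_s = record$frame_times_s),
                     file.path(dir, "frame_times.csv"))
  meta <- list(mouse_id = record$mouse_id, session_index = record$session_index,
               frame_rate_hz = traces$frame_rate_hz, tone_s = record$tone_s,
               trace_interval_s = record$trace_interval_s)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    data.table::fwrite(truth$cells, file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A list with `record` and `traces` (validated), plus `truth`
#'   (`NULL` unless `ground_truth.csv` is present).
#' @export
read_session <- function(dir) {
  need <- c("events.csv", "traces.csv", "frame_times.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop_validation("session directory '%s' is missing file(s): %s",
                    dir, paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  events <- data.table::fread(file.path(dir, "events.csv"), data.table = FALSE)
  if (!all(c("time_s", "type") %in% names(events))) {
    stop_validation("events.csv must have columns time_s, type")
  }
  ft <- data.table::fread(file.path(dir, "frame_times.csv"),
                          data.table = FALSE)$frame_times_s
  on_p <- events$time_s[events$type == "cs_plus_on"]
  off_p <- events$time_s[events$type == "cs_plus_off"]
  on_m <- events$time_s[events$type == "cs_minus_on"]
  off_m <- events$time_s[events$type == "cs_minus_off"]
  if (length(on_p) != length(off_p) || length(on_m) != length(off_m)) {
    stop_validation("unbalanced cue on/off events in %s", dir)
  }
  cue <- data.frame(
    onset_s = c(on_p, on_m), offset_s = c(off_p, off_m),
    identity = c(rep("CS+", length(on_p)), rep("CS-", length(on_m)))
  )
  cue <- cue[order(cue$onset_s), ]
  rownames(cue) <- NULL
  record <- new_session_record(
    mouse_id = meta$mouse_id, session_index = meta$session_index,
    cue_events = cue,
    reward_times_s = sort(events$time_s[events$type == "reward"]),
    lick_times_s = sort(events$time_s[events$type == "lick"]),
    frame_times_s = ft, tone_s = meta$tone_s,
    trace_interval_s = meta$trace_interval_s
  )
  tr <- data.table::fread(file.path(dir, "traces.csv"), data.table = FALSE)
  traces <- new_trace_matrix(cell_ids = tr$cell_id,
                             values = as.matrix(tr[, -1, drop = FALSE]),
                             frame_rate_hz = meta$frame_rate_hz)
  validate_session(record, traces)
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth.csv"))) {
    truth <- list(cells = data.table::fread(file.path(dir, "ground_truth.csv"),
                                            data.table = FALSE))
    class(truth) <- "ground_truth"
  }
  list(record = record, traces = traces, truth = truth)
}

#' Load a directory tree of sessions with phase metadata
#'
#' Scans `root_dir` for session directories in the layout written by
#' [write_session()] (optionally augmented with `phase` and `fov_id`
#' entries in each `meta.json`), pools them, and reports FOV and neuron
#' counts per learning phase. Intended for locally organized copies of
#' the deposited study dataset; the core pipeline never requires it.
#'
#' @param root_dir Root directory containing one subdirectory per session.
#' @return A list with `sessions` (as from [read_session()], plus `phase`),
#'   and `summary` (data frame of FOV and neuron counts per phase).
#' @export
load_dryad_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop_validation("directory '%s' does not exist", root_dir)
  dirs <- list.dirs(root_dir, recursive = TRUE, full.names = TRUE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (length(dirs) == 0) {
    stop_validation(paste0(
      "unrecognized layout under '%s': expected session subdirectories each ",
      "containing events.csv, traces.csv, frame_times.csv and meta.json ",
      "(with optional 'phase' and 'fov_id' fields)"), root_dir)
  }
  sessions <- lapply(dirs, function(d) {
    s <- read_session(d)
    meta <- jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE)
    s$phase <- meta$phase %||% "unknown"
    s$fov_id <- meta$fov_id %||% basename(d)
    s
  })
  phase <- vapply(sessions, function(s) s$phase, character(1))
  ncells <- vapply(sessions, function(s) length(s$traces$cell_ids), integer(1))
  summary <- stats::aggregate(
    cbind(n_fovs = rep(1L, length(phase)), n_neurons = ncells),
    by = list(phase = phase), FUN = sum)
  list(sessions = sessions, summary = summary)
}
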
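#' Simulation configuration for synthetic conditioning sessions
#'
#' Bundles and validates all parameters of the session generator. Defaults
#' reproduce the task design of the experiments the analysis targets: 50
#' CS+ and 50 CS- trials presented in random order, 2 s tones, a 1 s trace
#' interval between CS+ offset and reward, inter-trial intervals drawn
#' uniformly from 20-50 s, and imaging at 23/3 Hz so that a 3 s epoch
#' contains exactly 23 frames.
#'
#' @param n_cells Number of cells in the field of view.
#' @param motif_props Mixture proportions over the five canonical motifs
#'   (see [motif_library()]). Must sum to at most 1; the remainder of the
#'   population consists of background cells with no event-locked drive.
#' @param noise_sd Standard deviation of i.i.d. Gaussian trace noise, in
#'   the same arbitrary fluorescence units as the unit-amplitude response.
#' @param amplitude,amplitude_sd Mean and SD of the per-cell response
#'   amplitude scalar (truncated below at 0.5).
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param trials_per_cue Number of trials of each cue identity.
#' @param iti_range_s Inter-trial interval bounds (s), measured from reward
#'   delivery (or the equivalent no-reward time on CS- trials) to the next
#'   tone onset.
#' @param tone_s Tone duration (s).
#' @param trace_interval_s Gap between tone offset and reward (s).
#' @param kernel_rise_s,kernel_decay_s Rise and decay time constants (s) of
#'   the difference-of-exponentials calcium kernel (GCaMP6s-like).
#' @param reward_drive_s Duration (s) of the reward/consumption drive
#'   window following reward delivery on CS+ trials.
#' @param baseline_lick_hz Baseline lick rate (Hz) throughout the session.
#' @param learned_anticip_hz Asymptotic anticipatory lick rate (Hz) added
#'   during the CS+ trace interval; scaled by the session's learning stage.
#' @param consumption_lick_hz,consumption_s Consumption lick rate (Hz) and
#'   duration (s) following reward delivery.
#' @param trial_gain_shape Shape of the Gamma(shape, rate = shape)
#'   distribution of the per-trial response gain shared by all cells of a
#'   motif (mean 1; larger values mean less trial-to-trial variability).
#' @param lick_gain_shape Shape of the same Gamma gain for motif 5, whose
#'   gain also drives anticipatory licking; smaller than
#'   `trial_gain_shape` because behaviour-coupled responses fluctuate more
#'   from trial to trial.
#' @param drift_sd,drift_tau_s Stationary SD and time constant (s) of the
#'   Ornstein-Uhlenbeck baseline drift given to background cells.
#' @param couple_motif5_licking If `TRUE` (default), a field of view's
#'   asymptotic anticipatory lick rate scales with its motif-5 share in
#'   [generate_experiment()], planting the ensemble-proportion/behaviour
#'   relationship seen in the data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 300,
                       motif_props = default_motif_props(),
                       noise_sd = 1,
                       amplitude = 3,
                       amplitude_sd = 0.5,
                       frame_rate_hz = 23 / 3,
                       trials_per_cue = 50,
                       iti_range_s = c(20, 50),
                       tone_s = 2,
                       trace_interval_s = 1,
                       kernel_rise_s = 0.2,
                       kernel_decay_s = 1.5,
                       reward_drive_s = 2,
                       baseline_lick_hz = 0.5,
                       learned_anticip_hz = 6,
                       consumption_lick_hz = 6,
                       consumption_s = 2,
                       trial_gain_shape = 6,
                       lick_gain_shape = 3,
                       drift_sd = 0.5,
                       drift_tau_s = 30,
                       couple_motif5_licking = TRUE) {
  cfg <- list(
    n_cells = as.integer(n_cells), motif_props = as.numeric(motif_props),
    noise_sd = noise_sd, amplitude = amplitude, amplitude_sd = amplitude_sd,
    frame_rate_hz = frame_rate_hz, trials_per_cue = as.integer(trials_per_cue),
    iti_range_s = as.numeric(iti_range_s), tone_s = tone_s,
    trace_interval_s = trace_interval_s, kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s, reward_drive_s = reward_drive_s,
    baseline_lick_hz = baseline_lick_hz, learned_anticip_hz = learned_anticip_hz,
    consumption_lick_hz = consumption_lick_hz, consumption_s = consumption_s,
    trial_gain_shape = trial_gain_shape,
    lick_gain_shape = lick_gain_shape, drift_sd = drift_sd,
    drift_tau_s = drift_tau_s, couple_motif5_licking = isTRUE(couple_motif5_licking)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_cells < 1L) stop_validation("n_cells must be >= 1")
  if (length(cfg$motif_props) != 5L || any(cfg$motif_props < 0)) {
    stop_validation("motif_props must be five non-negative proportions")
  }
  if (sum(cfg$motif_props) > 1 + 1e-8) {
    stop_validation("motif_props must sum to <= 1 (remainder = background cells)")
  }
  durs <- c(cfg$tone_s, cfg$trace_interval_s, cfg$kernel_rise_s,
            cfg$kernel_decay_s, cfg$reward_drive_s, cfg$consumption_s,
            cfg$frame_rate_hz, cfg$drift_tau_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop_validation("all durations and rates must be positive and finite")
  }
  if (length(cfg$iti_range_s) != 2L || cfg$iti_range_s[1] >= cfg$iti_range_s[2] ||
      cfg$iti_range_s[1] <= 0) {
    stop_validation("iti_range_s must be positive bounds with lower < upper")
  }
  if (cfg$trials_per_cue < 1L) stop_validation("trials_per_cue must be >= 1")
  if (cfg$noise_sd < 0 || cfg$drift_sd < 0 || cfg$amplitude_sd < 0) {
    stop_validation("noise_sd, drift_sd and amplitude_sd must be non-negative")
  }
  invisible(cfg)
}

#' Sample per-cell ground truth for one field of view
#'
#' Allocates cells to the five canonical motifs (largest-remainder rounding
#' of `config$motif_props`; any remainder becomes background cells with no
#' event-locked gain) and draws per-cell amplitude scalars.
#'
#' @param config A [sim_config()].
#' @param stage Learning stage in \[0, 1\]: scales the response amplitude of
#'   motifs 2-5 and the anticipatory lick rate. Motif 1 is
#'   stage-independent.
#' @param seed Integer seed.
#' @param cell_prefix Prefix for generated cell IDs.
#' @param learned_anticip_hz Optional override of the asymptotic
#'   anticipatory lick rate (used by [generate_experiment()] to couple
#'   behaviour to ensemble composition).
#' @return An object of class `ground_truth`: list with `cells` (data frame
#'   `cell_id`, `motif` (0 = background), `amplitude`), `stage` and the
#'   lick-model rates.
#' @export
sample_ground_truth <- function(config, stage = 1, seed = 1,
                                cell_prefix = "cell",
                                learned_anticip_hz = NULL) {
  stopifnot(inherits(config, "sim_config"), stage >= 0, stage <= 1)
  n <- config$n_cells
  target <- config$motif_props * n
  counts <- floor(target)
  rem <- n - sum(counts) - round((1 - sum(config$motif_props)) * n)
  if (rem > 0) { # distribute remainder by largest fractional part
    ord <- order(target - floor(target), decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  motif <- c(rep.int(1:5, counts), rep.int(0L, n - sum(counts)))
  with_seed(seed, {
    motif <- motif[sample.int(length(motif))]
    amplitude <- pmax(0.5, stats::rnorm(n, config$amplitude, config$amplitude_sd))
  })
  truth <- list(
    cells = data.frame(
      cell_id = sprintf("%s%04d", cell_prefix, seq_len(n)),
      motif = as.integer(motif),
      amplitude = amplitude
    ),
    stage = stage,
    baseline_lick_hz = config$baseline_lick_hz,
    learned_anticip_hz = learned_anticip_hz %||% config$learned_anticip_hz
  )
  class(truth) <- "ground_truth"
  truth
}

#' Difference-of-exponentials calcium impulse response sampled on frames
#' @noRd
calcium_kernel <- function(config) {
  dt <- 1 / config$frame_rate_hz
  t <- seq(0, config$kernel_decay_s * 6, by = dt)
  k <- exp(-t / config$kernel_decay_s) - exp(-t / config$kernel_rise_s)
  k / max(k)
}

# Onset-adaptation constants of the underlying rate model: each step of the
# drive level towards a stronger response adds a fast-decaying transient
# proportional to the step, compensating the indicator's low-pass so that a
# sustained unit drive produces an approximately flat unit fluorescence
# plateau. Steps back towards baseline get no transient; the fluorescence
# then relaxes with the kernel's decay constant, as an indicator does.
ADAPT_TAU_S <- 0.2
ADAPT_KAPPA <- 4.9

#' Fluorescence response to a piecewise-constant drive-level vector
#'
#' Adds the onset-adaptation transients at response-onset steps, convolves
#' with the calcium kernel and rescales so a unit sustained drive gives a
#' unit plateau.
#' @noRd
drive_response <- function(level, config, kern = calcium_kernel(config),
                           scale = plateau_scale(config, kern)) {
  n <- length(level)
  dt <- 1 / config$frame_rate_hz
  steps <- c(level[1], diff(level))
  s <- sign(level[which.max(abs(level))]) # response direction of this motif
  if (s == 0) s <- 1
  steps[sign(steps) != s] <- 0 # only onset steps are compensated
  trans <- as.numeric(stats::filter(steps, exp(-dt / ADAPT_TAU_S),
                                    method = "recursive"))
  rate <- level + ADAPT_KAPPA * trans
  stats::convolve(rate, rev(kern), type = "open")[seq_len(n)] / scale
}

#' Plateau height of the unit step response (normalization constant)
#' @noRd
plateau_scale <- function(config, kern = calcium_kernel(config)) {
  fr <- config$frame_rate_hz
  n <- ceiling(8 * fr)
  t <- (seq_len(n) - 1) / fr
  dt <- 1 / fr
  level <- rep(1, n)
  steps <- c(1, numeric(n - 1))
  trans <- as.numeric(stats::filter(steps, exp(-dt / ADAPT_TAU_S),
                                    method = "recursive"))
  rate <- level + ADAPT_KAPPA * trans
  y <- stats::convolve(rate, rev(kern), type = "open")[seq_len(n)]
  mean(y[t >= 1 & t <= 5])
}

#' Generate one synthetic conditioning session
#'
#' Builds the event schedule (random interleaving of CS+ and CS- trials,
#' reward one trace interval after each CS+ offset, uniform ITIs), draws
#' lick times from an inhomogeneous Poisson process whose trace-interval
#' rate scales with the learning stage, and synthesizes fluorescence traces
#' as a motif-specific event-locked underlying rate (piecewise-constant
#' drive levels with fast onset-adaptation transients at every step)
#' convolved with a calcium kernel, plus Gaussian noise. Background cells
#' receive slow Ornstein-Uhlenbeck drift instead of event-locked drive.
#'
#' @param config A [sim_config()].
#' @param truth A [sample_ground_truth()] result; defaults to a stage-1
#'   (fully learned) population drawn with the same seed.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @param mouse_id,session_index Metadata stored in the session record.
#' @return A list with components `record` (class `session_record`) and
#'   `traces` (class `trace_matrix`).
#' @examples
#' cfg <- sim_config(n_cells = 20, trials_per_cue = 4)
#' s <- generate_session(cfg, seed = 1)
#' table(s$record$cue_events$identity)
#' @export
generate_session <- function(config, truth = NULL, seed = 1,
                             mouse_id = "m1", session_index = 1L) {
  validate_sim_config(config)
  if (is.null(truth)) truth <- sample_ground_truth(config, stage = 1, seed = seed)
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, generate_session_impl(config, truth, mouse_id, session_index))
}

#' @noRd
generate_session_impl <- function(config, truth, mouse_id, session_index) {
  fr <- config$frame_rate_hz
  npc <- config$trials_per_cue
  n_trials <- 2L * npc
  identity <- sample(rep(c("CS+", "CS-"), npc))

  onset <- numeric(n_trials)
  t_cursor <- 30 # pre-roll so the first trial has a full baseline epoch
  itis <- stats::runif(n_trials, config$iti_range_s[1], config$iti_range_s[2])
  outcome <- offset <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    onset[i] <- t_cursor
    offset[i] <- onset[i] + config$tone_s
    outcome[i] <- offset[i] + config$trace_interval_s
    t_cursor <- outcome[i] + itis[i]
  }
  session_end <- outcome[n_trials] + 12 # room for outcome epoch + kernel tail
  n_frames <- floor(session_end * fr) + 1L
  frame_times <- (seq_len(n_frames) - 1L) / fr

  is_plus <- identity == "CS+"
  reward_times <- outcome[is_plus]
  # per-motif, per-trial shared response gains (ensemble-wide trial-to-trial
  # variability); the motif-5 gain also drives anticipatory licking
  shp <- c(rep(config$trial_gain_shape, 4L), config$lick_gain_shape)
  gain <- matrix(stats::rgamma(5L * n_trials, shape = shp, rate = shp),
                 nrow = 5L)

  lib <- motif_library()
  stage_mult <- c(1, rep(truth$stage, 4)) # motif 1 is learning-independent
  kern <- calcium_kernel(config)
  scale <- plateau_scale(config, kern)
  conv <- matrix(0, nrow = 5L, ncol = n_frames)
  for (m in 1:5) {
    # piecewise-constant drive level: cue gain over tone + trace interval,
    # reward gain over the reward/consumption window (CS+ trials)
    level <- numeric(n_frames)
    for (i in seq_len(n_trials)) {
      g_trial <- gain[m, i]
      g_cue <- if (is_plus[i]) lib$cs_plus_cue_gain[m] else lib$cs_minus_cue_gain[m]
      # sustained motifs hold the cue level through the outcome window of
      # both trial types; transient motifs end at the outcome reference
      cue_end <- if (lib$sustained[m]) outcome[i] + config$reward_drive_s
                 else outcome[i]
      if (g_cue != 0) {
        idx <- frames_in(frame_times, onset[i], cue_end)
        level[idx] <- level[idx] + g_cue * g_trial
      }
      if (is_plus[i] && !lib$sustained[m] && lib$reward_gain[m] != 0) {
        idx <- frames_in(frame_times, outcome[i],
                         outcome[i] + config$reward_drive_s)
        level[idx] <- level[idx] + lib$reward_gain[m] * g_trial
      }
    }
    if (stage_mult[m] != 0 && any(level != 0)) {
      conv[m, ] <- drive_response(level * stage_mult[m], config, kern, scale)
    }
  }

  n_cells <- nrow(truth$cells)
  values <- matrix(0, nrow = n_cells, ncol = n_frames)
  for (j in seq_len(n_cells)) {
    m <- truth$cells$motif[j]
    if (m > 0L) values[j, ] <- truth$cells$amplitude[j] * conv[m, ]
  }
  bg <- which(truth$cells$motif == 0L)
  if (length(bg) > 0 && config$drift_sd > 0) {
    phi <- exp(-1 / (fr * config$drift_tau_s))
    innov_sd <- config$drift_sd * sqrt(1 - phi^2)
    eps <- matrix(stats::rnorm(length(bg) * n_frames, sd = innov_sd),
                  nrow = n_frames)
    ou <- stats::filter(eps, phi, method = "recursive")
    values[bg, ] <- values[bg, ] + t(ou)
  }
  if (config$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(n_cells * n_frames, sd = config$noise_sd),
                              nrow = n_cells)
  }
  rownames(values) <- truth$cells$cell_id

  lick_times <- simulate_licks(config, truth, identity, offset, outcome,
                               gain[5L, ], session_end)

  record <- new_session_record(
    mouse_id = mouse_id, session_index = as.integer(session_index),
    cue_events = data.frame(onset_s = onset, offset_s = offset,
                            identity = identity),
    reward_times_s = reward_times, lick_times_s = lick_times,
    frame_times_s = frame_times, tone_s = config$tone_s,
    trace_interval_s = config$trace_interval_s
  )
  traces <- new_trace_matrix(cell_ids = truth$cells$cell_id, values = values,
                             frame_rate_hz = fr)
  list(record = record, traces = traces)
}

#' Inhomogeneous Poisson lick times (piecewise-constant rate)
#' @noRd
simulate_licks <- function(config, truth, identity, offset, outcome,
                           gain, session_end) {
  licks <- numeric(0)
  b <- truth$baseline_lick_hz
  if (b > 0) {
    n <- stats::rpois(1, b * session_end)
    licks <- stats::runif(n, 0, session_end)
  }
  is_plus <- identity == "CS+"
  anticip <- truth$stage * truth$learned_anticip_hz
  for (i in which(is_plus)) {
    r <- anticip * gain[i]
    if (r > 0) {
      n <- stats::rpois(1, r * config$trace_interval_s)
      licks <- c(licks, stats::runif(n, offset[i], outcome[i]))
    }
    rc <- config$consumption_lick_hz * gain[i]
    if (rc > 0) {
      n <- stats::rpois(1, rc * config$consumption_s)
      licks <- c(licks, stats::runif(n, outcome[i], outcome[i] + config$consumption_s))
    }
  }
  sort(licks)
}

#' Generate a multi-mouse, multi-session synthetic experiment
#'
#' Each mouse contributes one field of view whose cells keep stable IDs
#' across sessions. Learning stages increase linearly from 0 (first
#' session, "early") to 1 (last session, "late") within each mouse; motif
#' amplitudes for motifs 2-5 and anticipatory licking scale with stage,
#' while motif 1 responds equally at every stage. Motif mixture
#' proportions are jittered across mice (Dirichlet), and when
#' `config$couple_motif5_licking` is `TRUE` the asymptotic anticipatory
#' lick rate of a mouse scales with its motif-5 share.
#'
#' @param config A [sim_config()].
#' @param n_mice Number of mice (one FOV each).
#' @param sessions_per_mouse Sessions per mouse (>= 1).
#' @param seed Integer seed.
#' @return An object of class `ensemble_experiment`: list with `sessions`
#'   (each: `mouse_id`, `session_index`, `stage`, `record`, `traces`),
#'   `truths` (per-mouse `ground_truth`), `config`, `seed`.
#' @export
generate_experiment <- function(config, n_mice = 3, sessions_per_mouse = 2,
                                seed = 1) {
  validate_sim_config(config)
  stopifnot(n_mice >= 1, sessions_per_mouse >= 1)
  base_props <- config$motif_props
  sub <- with_seed(seed, {
    list(
      seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                n_mice * (sessions_per_mouse + 1L)),
                     nrow = n_mice),
      dirichlet = matrix(stats::rgamma(n_mice * 5L, shape = 60 * base_props),
                         nrow = n_mice)
    )
  })
  stages <- if (sessions_per_mouse == 1L) 1 else
    seq(0, 1, length.out = sessions_per_mouse)
  truths <- vector("list", n_mice)
  sessions <- list()
  for (m in seq_len(n_mice)) {
    props <- sub$dirichlet[m, ] / sum(sub$dirichlet[m, ]) * sum(base_props)
    cfg_m <- config
    cfg_m$motif_props <- props
    anticip <- config$learned_anticip_hz
    if (config$couple_motif5_licking && base_props[5] > 0) {
      anticip <- anticip * min(2, props[5] / base_props[5])
    }
    truth <- sample_ground_truth(cfg_m, stage = 1, seed = sub$seeds[m, 1L],
                                 cell_prefix = sprintf("m%02d_c", m),
                                 learned_anticip_hz = anticip)
    truths[[m]] <- truth
    for (s in seq_len(sessions_per_mouse)) {
      truth_s <- truth
      truth_s$stage <- stages[s]
      sess <- generate_session(cfg_m, truth_s, seed = sub$seeds[m, s + 1L],
                               mouse_id = sprintf("m%02d", m),
                               session_index = s)
      sessions[[length(sessions) + 1L]] <- list(
        mouse_id = sprintf("m%02d", m), session_index = s,
        stage = stages[s], record = sess$record, traces = sess$traces
      )
    }
  }
  structure(list(sessions = sessions, truths = truths, config = config,
                 seed = seed),
            class = "ensemble_experiment")
}

#' Identity tracking map between two sessions of one mouse's FOV
#'
#' @param experiment An [generate_experiment()] result.
#' @param mouse Mouse index.
#' @return A data frame (`fov_id`, `cell_id_a`, `cell_id_b`) pairing each
#'   cell with itself, the ground-truth correspondence between sessions.
#' @export
experiment_tracking_map <- function(experiment, mouse = 1) {
  stopifnot(inherits(experiment, "ensemble_experiment"))
  ids <- experiment$truths[[mouse]]$cells$cell_id
  data.frame(fov_id = sprintf("m%02d", mouse), cell_id_a = ids, cell_id_b = ids)
}
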
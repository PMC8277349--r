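#' Canonical ensemble response motifs
#'
#' Returns the library of five response motifs used both to simulate
#' populations and to label fitted clusters with canonical ensemble
#' identities. Gains are dimensionless multipliers applied to the
#' event-locked drive of a cell:
#'
#' 1. excitatory to CS+, CS- and reward (a sustained response held at the
#'    same level from cue onset through reward consumption);
#' 2. excitatory to CS+ only;
#' 3. equal excitatory responses to both cues;
#' 4. excitatory to reward only;
#' 5. inhibitory during CS+ trials.
#'
#' The cue gain sets the drive level from tone onset through the trace
#' interval; the reward gain sets it over the reward/consumption window of
#' CS+ trials. Motif 1 is a sustained responder: its drive holds the cue
#' level through the outcome window of both trial types (with equal cue
#' and reward gains this is one continuous trial-long plateau), so its
#' fluorescence carries no event-locked contrast at reward delivery.
#'
#' @return A data frame with one row per motif and columns `motif_id`,
#'   `cs_plus_cue_gain`, `cs_minus_cue_gain`, `reward_gain`, `sustained`.
#' @examples
#' motif_library()
#' @export
motif_library <- function() {
  data.frame(
    motif_id = 1:5,
    cs_plus_cue_gain  = c(1.0, 1.0, 0.8,  0.0, -0.8),
    cs_minus_cue_gain = c(1.0, 0.0, 0.8,  0.0,  0.0),
    reward_gain       = c(1.0, 0.0, 0.0,  2.0,  0.0),
    sustained         = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Default mixture proportions of the five motifs
#'
#' The default population composition follows the relative sizes of the
#' five ensembles reported for the pooled late-in-learning population
#' (192, 346, 291, 320 and 362 cells of 1511).
#' @noRd
default_motif_props <- function() {
  p <- c(192, 346, 291, 320, 362)
  p / sum(p)
}

#' Template 138-frame response vectors for the canonical motifs
#'
#' Idealized (un-convolved) CS+/CS- concatenated profiles used to match
#' fitted clusters to canonical motif identities by cosine similarity.
#' Frames 1-23 baseline, 24-46 cue/trace, 47-69 outcome, per cue block.
#' @noRd
motif_templates <- function() {
  lib <- motif_library()
  tpl <- matrix(0, nrow = nrow(lib), ncol = 138)
  for (i in seq_len(nrow(lib))) {
    v <- numeric(138)
    v[24:46] <- lib$cs_plus_cue_gain[i]   # CS+ cue + trace epoch
    v[47:69] <- lib$reward_gain[i]        # CS+ reward/consumption epoch
    v[93:115] <- lib$cs_minus_cue_gain[i] # CS- cue epoch
    if (lib$sustained[i]) v[116:138] <- lib$cs_minus_cue_gain[i]
    tpl[i, ] <- v
  }
  rownames(tpl) <- paste0("motif", lib$motif_id)
  tpl
}
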
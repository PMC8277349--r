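# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded internals do
#' not perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Indices of frames whose timestamps fall in the half-open window [start, end)
#' @noRd
frames_in <- function(frame_times, start, end) {
  which(frame_times >= start & frame_times < end)
}

#' Index of the first frame at or after a time point (NA if none)
#' @noRd
frame_at_or_after <- function(frame_times, t) {
  i <- which(frame_times >= t)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers can distinguish validation errors
#' @noRd
stop_validation <- function(fmt, ..., class = "pfc_validation_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
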
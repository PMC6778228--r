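#' Define the covert-attention task schedule
#'
#' The simulated task mirrors the three-stimulus covert attention dimming
#' paradigm: stimulus onset at 0 ms, a central cue after a variable delay, and
#' a first dimming late enough that the three canonical analysis windows
#' (post-stimulus, post-cue, predimming) exist in every trial. Crossing the
#' 3 attention conditions (attend-RF and two attend-away locations) with 2
#' motion directions gives 6 stimulus conditions per drug state.
#'
#' @param n_trials_per_condition trials per attention x direction x drug cell.
#' @param cue_onset_range_ms range of the cue onset after stimulus onset.
#' @param dim_delay_range_ms range of the first-dimming delay after cue onset;
#'   the lower bound must leave room for the predimming window.
#' @param drug_states drug factor levels; use `"off"` alone for control-only
#'   sessions.
#' @param n_dimming_epochs number of potential dimming times monitored by the
#'   animal (sets the chance hit rate `1 / n_dimming_epochs`).
#' @return an object of class `task_design`.
#' @export
task_design <- function(n_trials_per_condition = 15,
                        cue_onset_range_ms = c(300, 1400),
                        dim_delay_range_ms = c(1500, 2100),
                        drug_states = c("off", "on"),
                        n_dimming_epochs = 3) {
  stopifnot(
    n_trials_per_condition >= 1,
    length(cue_onset_range_ms) == 2L, diff(cue_onset_range_ms) >= 0,
    cue_onset_range_ms[1] >= 300, cue_onset_range_ms[2] <= 1400,
    length(dim_delay_range_ms) == 2L, dim_delay_range_ms[1] >= 1500,
    all(drug_states %in% c("off", "on")), length(drug_states) >= 1,
    n_dimming_epochs >= 1
  )
  structure(
    list(
      n_trials_per_condition = as.integer(n_trials_per_condition),
      attention_levels = c("RF", "away1", "away2"),
      direction_levels = c("d1", "d2"),
      drug_states = unique(drug_states),
      stim_onset_ms = 0,
      cue_onset_range_ms = cue_onset_range_ms,
      dim_delay_range_ms = dim_delay_range_ms,
      n_dimming_epochs = as.integer(n_dimming_epochs)
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "<task_design> %d trials/condition, %d conditions x drug %s, cue U(%g,%g) ms, dim cue+U(%g,%g) ms\n",
    x$n_trials_per_condition,
    length(x$attention_levels) * length(x$direction_levels),
    paste(x$drug_states, collapse = "/"),
    x$cue_onset_range_ms[1], x$cue_onset_range_ms[2],
    x$dim_delay_range_ms[1], x$dim_delay_range_ms[2]
  ))
  invisible(x)
}
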
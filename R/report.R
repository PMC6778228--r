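#' Report-formatting helpers
#'
#' Small helpers used when formatting population reports: percentage of a
#' numerator/denominator pair at printing precision, the chance hit rate of
#' a dimming task, and the expected fraction of parvalbumin-positive cells
#' in an opportunistic cortical sample.
#'
#' @param numerator,denominator integer counts.
#' @param digits decimal places for the percentage (default 1).
#' @return `format_fraction_pct`: the percentage rounded to `digits`.
#' @export
format_fraction_pct <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0, numerator >= 0)
  round(100 * numerator / denominator, digits)
}

#' @rdname format_fraction_pct
#' @param n_dimming_epochs number of potential dimming times the animal must
#'   monitor; guessing one of them gives the chance hit rate.
#' @export
chance_hit_rate <- function(n_dimming_epochs = 3, digits = 2) {
  stopifnot(n_dimming_epochs >= 1)
  round(1 / n_dimming_epochs, digits)
}

#' @rdname format_fraction_pct
#' @param p_inhibitory fraction of cortical neurons that are inhibitory.
#' @param p_pv_among_inhibitory fraction of inhibitory neurons that are
#'   parvalbumin-positive.
#' @export
expected_pv_fraction_pct <- function(p_inhibitory = 0.25,
                                     p_pv_among_inhibitory = 0.25) {
  100 * p_inhibitory * p_pv_among_inhibitory
}
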
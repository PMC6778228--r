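#' Normalized modulation index
#'
#' `MI(a, b) = (a - b) / (a + b)`, defined for non-negative inputs that are
#' not both zero; bounded in `[-1, 1]`, antisymmetric under swapping the
#' inputs, and invariant to common rescaling.
#'
#' @param a,b non-negative values (first argument is the reference, e.g.
#'   activity without drug).
#' @return the index, or `NA` when undefined.
#' @export
modulation_index <- function(a, b) {
  ifelse(is.na(a) | is.na(b) | (a == 0 & b == 0) | a < 0 | b < 0,
         NA_real_, (a - b) / (a + b))
}

#' Per-cell drug modulation index of firing rate
#'
#' `Drug MI = (rate_nodrug - rate_drug) / (rate_nodrug + rate_drug)`,
#' computed per stimulus condition (attention x direction) and analysis
#' window from condition-mean rates. Positive values mean the drug lowered
#' the rate (blockade); excitation yields negative values. The headline
#' per-cell value averages the per-condition MIs across conditions
#' (mean-of-MIs, the default); `order = "mi_of_means"` instead averages the
#' rates across conditions first.
#'
#' @param cell a `cell_recording` with both drug states.
#' @param windows named list of [epoch_window()]s.
#' @param order `"mean_of_mis"` (default) or `"mi_of_means"`.
#' @return tibble with one row per window: `epoch`, `drug_mi`,
#'   `n_conditions`.
#' @export
cell_drug_mi <- function(cell, windows = canonical_windows(),
                         order = c("mean_of_mis", "mi_of_means")) {
  order <- match.arg(order)
  tr <- trial_rates(cell, windows)
  if (length(unique(tr$drug)) < 2) {
    return(tibble::tibble(cell_id = cell$cell_id, epoch = names(windows),
                          drug_mi = NA_real_, n_conditions = 0L))
  }
  rows <- lapply(names(windows), function(nm) {
    col <- paste0("rate_", nm)
    agg <- stats::aggregate(tr[[col]],
                            by = list(attention = tr$attention,
                                      direction = tr$direction,
                                      drug = tr$drug),
                            FUN = mean)
    wide <- merge(agg[agg$drug == "off", c("attention", "direction", "x")],
                  agg[agg$drug == "on", c("attention", "direction", "x")],
                  by = c("attention", "direction"),
                  suffixes = c("_off", "_on"))
    mi <- if (order == "mean_of_mis") {
      mean(modulation_index(wide$x_off, wide$x_on), na.rm = TRUE)
    } else {
      modulation_index(mean(wide$x_off), mean(wide$x_on))
    }
    tibble::tibble(cell_id = cell$cell_id, epoch = nm, drug_mi = mi,
                   n_conditions = nrow(wide))
  })
  dplyr::bind_rows(rows)
}

#' Drug modulation index of gain variance
#'
#' `Drug Gain MI = (gv_nodrug - gv_drug) / (gv_nodrug + gv_drug)`. Negative
#' values mean the drug increased gain variance (as receptor blockade does).
#'
#' @param gv_nodrug,gv_drug gain-variance estimates (>= 0).
#' @export
drug_gain_mi <- function(gv_nodrug, gv_drug) {
  modulation_index(gv_nodrug, gv_drug)
}

#' Attention modulation index of gain variance
#'
#' `Attention Gain MI = (gv_away - gv_rf) / (gv_away + gv_rf)`, oriented so
#' that attentional stabilization (lower gain variance when attending the RF)
#' yields positive values.
#'
#' @param gv_attend_away,gv_attend_rf gain-variance estimates (>= 0).
#' @export
attention_gain_mi <- function(gv_attend_away, gv_attend_rf) {
  modulation_index(gv_attend_away, gv_attend_rf)
}

#' Tidy per-cell modulation-index table
#'
#' Combines the rate drug MI (per analysis window), the gain-variance drug MI
#' and the attention gain MI (per drug state) into one long table.
#'
#' @param population a `cell_population`.
#' @param windows named list of analysis windows for the rate MI.
#' @param gv_table optional precomputed [population_gain_variance()] table.
#' @param min_trials trial floor for the NB fits.
#' @return tibble: `cell_id`, `drug_name`, `index` (kind), `epoch`, `value`.
#' @export
population_modulation_indices <- function(population,
                                          windows = canonical_windows(),
                                          gv_table = NULL,
                                          min_trials = 5) {
  rate_mi <- dplyr::bind_rows(lapply(population$cells, cell_drug_mi,
                                     windows = windows))
  rate_mi <- tibble::tibble(
    cell_id = rate_mi$cell_id,
    index = "drug_mi_rate",
    epoch = rate_mi$epoch,
    value = rate_mi$drug_mi
  )
  if (is.null(gv_table)) {
    gv_table <- population_gain_variance(population, min_trials = min_trials)
  }
  off <- gv_table[gv_table$drug == "off", ]
  on <- gv_table[gv_table$drug == "on", ]
  both <- merge(off, on, by = "cell_id", suffixes = c("_off", "_on"))
  gv_rows <- dplyr::bind_rows(
    tibble::tibble(
      cell_id = both$cell_id, index = "drug_gain_mi", epoch = "dim",
      value = drug_gain_mi(
        (both$gv_attend_rf_off + both$gv_attend_away_off) / 2,
        (both$gv_attend_rf_on + both$gv_attend_away_on) / 2
      )
    ),
    tibble::tibble(
      cell_id = off$cell_id, index = "attention_gain_mi_nodrug", epoch = "dim",
      value = attention_gain_mi(off$gv_attend_away, off$gv_attend_rf)
    ),
    if (nrow(on)) tibble::tibble(
      cell_id = on$cell_id, index = "attention_gain_mi_drug", epoch = "dim",
      value = attention_gain_mi(on$gv_attend_away, on$gv_attend_rf)
    )
  )
  out <- dplyr::bind_rows(rate_mi, gv_rows)
  truth <- population$ground_truth
  out$drug_name <- population$drug_name
  out[, c("cell_id", "drug_name", "index", "epoch", "value")]
}
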
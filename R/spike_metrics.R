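#' Analysis windows
#'
#' An epoch window is an offset pair relative to a trial anchor event. The
#' three canonical windows are 100-400 ms after stimulus onset, 100-400 ms
#' after cue onset, and -500-0 ms before the first dimming. Windows are
#' half-open `[start, end)` so abutting windows never double-count a spike.
#'
#' @param anchor one of `"stimulus_onset"`, `"cue_onset"`, `"first_dimming"`.
#' @param start_ms,end_ms window offsets in ms relative to the anchor.
#' @return an `epoch_window` object.
#' @export
epoch_window <- function(anchor = c("stimulus_onset", "cue_onset", "first_dimming"),
                         start_ms, end_ms) {
  anchor <- match.arg(anchor)
  stopifnot(start_ms < end_ms)
  structure(list(anchor = anchor, start_ms = start_ms, end_ms = end_ms),
            class = "epoch_window")
}

#' @rdname epoch_window
#' @export
canonical_windows <- function() {
  list(
    stim = epoch_window("stimulus_onset", 100, 400),
    cue = epoch_window("cue_onset", 100, 400),
    dim = epoch_window("first_dimming", -500, 0)
  )
}

anchor_time <- function(trial_row, anchor) {
  switch(anchor,
    stimulus_onset = trial_row$stim_on_ms,
    cue_onset = trial_row$cue_on_ms,
    first_dimming = trial_row$dim1_ms
  )
}

#' Waveform trough-to-peak time
#'
#' Measures the time from the global trough to the subsequent maximum on a
#' 10-fold cubic-spline-interpolated waveform, in microseconds. Waveforms
#' without a trough followed by a later peak are flagged invalid (`NA`).
#'
#' @param waveform a `cholattn_waveform` (list with `amplitude` and
#'   `sampling_khz`).
#' @return trough-to-peak time in microseconds, or `NA_real_` if invalid.
#' @export
peak_to_trough <- function(waveform) {
  amp <- waveform$amplitude
  stopifnot(is.numeric(amp), length(amp) >= 4, waveform$sampling_khz > 0)
  dt_us <- 1000 / waveform$sampling_khz
  t <- (seq_along(amp) - 1) * dt_us
  sp <- stats::spline(t, amp, n = (length(amp) - 1L) * 10L + 1L, method = "fmm")
  i_trough <- which.min(sp$y)
  # a boundary trough means there is no biphasic trough-then-peak shape
  if (i_trough <= 1L || i_trough >= length(sp$y)) return(NA_real_)
  after <- sp$y[(i_trough + 1L):length(sp$y)]
  i_peak <- i_trough + which.max(after)
  # a true biphasic waveform rises above baseline after the trough
  if (sp$y[i_peak] <= sp$y[i_trough] || sp$y[i_peak] <= 0) return(NA_real_)
  sp$x[i_peak] - sp$x[i_trough]
}

#' Classify a cell by waveform width
#'
#' Narrow spiking cells have trough-to-peak times at or below 250 us; broad
#' spiking cells are wider.
#'
#' @param p2t_us trough-to-peak time in microseconds.
#' @return `"narrow"` or `"broad"` (`NA` for invalid widths).
#' @export
classify_cell_width <- function(p2t_us) {
  ifelse(is.na(p2t_us) | p2t_us <= 0, NA_character_,
         ifelse(p2t_us <= 250, "narrow", "broad"))
}

#' Firing rate of one trial in one window
#'
#' Spike count in the half-open window `[anchor + start, anchor + end)`
#' divided by the window length.
#'
#' @param spike_times numeric vector of spike times (ms, stimulus onset = 0).
#' @param trial_row one-row data frame with the trial's event times.
#' @param window an [epoch_window()].
#' @return rate in spikes/s, or `NA` when the anchor event is missing.
#' @export
epoch_rate <- function(spike_times, trial_row, window) {
  1000 * epoch_count(spike_times, trial_row, window) /
    (window$end_ms - window$start_ms)
}

#' @rdname epoch_rate
#' @export
epoch_count <- function(spike_times, trial_row, window) {
  t0 <- anchor_time(trial_row, window$anchor)
  if (is.null(t0) || is.na(t0)) return(NA_real_)
  sum(spike_times >= t0 + window$start_ms & spike_times < t0 + window$end_ms)
}

#' ISI variability statistics
#'
#' Computes CV, CV2 and Lv from interspike intervals. ISIs are formed within
#' trials only, never across trial boundaries. CV is the SD/mean of the
#' pooled ISIs; CV2 and Lv are means over adjacent within-trial ISI pairs:
#' `CV2 = mean(2 |I2 - I1| / (I1 + I2))` and `Lv = mean(3 ((I1 - I2) /
#' (I1 + I2))^2)`. For a single train of `n` ISIs the Lv reduces to the usual
#' `3/(n-1) * sum(...)` form. For a gamma renewal process with shape `kappa`,
#' `E[Lv] = 3 / (2 kappa + 1)`.
#'
#' @param spike_trains list of per-trial spike-time vectors (ms).
#' @param min_isis minimum number of ISIs required (default 3).
#' @return list with `cv`, `cv2`, `lv`, `n_isis`, `n_pairs`, and `valid`.
#' @export
isi_stats <- function(spike_trains, min_isis = 3) {
  if (is.numeric(spike_trains)) spike_trains <- list(spike_trains)
  isis <- lapply(spike_trains, function(s) if (length(s) >= 2) diff(sort(s)) else numeric(0))
  pooled <- unlist(isis, use.names = FALSE)
  pairs1 <- unlist(lapply(isis, function(v) if (length(v) >= 2) v[-length(v)] else numeric(0)))
  pairs2 <- unlist(lapply(isis, function(v) if (length(v) >= 2) v[-1] else numeric(0)))
  n_pairs <- length(pairs1)
  if (length(pooled) < min_isis || n_pairs < 1) {
    return(list(cv = NA_real_, cv2 = NA_real_, lv = NA_real_,
                n_isis = length(pooled), n_pairs = n_pairs, valid = FALSE))
  }
  u <- (pairs1 - pairs2) / (pairs1 + pairs2)
  list(
    cv = stats::sd(pooled) / mean(pooled),
    cv2 = mean(2 * abs(pairs1 - pairs2) / (pairs1 + pairs2)),
    lv = mean(3 * u^2),
    n_isis = length(pooled),
    n_pairs = n_pairs,
    valid = TRUE
  )
}

#' Fano factor of trial spike counts
#'
#' @param counts integer spike counts, one per trial, from a single condition
#'   and window.
#' @return variance/mean of the counts; `NA` when fewer than 2 trials or the
#'   mean count is zero.
#' @export
fano_factor <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2 || mean(counts) == 0) return(NA_real_)
  stats::var(counts) / mean(counts)
}

#' Per-trial rates and counts for a cell
#'
#' @param cell a `cell_recording`.
#' @param windows named list of [epoch_window()]s (default the three
#'   canonical windows).
#' @return tibble: trial labels plus `rate_<name>` and `count_<name>` columns.
#' @export
trial_rates <- function(cell, windows = canonical_windows()) {
  out <- cell$trials[, c("trial_id", "attention", "direction", "drug")]
  anchors <- list(
    stimulus_onset = cell$trials$stim_on_ms,
    cue_onset = cell$trials$cue_on_ms,
    first_dimming = cell$trials$dim1_ms
  )
  for (nm in names(windows)) {
    w <- windows[[nm]]
    t0 <- anchors[[w$anchor]]
    lo <- t0 + w$start_ms
    hi <- t0 + w$end_ms
    cnt <- vapply(seq_along(cell$spikes), function(i) {
      if (is.na(t0[i])) return(NA_real_)
      sum(cell$spikes[[i]] >= lo[i] & cell$spikes[[i]] < hi[i])
    }, numeric(1))
    out[[paste0("count_", nm)]] <- cnt
    out[[paste0("rate_", nm)]] <- 1000 * cnt / (w$end_ms - w$start_ms)
  }
  out
}

#' Clustering features and summary metrics of one cell
#'
#' Computes the candidate clustering features: waveform width (P2T) and its
#' narrow/broad class, ISI regularity (CV, CV2, Lv) pooled over all no-drug
#' trials (the manipulation should not contaminate a cell's intrinsic
#' physiology), mean predimming firing rate over no-drug trials, the Fano
#' factor of predimming counts in the attend-RF no-drug condition (averaged
#' over the two directions), and the attentional AUROC from no-drug
#' predimming rates.
#'
#' @param cell a `cell_recording`.
#' @param windows named list of windows; the `dim` entry is used for rates.
#' @return one-row tibble of metrics.
#' @export
cell_metrics <- function(cell, windows = canonical_windows()) {
  p2t <- peak_to_trough(cell$waveform)
  tr <- trial_rates(cell, windows)
  nodrug <- tr$drug == "off"
  stats_isi <- isi_stats(cell$spikes[nodrug])
  ff_by_dir <- vapply(unique(tr$direction), function(d) {
    fano_factor(tr$count_dim[nodrug & tr$attention == "RF" & tr$direction == d])
  }, numeric(1))
  rf <- tr$rate_dim[nodrug & tr$attention == "RF"]
  away <- tr$rate_dim[nodrug & tr$attention != "RF"]
  tibble::tibble(
    cell_id = cell$cell_id,
    drug_name = cell$drug_name,
    p2t_us = p2t,
    cell_class = classify_cell_width(p2t),
    cv = stats_isi$cv,
    cv2 = stats_isi$cv2,
    lv = stats_isi$lv,
    fr = mean(tr$rate_dim[nodrug]),
    fano = mean(ff_by_dir, na.rm = TRUE),
    auroc = if (length(rf) && length(away)) auroc(rf, away) else NA_real_
  )
}

#' @rdname cell_metrics
#' @param population a `cell_population`.
#' @export
population_metrics <- function(population, windows = canonical_windows()) {
  dplyr::bind_rows(lapply(population$cells, cell_metrics, windows = windows))
}
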
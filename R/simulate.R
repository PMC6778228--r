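#' Simulate an extracellular mean spike waveform
#'
#' Builds a biphasic trough-then-peak template whose trough-to-peak interval
#' is drawn from the archetype's `N(p2t_mean_us, p2t_sd_us)`. The template is
#' the sum of a negative and a delayed positive Gaussian lobe, narrow relative
#' to their separation so that the extrema sit at the intended positions on
#' the continuous curve; [peak_to_trough()] recovers the interval to within
#' one interpolated sample.
#'
#' @param archetype a [cell_archetype()].
#' @param sampling_khz waveform sampling rate in kHz (>= 30).
#' @param seed integer seed.
#' @param max_retries redraws allowed when the sampled P2T is non-positive
#'   or too short to be representable.
#' @return a `cholattn_waveform`: list with `amplitude` (samples) and
#'   `sampling_khz`.
#' @export
simulate_waveform <- function(archetype, sampling_khz = 40, seed,
                              max_retries = 20) {
  stopifnot(inherits(archetype, "cell_archetype"), sampling_khz >= 30)
  local_seed(seed, {
    p2t <- NA_real_
    for (i in seq_len(max_retries)) {
      cand <- stats::rnorm(1, archetype$p2t_mean_us, archetype$p2t_sd_us)
      if (cand >= 60) { # representable on the interpolated grid
        p2t <- cand
        break
      }
    }
    if (is.na(p2t)) {
      stop("could not draw a positive trough-to-peak time for archetype ",
           archetype$name)
    }
    dt_us <- 1000 / sampling_khz
    t_us <- seq(0, 2000, by = dt_us)
    t0 <- 500 # trough position, us
    sig <- p2t / 5
    amp <- -exp(-(t_us - t0)^2 / (2 * sig^2)) +
      0.45 * exp(-(t_us - t0 - p2t)^2 / (2 * sig^2))
    structure(
      list(amplitude = amp, sampling_khz = sampling_khz, true_p2t_us = p2t),
      class = "cholattn_waveform"
    )
  })
}

# Event times of one gamma-renewal spike train with piecewise-constant rate.
#
# The train is generated in operational time (unit-rate gamma renewal with
# shape `shape`) and warped through the integrated rate, so regularity
# (`shape`) and rate modulation are independent. `breaks_ms` are segment
# boundaries, `rates_per_ms` the rate within each segment.
gamma_renewal_train <- function(breaks_ms, rates_per_ms, shape) {
  stopifnot(length(breaks_ms) == length(rates_per_ms) + 1L, all(rates_per_ms >= 0))
  durs <- diff(breaks_ms)
  seg_lambda <- rates_per_ms * durs
  total <- sum(seg_lambda)
  if (total <= 0) return(numeric(0))
  # draw operational-time events up to `total`
  n_guess <- ceiling(total + 4 * sqrt((total + 1) / shape) + 20)
  s <- cumsum(stats::rgamma(n_guess, shape = shape, rate = shape))
  while (s[length(s)] < total) {
    s <- c(s, s[length(s)] +
             cumsum(stats::rgamma(n_guess, shape = shape, rate = shape)))
  }
  s <- s[s < total]
  if (!length(s)) return(numeric(0))
  # invert the piecewise-linear integrated rate
  cum <- c(0, cumsum(seg_lambda))
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  breaks_ms[seg] + (s - cum[seg]) / rates_per_ms[seg]
}

#' Simulate one cell's trials
#'
#' Per trial, a multiplicative excitability gain `G` is drawn from a gamma
#' distribution with mean 1 and variance `sigma2_g` scaled per condition
#' (attend-RF and drug-on scalings from the archetype). Spikes are a gamma
#' renewal train (shape `isi_shape`) whose rate is `G` times the condition
#' rate; the attentional gain switches on at cue onset. Counts in a window of
#' length `T` therefore have mean `mu T` and, for `isi_shape = 1`, variance
#' `mu T + sigma2_g (mu T)^2` -- the negative-binomial structure the
#' gain-variance fit assumes.
#'
#' @param archetype a [cell_archetype()].
#' @param design a [task_design()].
#' @param seed integer seed.
#' @param cell_id identifier stored with the recording.
#' @param drug_name label of the drug tested on this cell.
#' @param sampling_khz waveform sampling rate.
#' @return a `cell_recording`: list with `cell_id`, `archetype`, `drug_name`,
#'   `waveform`, `trials` (tibble) and `spikes` (list of spike-time vectors in
#'   ms relative to stimulus onset, parallel to `trials` rows).
#' @export
simulate_cell <- function(archetype, design, seed, cell_id = archetype$name,
                          drug_name = "ACh", sampling_khz = 40) {
  stopifnot(inherits(archetype, "cell_archetype"), inherits(design, "task_design"))
  if (design$n_trials_per_condition < 1) stop("n_trials_per_condition must be >= 1")
  waveform <- simulate_waveform(archetype, sampling_khz,
                                seed = derive_seed(seed, "waveform"))
  grid <- expand.grid(
    drug = design$drug_states,
    attention = design$attention_levels,
    direction = design$direction_levels,
    stringsAsFactors = FALSE
  )
  grid <- grid[rep(seq_len(nrow(grid)), each = design$n_trials_per_condition), ]
  n <- nrow(grid)
  local_seed(derive_seed(seed, "trials"), {
    cue <- stats::runif(n, design$cue_onset_range_ms[1], design$cue_onset_range_ms[2])
    dim1 <- cue + stats::runif(n, design$dim_delay_range_ms[1], design$dim_delay_range_ms[2])
    spikes <- vector("list", n)
    for (i in seq_len(n)) {
      on_drug <- grid$drug[i] == "on"
      att_rf <- grid$attention[i] == "RF"
      ag <- if (att_rf) {
        1 + (archetype$attention_gain - 1) *
          (if (on_drug) archetype$attention_gain_drug_scale else 1)
      } else 1
      gv <- archetype$gain_var *
        (if (att_rf) archetype$gain_var_attend_scale else 1) *
        (if (on_drug) archetype$gain_var_drug_scale else 1)
      g <- if (gv > 0) stats::rgamma(1, shape = 1 / gv, rate = 1 / gv) else 1
      r_pre <- g * archetype$base_rate_hz *
        (if (on_drug) archetype$drug_gain else 1) / 1000
      spikes[[i]] <- gamma_renewal_train(
        breaks_ms = c(0, cue[i], dim1[i]),
        rates_per_ms = c(r_pre, r_pre * ag),
        shape = archetype$isi_shape
      )
    }
    trials <- tibble::tibble(
      trial_id = seq_len(n),
      attention = grid$attention,
      direction = grid$direction,
      drug = grid$drug,
      drug_name = drug_name,
      stim_on_ms = 0,
      cue_on_ms = cue,
      dim1_ms = dim1,
      outcome = "hit",
      rt_ms = NA_real_
    )
    structure(
      list(
        cell_id = cell_id,
        archetype = archetype$name,
        drug_name = drug_name,
        waveform = waveform,
        trials = trials,
        spikes = spikes
      ),
      class = "cell_recording"
    )
  })
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf(
    "<cell_recording %s> archetype %s, drug %s, %d trials, %d spikes\n",
    x$cell_id, x$archetype, x$drug_name, nrow(x$trials),
    sum(lengths(x$spikes))
  ))
  invisible(x)
}

#' Simulate a population of cells with ground truth
#'
#' @param archetypes list of [cell_archetype()] objects.
#' @param cells_per_archetype integer count (recycled across archetypes).
#' @param design a [task_design()].
#' @param seed integer master seed; each cell gets a derived seed.
#' @param drug_name drug label attached to all cells.
#' @return a `cell_population`: list with `cells` (list of `cell_recording`)
#'   and `ground_truth` (tibble `cell_id`, `archetype`).
#' @export
simulate_population <- function(archetypes, cells_per_archetype, design, seed,
                                drug_name = "ACh") {
  if (!length(archetypes)) stop("at least one archetype is required")
  stopifnot(all(vapply(archetypes, inherits, TRUE, "cell_archetype")))
  counts <- rep_len(as.integer(cells_per_archetype), length(archetypes))
  if (all(counts == 0)) stop("all cells_per_archetype are zero")
  cells <- list()
  truth <- list()
  for (a in seq_along(archetypes)) {
    arch <- archetypes[[a]]
    for (j in seq_len(counts[a])) {
      id <- sprintf("%s_%03d", arch$name, j)
      cells[[id]] <- simulate_cell(
        arch, design,
        seed = derive_seed(seed, paste0("cell/", id)),
        cell_id = id, drug_name = drug_name
      )
      truth[[id]] <- tibble::tibble(cell_id = id, archetype = arch$name)
    }
  }
  structure(
    list(cells = cells, ground_truth = dplyr::bind_rows(truth),
         drug_name = drug_name),
    class = "cell_population"
  )
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells (%s), drug %s\n",
              length(x$cells),
              paste(sprintf("%s x%d", names(table(x$ground_truth$archetype)),
                            as.integer(table(x$ground_truth$archetype))),
                    collapse = ", "),
              x$drug_name))
  invisible(x)
}

#' Simulate a behavioral session
#'
#' Per trial the cued stimulus dims once; distractor dimmings may precede it.
#' Each pre-target distractor dimming is (erroneously) reported with
#' probability `false_alarm_p`, ending the trial as a false alarm; otherwise
#' the target dimming is reported with probability `hit_p`. Reaction times of
#' responses are Gaussian around `rt_mean_ms`; `rt_drug_rf_scale` multiplies
#' the RT on drug-on attend-RF trials only, emulating an attention-specific
#' drug effect on behavior.
#'
#' @param design a [task_design()].
#' @param hit_p,false_alarm_p response probabilities in `[0, 1]`.
#' @param rt_mean_ms,rt_sd_ms session reaction-time distribution (ms).
#' @param rt_drug_rf_scale multiplicative RT factor for drug-on attend-RF
#'   trials.
#' @param session_id identifier attached to every trial.
#' @param seed integer seed.
#' @return tibble with one row per trial: outcome (`hit`, `miss`,
#'   `false_alarm`), reaction time, and dimming bookkeeping columns
#'   (`n_target_dims`, `n_distractor_dims`, `n_distractor_reported`).
#' @export
simulate_behavior <- function(design, hit_p = 0.997, false_alarm_p = 0.041,
                              rt_mean_ms = 400, rt_sd_ms = 50,
                              rt_drug_rf_scale = 1,
                              session_id = "s01", seed) {
  stopifnot(inherits(design, "task_design"),
            hit_p >= 0, hit_p <= 1, false_alarm_p >= 0, false_alarm_p <= 1)
  grid <- expand.grid(
    drug = design$drug_states,
    attention = design$attention_levels,
    direction = design$direction_levels,
    stringsAsFactors = FALSE
  )
  grid <- grid[rep(seq_len(nrow(grid)), each = design$n_trials_per_condition), ]
  n <- nrow(grid)
  local_seed(seed, {
    n_distract <- sample(0:(design$n_dimming_epochs - 1), n, replace = TRUE)
    outcome <- character(n)
    n_shown <- integer(n)
    n_fa <- integer(n)
    rt <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      shown <- 0L
      fa <- FALSE
      for (k in seq_len(n_distract[i])) {
        shown <- shown + 1L
        if (stats::runif(1) < false_alarm_p) {
          fa <- TRUE
          break
        }
      }
      n_shown[i] <- shown
      n_fa[i] <- as.integer(fa)
      if (fa) {
        outcome[i] <- "false_alarm"
      } else if (stats::runif(1) < hit_p) {
        outcome[i] <- "hit"
      } else {
        outcome[i] <- "miss"
      }
      if (outcome[i] %in% c("hit", "false_alarm")) {
        scale <- if (grid$drug[i] == "on" && grid$attention[i] == "RF") {
          rt_drug_rf_scale
        } else 1
        rt[i] <- max(50, stats::rnorm(1, rt_mean_ms * scale, rt_sd_ms))
      }
    }
    tibble::tibble(
      session_id = session_id,
      trial_id = seq_len(n),
      attention = grid$attention,
      direction = grid$direction,
      drug = grid$drug,
      outcome = outcome,
      rt_ms = rt,
      n_target_dims = as.integer(outcome != "false_alarm"),
      n_distractor_dims = n_shown,
      n_distractor_reported = n_fa
    )
  })
}
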
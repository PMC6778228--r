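#' Negative-binomial (gamma-gain Poisson) fit of trial counts
#'
#' Fits single-trial spike counts with the modulated-Poisson model: the count
#' is Poisson with rate `G * lambda`, where the trial gain `G` is gamma with
#' mean 1 and variance `sigma2_g`. Marginally the count is negative binomial
#' with mean `lambda` and variance `lambda + sigma2_g * lambda^2`; `sigma2_g`
#' is the gain-variance term of interest (equal to `1 / size` of the standard
#' NB parameterization).
#'
#' The mean is estimated by the sample mean (its maximum-likelihood estimate
#' in this parameterization) and `sigma2_g` by maximizing the profile
#' likelihood on `[0, upper]`, with a method-of-moments start
#' `max(0, (v - m) / m^2)`. Under-dispersed counts land on the boundary
#' `sigma2_g = 0` (the Poisson submodel) with `converged = TRUE`.
#'
#' @param counts non-negative integer counts, one per trial (>= `min_trials`).
#' @param min_trials minimum number of trials for a fit.
#' @return a `gain_fit`: list with `mean_count`, `gain_var`, `loglik`,
#'   `converged`, `n_trials`.
#' @export
fit_negative_binomial <- function(counts, min_trials = 5) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  counts <- as.integer(round(counts))
  out <- list(mean_count = NA_real_, gain_var = NA_real_, loglik = NA_real_,
              converged = FALSE, n_trials = length(counts))
  class(out) <- "gain_fit"
  if (length(counts) < min_trials) return(out)
  m <- mean(counts)
  if (m == 0) return(out) # all-zero counts: dispersion undefined
  ll <- function(s2) {
    if (s2 < 1e-10) sum(stats::dpois(counts, m, log = TRUE))
    else sum(stats::dnbinom(counts, size = 1 / s2, mu = m, log = TRUE))
  }
  s2_mom <- max(0, (stats::var(counts) - m) / m^2)
  upper <- max(1, 5 * s2_mom, 20 / m)
  opt <- stats::optimize(ll, c(0, upper), maximum = TRUE, tol = 1e-9)
  # compare the interior optimum against the Poisson boundary
  if (ll(0) >= opt$objective) {
    out$gain_var <- 0
    out$loglik <- ll(0)
  } else {
    out$gain_var <- opt$maximum
    out$loglik <- opt$objective
  }
  out$mean_count <- m
  out$converged <- TRUE
  out
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> lambda %.3f, sigma2_g %.4f, loglik %.2f, n %d%s\n",
              x$mean_count, x$gain_var, x$loglik, x$n_trials,
              if (x$converged) "" else " (failed)"))
  invisible(x)
}

#' Attend-RF and attend-away gain-variance estimates
#'
#' Fits the negative-binomial count model per stimulus condition (the 2
#' attend-RF conditions: RF x 2 directions; the 4 attend-away conditions:
#' 2 locations x 2 directions) and arithmetically averages the gain-variance
#' terms within the attend-RF set and within the attend-away set. Computed
#' for one drug state at a time. Conditions whose fit fails (too few trials,
#' all-zero counts) are dropped; a side with no surviving condition is `NA`.
#'
#' @param cell a `cell_recording`.
#' @param window counting window (default predimming, -500..0 ms).
#' @param drug_state `"off"` or `"on"`.
#' @param min_trials minimum trials per condition fit.
#' @return list with `gv_attend_rf`, `gv_attend_away`, `n_conditions_rf`,
#'   `n_conditions_away`, and the per-condition `fits`.
#' @export
gain_variance_by_attention <- function(cell, window = canonical_windows()$dim,
                                       drug_state = "off", min_trials = 5) {
  tr <- trial_rates(cell, list(w = window))
  tr <- tr[tr$drug == drug_state, ]
  conds <- unique(tr[, c("attention", "direction")])
  fits <- list()
  side <- character(0)
  for (i in seq_len(nrow(conds))) {
    sel <- tr$attention == conds$attention[i] & tr$direction == conds$direction[i]
    fit <- fit_negative_binomial(tr$count_w[sel], min_trials = min_trials)
    key <- paste(conds$attention[i], conds$direction[i], sep = "_")
    fits[[key]] <- fit
    side[key] <- if (conds$attention[i] == "RF") "rf" else "away"
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  gv <- vapply(fits, `[[`, numeric(1), "gain_var")
  gv_rf <- gv[ok & side == "rf"]
  gv_away <- gv[ok & side == "away"]
  list(
    gv_attend_rf = if (length(gv_rf)) mean(gv_rf) else NA_real_,
    gv_attend_away = if (length(gv_away)) mean(gv_away) else NA_real_,
    n_conditions_rf = length(gv_rf),
    n_conditions_away = length(gv_away),
    fits = fits
  )
}

#' Population gain-variance table
#'
#' One row per cell and drug state with attend-RF and attend-away
#' gain-variance estimates from [gain_variance_by_attention()].
#'
#' @param population a `cell_population`.
#' @inheritParams gain_variance_by_attention
#' @export
population_gain_variance <- function(population,
                                     window = canonical_windows()$dim,
                                     min_trials = 5) {
  rows <- list()
  for (cell in population$cells) {
    for (state in unique(cell$trials$drug)) {
      gv <- gain_variance_by_attention(cell, window, state, min_trials)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = cell$cell_id,
        drug_name = cell$drug_name,
        drug = state,
        gv_attend_rf = gv$gv_attend_rf,
        gv_attend_away = gv$gv_attend_away,
        n_conditions_rf = gv$n_conditions_rf,
        n_conditions_away = gv$n_conditions_away
      )
    }
  }
  dplyr::bind_rows(rows)
}
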
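#' Hit and correct-rejection rates
#'
#' Hit rate: reported target dimmings over target dimmings shown. Correct
#' rejection rate: unreported distractor dimmings over distractor dimmings
#' shown.
#'
#' @param behavior trial table from [simulate_behavior()] (or any table with
#'   `outcome`, `n_target_dims`, `n_distractor_dims`,
#'   `n_distractor_reported`).
#' @return list with `hit_rate`, `cr_rate`, and the underlying counts
#'   (`NA` rate when a denominator is zero).
#' @export
hit_cr_rates <- function(behavior) {
  n_targets <- sum(behavior$n_target_dims)
  n_hits <- sum(behavior$outcome == "hit")
  n_distract <- sum(behavior$n_distractor_dims)
  n_fa <- sum(behavior$n_distractor_reported)
  list(
    hit_rate = if (n_targets > 0) n_hits / n_targets else NA_real_,
    cr_rate = if (n_distract > 0) 1 - n_fa / n_distract else NA_real_,
    n_targets = n_targets, n_hits = n_hits,
    n_distractor_dims = n_distract, n_false_alarms = n_fa
  )
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the standard normal
#' quantile `z`. Rates of exactly 0 or 1 are clipped by `1/(2N)` when the
#' corresponding trial count is supplied (with a warning); without a count
#' they produce infinite values.
#'
#' @param hit_rate,false_alarm_rate rates in `[0, 1]`.
#' @param n_targets,n_distractors optional counts for the clipping rule.
#' @return d-prime (dimensionless).
#' @export
d_prime <- function(hit_rate, false_alarm_rate,
                    n_targets = NULL, n_distractors = NULL) {
  clip <- function(r, n, what) {
    if (r %in% c(0, 1)) {
      if (is.null(n)) {
        warning(what, " rate of ", r, " without a trial count gives an infinite d-prime")
        return(r)
      }
      warning("clipping ", what, " rate of ", r, " by 1/(2N), N = ", n)
      return(min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n)))
    }
    r
  }
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1)
  h <- clip(hit_rate, n_targets, "hit")
  f <- clip(false_alarm_rate, n_distractors, "false-alarm")
  stats::qnorm(h) - stats::qnorm(f)
}

#' Session-normalized reaction times
#'
#' Divides each correct-response (hit) RT by its session's mean hit RT, so
#' normalized RTs have mean exactly 1 within every session and sessions with
#' different overall speed become comparable. Sessions without any hit RT
#' are skipped with a warning.
#'
#' @param behavior trial table with `session_id`, `outcome`, `rt_ms`.
#' @return the table restricted to hit trials, with an `rt_norm` column.
#' @export
normalize_rts <- function(behavior) {
  hits <- behavior[behavior$outcome == "hit" & !is.na(behavior$rt_ms), ]
  means <- tapply(hits$rt_ms, hits$session_id, mean)
  empty <- setdiff(unique(behavior$session_id), names(means))
  if (length(empty)) {
    warning("session(s) without hit RTs skipped: ", paste(empty, collapse = ", "))
  }
  hits$rt_norm <- hits$rt_ms / as.numeric(means[as.character(hits$session_id)])
  hits
}

#' Drug x attention ANOVA on normalized reaction times
#'
#' Two-factor fixed-effects ANOVA (Type-II SS) of session-normalized RTs on
#' drug state and locus of attention (the two attend-away locations pooled
#' into "away"), followed by the post-hoc two-sided Welch t tests of drug
#' effect within each attention condition.
#'
#' @param normalized output of [normalize_rts()].
#' @return list with `anova` (tibble) and `posthoc` (tibble per attention
#'   condition).
#' @export
rt_anova <- function(normalized) {
  df <- normalized
  df$attention2 <- ifelse(df$attention == "RF", "RF", "away")
  df$rate <- df$rt_norm
  tab <- factorial_anova(df, response = "rate", factors = c("drug", "attention2"))
  posthoc <- dplyr::bind_rows(lapply(unique(df$attention2), function(a) {
    sub <- df[df$attention2 == a, ]
    if (length(unique(sub$drug)) < 2) return(NULL)
    tt <- stats::t.test(rt_norm ~ drug, data = sub)
    tibble::tibble(
      attention = a,
      mean_off = mean(sub$rt_norm[sub$drug == "off"]),
      mean_on = mean(sub$rt_norm[sub$drug == "on"]),
      statistic = unname(tt$statistic),
      p_value = tt$p.value
    )
  }))
  list(anova = tab, posthoc = posthoc)
}

#' Behavioral performance summary
#'
#' Hit and correct-rejection rates, d-prime, and the drug effect on
#' session-normalized reaction times.
#'
#' @param behavior trial table (one or more sessions).
#' @return a `behavior_summary` list.
#' @export
behavior_summary <- function(behavior) {
  rates <- hit_cr_rates(behavior)
  dp <- d_prime(rates$hit_rate, 1 - rates$cr_rate,
                n_targets = rates$n_targets,
                n_distractors = rates$n_distractor_dims)
  normalized <- normalize_rts(behavior)
  rt <- if (length(unique(behavior$drug)) >= 2) rt_anova(normalized) else NULL
  structure(
    list(
      hit_rate = rates$hit_rate,
      cr_rate = rates$cr_rate,
      d_prime = dp,
      counts = rates[c("n_targets", "n_hits", "n_distractor_dims",
                       "n_false_alarms")],
      normalized_rts = normalized,
      rt_anova = rt
    ),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> hit %.3f, CR %.3f, d-prime %.2f, %d hit RTs\n",
              x$hit_rate, x$cr_rate, x$d_prime, nrow(x$normalized_rts)))
  invisible(x)
}
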
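#' Factorial ANOVA on per-trial rates
#'
#' Fixed-effects factorial ANOVA with all main effects and interactions,
#' using Type-II sums of squares so unbalanced designs are handled sensibly.
#' Factors with a single observed level are dropped with a warning.
#'
#' @param data data frame with the response and factor columns.
#' @param response name of the response column (per-trial firing rate).
#' @param factors character vector of factor column names, e.g.
#'   `c("attention", "direction", "drug")`.
#' @return tibble with one row per effect: `effect`, `df`, `statistic`
#'   (F value) and `p_value`.
#' @export
factorial_anova <- function(data, response = "rate",
                            factors = c("attention", "direction", "drug")) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  keep <- factors[vapply(factors, function(f) {
    length(unique(data[[f]][!is.na(data[[f]])])) >= 2
  }, logical(1))]
  if (length(dropped <- setdiff(factors, keep))) {
    warning("dropping single-level factor(s): ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no factor with at least two levels")
  df <- data[stats::complete.cases(data[, c(response, keep)]), , drop = FALSE]
  for (f in keep) df[[f]] <- factor(df[[f]])
  form <- stats::reformulate(paste(keep, collapse = " * "), response = response)
  fit <- stats::lm(form, data = df)
  aov_tab <- car::Anova(fit, type = 2)
  rows <- rownames(aov_tab)
  keep_rows <- !(rows %in% c("Residuals", "(Intercept)"))
  tibble::tibble(
    effect = rows[keep_rows],
    df = aov_tab$Df[keep_rows],
    statistic = aov_tab$`F value`[keep_rows],
    p_value = aov_tab$`Pr(>F)`[keep_rows]
  )
}

#' Classify a cell's modulation from its ANOVA screen
#'
#' A cell is attention modulated when the attention main effect or any
#' interaction involving attention is significant; drug modulated when the
#' drug main effect or any interaction involving drug is significant.
#'
#' @param anova_table output of [factorial_anova()].
#' @param alpha significance level (two-sided, default 0.05).
#' @return one-row tibble with the main-effect p values and the two flags.
#' @export
classify_modulation <- function(anova_table, alpha = 0.05) {
  has <- function(term, factor_name) {
    factor_name %in% strsplit(term, ":", fixed = TRUE)[[1]]
  }
  p_of <- function(factor_name) {
    i <- which(anova_table$effect == factor_name)
    if (length(i)) anova_table$p_value[i] else NA_real_
  }
  involved <- function(factor_name) {
    idx <- vapply(anova_table$effect, has, logical(1), factor_name = factor_name)
    any(anova_table$p_value[idx] < alpha, na.rm = TRUE)
  }
  tibble::tibble(
    p_attention = p_of("attention"),
    p_direction = p_of("direction"),
    p_drug = p_of("drug"),
    attention_modulated = involved("attention"),
    drug_modulated = involved("drug")
  )
}

#' Ideal-observer AUROC
#'
#' Pair-counting estimator of the probability that a random single-trial
#' rate from the attend-RF condition exceeds one from the attend-away
#' condition, ties counted half:
#' `(#\{RF > away\} + 0.5 #\{ties\}) / (n_RF n_away)`. Equal to the
#' Wilcoxon-Mann-Whitney `U / (n1 n2)`.
#'
#' @param rates_rf,rates_away numeric samples of per-trial rates.
#' @return AUROC in `[0, 1]`, `NA` if either sample is empty.
#' @export
auroc <- function(rates_rf, rates_away) {
  rates_rf <- rates_rf[!is.na(rates_rf)]
  rates_away <- rates_away[!is.na(rates_away)]
  if (!length(rates_rf) || !length(rates_away)) return(NA_real_)
  cmp <- outer(rates_rf, rates_away, ">") + 0.5 * outer(rates_rf, rates_away, "==")
  mean(cmp)
}

#' Folded AUROC sensitivity variant
#'
#' Returns `max(auroc, 1 - auroc)`; reported alongside (never instead of)
#' the raw value, for cells whose rate decreases under attention.
#'
#' @param auroc AUROC value(s) in `[0, 1]`.
#' @export
auroc_folding <- function(auroc) pmax(auroc, 1 - auroc)

#' Cohen's d with pooled SD
#'
#' @param sample_a,sample_b numeric samples (each at least 2 values).
#' @return `(mean_a - mean_b) / pooled SD`; `NA` when the pooled SD is 0.
#' @export
cohens_d <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2) return(NA_real_)
  sp <- sqrt(((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(sample_a) - mean(sample_b)) / sp
}

#' Benjamini-Hochberg adjusted p values
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, the step-up false
#' discovery rate control used for all multiple-comparison corrections here.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Per-cell ANOVA screen and attentional modulation
#'
#' Screens the predimming rates of one cell with the factorial ANOVA
#' (attention x direction x drug) and quantifies attentional modulation with
#' AUROC and Cohen's d, separately for the no-drug and drug conditions. Both
#' attend-away locations and both directions are pooled into the "away"
#' sample by default.
#'
#' @param cell a `cell_recording`.
#' @param window an [epoch_window()]; default the predimming window.
#' @param alpha screen significance level.
#' @param pool_away pool the two attend-away locations (default `TRUE`);
#'   otherwise the first away location alone is used.
#' @return one-row tibble: screen p values and flags, AUROC and Cohen's d per
#'   drug state, folded AUROC, and trial counts.
#' @export
cell_attention_stats <- function(cell, window = canonical_windows()$dim,
                                 alpha = 0.05, pool_away = TRUE) {
  tr <- trial_rates(cell, list(w = window))
  tr$rate <- tr$rate_w
  has_drug <- length(unique(tr$drug)) >= 2
  screen <- classify_modulation(
    factorial_anova(tr, "rate", c("attention", "direction",
                                  if (has_drug) "drug")),
    alpha = alpha
  )
  one_state <- function(state) {
    sub <- tr[tr$drug == state, ]
    away_levels <- if (pool_away) c("away1", "away2") else "away1"
    rf <- sub$rate[sub$attention == "RF"]
    away <- sub$rate[sub$attention %in% away_levels]
    list(auroc = auroc(rf, away), d = cohens_d(rf, away),
         n_rf = length(rf), n_away = length(away))
  }
  nd <- one_state("off")
  dr <- if (has_drug) one_state("on") else list(auroc = NA_real_, d = NA_real_,
                                                n_rf = 0L, n_away = 0L)
  dplyr::bind_cols(
    tibble::tibble(cell_id = cell$cell_id, drug_name = cell$drug_name),
    screen,
    tibble::tibble(
      auroc_nodrug = nd$auroc, auroc_drug = dr$auroc,
      auroc_nodrug_folded = auroc_folding(nd$auroc),
      auroc_drug_folded = auroc_folding(dr$auroc),
      cohens_d_nodrug = nd$d, cohens_d_drug = dr$d,
      n_rf_nodrug = nd$n_rf, n_away_nodrug = nd$n_away,
      n_rf_drug = dr$n_rf, n_away_drug = dr$n_away
    )
  )
}

#' @rdname cell_attention_stats
#' @param population a `cell_population`.
#' @export
population_attention_stats <- function(population,
                                       window = canonical_windows()$dim,
                                       alpha = 0.05, pool_away = TRUE) {
  dplyr::bind_rows(lapply(population$cells, cell_attention_stats,
                          window = window, alpha = alpha,
                          pool_away = pool_away))
}
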
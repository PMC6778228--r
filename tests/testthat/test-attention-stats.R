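test_that("factorial ANOVA matches a brute-force Type-II SS oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(18:30, 1)
    df <- data.frame(
      attention = sample(c("RF", "away1", "away2"), n, replace = TRUE),
      direction = sample(c("d1", "d2"), n, replace = TRUE),
      drug = sample(c("off", "on"), n, replace = TRUE),
      rate = rnorm(n, 10, 3)
    )
    # ensure every factor has 2+ levels
    if (length(unique(df$attention)) < 2 || length(unique(df$drug)) < 2 ||
          length(unique(df$direction)) < 2) next
    got <- try(factorial_anova(df), silent = TRUE)
    if (inherits(got, "try-error")) next # aliased random design
    oracle <- anova_type2_oracle(df, "rate", c("attention", "direction", "drug"))
    for (eff in names(oracle)) {
      i <- which(got$effect == eff)
      expect_equal(got$statistic[i], unname(oracle[[eff]]["statistic"]),
                   tolerance = 1e-10)
      expect_equal(got$df[i], unname(oracle[[eff]]["df"]))
    }
  }
})

test_that("purely additive balanced designs have zero interaction F", {
  set.seed(99)
  grid <- expand.grid(attention = c("RF", "away1"), drug = c("off", "on"),
                      rep = 1:4)
  grid$rate <- 5 + 2 * (grid$attention == "RF") + 1 * (grid$drug == "on")
  # cell-centered noise keeps every cell mean exactly additive while the
  # residual SS stays positive, so the interaction F is exactly 0
  noise <- rnorm(nrow(grid))
  grid$rate <- grid$rate + noise -
    ave(noise, grid$attention, grid$drug, FUN = mean)
  tab <- factorial_anova(grid, "rate", c("attention", "drug"))
  expect_equal(tab$statistic[tab$effect == "attention:drug"], 0,
               tolerance = 1e-12)
})

test_that("single-level factors are dropped with a warning", {
  df <- data.frame(attention = rep(c("RF", "away1"), each = 6),
                   drug = "off", rate = rnorm(12))
  expect_warning(tab <- factorial_anova(df, "rate", c("attention", "drug")),
                 "single-level")
  expect_false(any(grepl("drug", tab$effect)))
})

test_that("modulation flags follow the significance rule exactly", {
  tab <- tibble::tibble(
    effect = c("attention", "direction", "drug", "attention:drug"),
    df = c(2, 1, 1, 2),
    statistic = c(1, 1, 1, 1),
    p_value = c(0.06, 0.5, 0.2, 0.051)
  )
  flags <- classify_modulation(tab)
  expect_false(flags$attention_modulated)
  expect_false(flags$drug_modulated)

  tab$p_value[4] <- 0.049 # an interaction flips both factors it involves
  flags <- classify_modulation(tab)
  expect_true(flags$attention_modulated)
  expect_true(flags$drug_modulated)
})

test_that("AUROC is the pair-counting ideal observer", {
  expect_equal(auroc(c(3, 5, 7), c(2, 4, 6)), 6 / 9)
  x <- c(1, 2, 3, 4)
  expect_equal(auroc(x, x), 0.5)
  expect_equal(auroc(c(5, 6), c(1, 2)), 1)
  expect_true(is.na(auroc(numeric(0), 1:3)))
})

test_that("AUROC equals the rank-sum statistic and respects monotone maps", {
  set.seed(21)
  for (i in 1:50) {
    a <- round(rgamma(sample(3:20, 1), 3, 0.5), 1) # discrete: forces ties
    b <- round(rgamma(sample(3:20, 1), 3, 0.4), 1)
    u <- suppressWarnings(wilcox.test(a, b))$statistic
    expect_equal(auroc(a, b), unname(u) / (length(a) * length(b)))
    expect_equal(auroc(exp(a / 10), exp(b / 10)), auroc(a, b))
  }
})

test_that("Cohen's d uses the pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(cohens_d(c(5, 6), c(5, 6)), 0)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1)))) # zero pooled SD
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)))
})

test_that("AUROC folding reports the symmetric variant", {
  expect_equal(auroc_folding(0.3), 0.7)
  expect_equal(auroc_folding(0.5), 0.5)
  expect_equal(auroc_folding(c(0.2, 0.8)), c(0.8, 0.8))
})

test_that("per-cell screen flags known effects at adequate power", {
  design <- task_design(n_trials_per_condition = 25)
  arch <- cell_archetype("mod", p2t_mean_us = 420, p2t_sd_us = 0,
                         base_rate_hz = 15, attention_gain = 1.5,
                         drug_gain = 1, gain_var = 0, isi_shape = 1)
  cell <- simulate_cell(arch, design, seed = 13)
  res <- cell_attention_stats(cell)
  expect_true(res$attention_modulated)
  expect_gt(res$auroc_nodrug, 0.6)
  expect_gt(res$cohens_d_nodrug, 0.5)
  expect_equal(res$n_rf_nodrug, 50)
  expect_equal(res$n_away_nodrug, 100)
})
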